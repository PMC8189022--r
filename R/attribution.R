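#' @title ADL / ADP / ADR attribution workflows
#' @description Shapley decomposition of the dependence between the features
#'   and, respectively, the observed labels (ADL), an external model's
#'   predictions (ADP) or its residuals (ADR), with bootstrap percentile
#'   intervals and a misspecification comparison.
#' @name attribution
NULL

attribution_engine <- function(target, X, target_kind,
                               measure = "dcor",
                               method = c("exact", "mc"),
                               m = 1000L, seed = NULL,
                               features = NULL, kernel = NULL,
                               bootstrap = FALSE, B = 100L,
                               resample_size = NULL, boot_seed = NULL,
                               cap = 20L) {
  method <- match.arg(method)
  X <- as_data_matrix(X, "X")
  target <- as.numeric(target)
  if (length(target) != nrow(X)) {
    stop(sprintf("target vector has length %d but X has %d rows",
                 length(target), nrow(X)))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(features)) {
    features <- resolve_features(features, colnames(X))
    X <- X[, features, drop = FALSE]
  }
  decompose <- function(tgt, Xm) {
    C <- make_characteristic(measure, tgt, Xm, kernel = kernel)
    if (method == "exact") shapley_exact(C, cap = cap)
    else shapley_mc(C, m = m, seed = if (is.null(seed)) 1L else seed)
  }
  dec <- decompose(target, X)
  values <- stats::setNames(dec$values, colnames(X))
  boot <- NULL
  if (isTRUE(bootstrap)) {
    n <- nrow(X)
    size <- if (is.null(resample_size)) n else as.integer(resample_size)
    bs <- if (is.null(boot_seed)) 1L else boot_seed
    boot <- bootstrap_ci(function(idx) {
      d2 <- decompose(target[idx], X[idx, , drop = FALSE])
      stats::setNames(d2$values, colnames(X))
    }, n = n, B = B, resample_size = size, seed = bs)
  }
  structure(
    list(target_kind = target_kind, measure = measure, values = values,
         payoff_full = dec$payoff_full, n = nrow(X), method = dec$method,
         n_evaluations = dec$n_evaluations,
         n_permutations = dec$n_permutations, seed = seed,
         bootstrap = boot),
    class = "sunnies_attribution"
  )
}

resolve_features <- function(features, nms) {
  if (is.character(features)) {
    miss <- setdiff(features, nms)
    if (length(miss) > 0) {
      stop(sprintf("feature(s) not found in X: %s",
                   paste(miss, collapse = ", ")))
    }
    return(match(features, nms))
  }
  features <- as.integer(features)
  if (any(features < 1L) || any(features > length(nms)) ||
      anyDuplicated(features)) {
    stop("features must be distinct column indices of X")
  }
  features
}

#' @export
print.sunnies_attribution <- function(x, ...) {
  cat(sprintf("Attributed dependence on %s (%s, %s), n = %d\n",
              x$target_kind, x$measure, x$method, x$n))
  tab <- data.frame(value = round(x$values, 6))
  if (!is.null(x$bootstrap)) {
    tab$lower <- round(x$bootstrap$lower, 6)
    tab$upper <- round(x$bootstrap$upper, 6)
  }
  print(tab)
  cat(sprintf("full-set dependence: %.6g\n", x$payoff_full))
  invisible(x)
}

#' Attributed dependence on labels (ADL)
#'
#' Shapley decomposition of the dependence between the observed labels and
#' the features: feature `v` receives the average, over coalition sizes, of
#' its marginal contribution to the dependence measure. Requires no model;
#' the values sum (for exact decompositions) to the dependence of the full
#' feature set on the labels.
#'
#' @param y Numeric label vector, row-aligned with `X`.
#' @param X Feature matrix (columns named, or `x1..xd` assigned).
#' @param measure Dependence measure name; see [make_characteristic()].
#' @param method `"exact"` (power-set enumeration, default) or `"mc"`
#'   (permutation sampling).
#' @param m Permutation count when `method = "mc"`.
#' @param seed Seed for the Monte Carlo sampler.
#' @param features Optional subset of columns (names or indices) to treat as
#'   the players; the characteristic function is then the dependence of the
#'   target on the selected columns only. Used to scrutinise a few features
#'   of a wide table without paying the full `2^d` cost.
#' @param kernel Optional [kernel_spec()] for `measure = "hsic"`.
#' @param bootstrap If `TRUE`, attach percentile bootstrap summaries.
#' @param B Number of bootstrap resamples (default 100).
#' @param resample_size Rows per resample, drawn with replacement
#'   (default `n`).
#' @param boot_seed Seed for the bootstrap stream.
#' @param cap Exact-enumeration cap, passed to [shapley_exact()].
#' @return A `sunnies_attribution` object: per-feature `values`,
#'   `payoff_full`, method metadata and optional `bootstrap` summaries.
#' @examples
#' sim <- simulate_xor(500, seed = 7)
#' adl(sim$y, sim$X, measure = "dcor")
#' @export
adl <- function(y, X, measure = "dcor", method = c("exact", "mc"),
                m = 1000L, seed = NULL, features = NULL, kernel = NULL,
                bootstrap = FALSE, B = 100L, resample_size = NULL,
                boot_seed = NULL, cap = 20L) {
  attribution_engine(y, X, "labels", measure, method, m, seed, features,
                     kernel, bootstrap, B, resample_size, boot_seed, cap)
}

#' Attributed dependence on predictions (ADP)
#'
#' As [adl()] with the labels replaced by the predictions of an externally
#' fitted model: decomposes the dependence structure the model itself
#' generates, for comparison against the ADL via [compare_attributions()].
#'
#' @param yhat Prediction vector from any fitted model, row-aligned with `X`.
#' @inheritParams adl
#' @return A `sunnies_attribution` with `target_kind = "predictions"`.
#' @export
adp <- function(yhat, X, measure = "dcor", method = c("exact", "mc"),
                m = 1000L, seed = NULL, features = NULL, kernel = NULL,
                bootstrap = FALSE, B = 100L, resample_size = NULL,
                boot_seed = NULL, cap = 20L) {
  attribution_engine(yhat, X, "predictions", measure, method, m, seed,
                     features, kernel, bootstrap, B, resample_size,
                     boot_seed, cap)
}

#' Attributed dependence on residuals (ADR)
#'
#' Decomposes the dependence between the model residuals `e = y - yhat`
#' (always recomputed internally from labels and predictions) and the
#' features. Dependence left in the residuals, attributed to specific
#' features, points at structure the model fails to capture.
#'
#' @param y Label vector.
#' @param yhat Prediction vector, row-aligned with `y` and `X`.
#' @inheritParams adl
#' @return A `sunnies_attribution` with `target_kind = "residuals"`.
#' @export
adr <- function(y, yhat, X, measure = "dcor", method = c("exact", "mc"),
                m = 1000L, seed = NULL, features = NULL, kernel = NULL,
                bootstrap = FALSE, B = 100L, resample_size = NULL,
                boot_seed = NULL, cap = 20L) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) {
    stop(sprintf("y has length %d but yhat has length %d",
                 length(y), length(yhat)))
  }
  attribution_engine(y - yhat, X, "residuals", measure, method, m, seed,
                     features, kernel, bootstrap, B, resample_size,
                     boot_seed, cap)
}

#' Percentile bootstrap over row resamples
#'
#' Draws `B` with-replacement resamples of `resample_size` row indices from
#' `1:n`, applies `fn` to each index vector, and reports per-component
#' empirical 2.5% and 97.5% quantiles (type-7 linear-interpolation
#' definition). `point` is `fn` on the identity indices. Deterministic given
#' `seed`.
#'
#' @param fn Function taking an integer index vector and returning a numeric
#'   vector (named components are preserved).
#' @param n Number of rows available for resampling.
#' @param B Number of resamples, at least 2.
#' @param resample_size Rows drawn per resample (default `n`).
#' @param seed Integer seed for the resampling stream.
#' @return A data frame with columns `point`, `lower`, `upper`, `B`,
#'   `resample_size`, `seed`, one row per component of `fn`'s output.
#' @export
bootstrap_ci <- function(fn, n, B = 100L, resample_size = n, seed = 1L) {
  if (!is.numeric(B) || B < 2) stop("B must be at least 2")
  B <- as.integer(B)
  resample_size <- as.integer(resample_size)
  point <- fn(seq_len(n))
  draws <- matrix(NA_real_, nrow = B, ncol = length(point))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, resample_size, replace = TRUE)
      draws[b, ] <- fn(idx)
    }
  })
  q <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE, type = 7)
  out <- data.frame(point = as.numeric(point), lower = q[1L, ],
                    upper = q[2L, ], B = B, resample_size = resample_size,
                    seed = as.integer(seed))
  rownames(out) <- names(point)
  out
}

#' Compare ADL and ADP attributions for misspecification
#'
#' Flags feature `v` when `|ADP_v - ADL_v| >= delta`: a large gap means the
#' model's predictions place materially different dependence on that feature
#' than the labels do. When both results carry bootstrap summaries an
#' interval-overlap column is reported too (non-overlap being the stronger,
#' caption-style evidence), and `delta` may be omitted, in which case it is
#' derived as the mean bootstrap half-width and flagged as derived.
#'
#' @param adl_result,adp_result `sunnies_attribution` objects over the same
#'   features with the same measure.
#' @param delta Positive tolerance on the per-feature gap; required unless
#'   both inputs carry bootstrap summaries.
#' @return A `misspecification_report`: a data frame with per-feature `adl`,
#'   `adp`, `abs_diff`, `delta`, `flagged` and (when available)
#'   `intervals_overlap`, plus a `delta_derived` attribute.
#' @export
compare_attributions <- function(adl_result, adp_result, delta = NULL) {
  stopifnot(inherits(adl_result, "sunnies_attribution"),
            inherits(adp_result, "sunnies_attribution"))
  if (!identical(names(adl_result$values), names(adp_result$values))) {
    stop("feature sets of the two attributions differ")
  }
  if (!identical(adl_result$measure, adp_result$measure)) {
    stop(sprintf("measures differ: %s vs %s", adl_result$measure,
                 adp_result$measure))
  }
  have_boot <- !is.null(adl_result$bootstrap) && !is.null(adp_result$bootstrap)
  delta_derived <- FALSE
  if (is.null(delta)) {
    if (!have_boot) {
      stop("delta is required when the attributions carry no bootstrap summaries")
    }
    hw <- c(adl_result$bootstrap$upper - adl_result$bootstrap$lower,
            adp_result$bootstrap$upper - adp_result$bootstrap$lower) / 2
    delta <- mean(hw)
    delta_derived <- TRUE
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a single positive number")
  }
  diff <- abs(adp_result$values - adl_result$values)
  rep <- data.frame(feature = names(adl_result$values),
                    adl = as.numeric(adl_result$values),
                    adp = as.numeric(adp_result$values),
                    abs_diff = as.numeric(diff),
                    delta = delta,
                    flagged = as.numeric(diff) >= delta,
                    stringsAsFactors = FALSE)
  if (have_boot) {
    rep$intervals_overlap <-
      adl_result$bootstrap$lower <= adp_result$bootstrap$upper &
      adp_result$bootstrap$lower <= adl_result$bootstrap$upper
  }
  attr(rep, "delta_derived") <- delta_derived
  class(rep) <- c("misspecification_report", "data.frame")
  rep
}

#' @export
print.misspecification_report <- function(x, ...) {
  cat("ADP vs ADL misspecification report (delta =",
      format(x$delta[1L], digits = 4),
      if (isTRUE(attr(x, "delta_derived"))) "[derived from bootstrap half-widths]",
      ")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
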