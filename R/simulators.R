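#' @title Reference data-generating processes
#' @description Seeded generators for the four simulation designs used
#'   throughout the package: a quadratic form with zero linear covariance, a
#'   binary XOR with mutual but no pairwise dependence, a 50-feature linear
#'   process with concept drift, and a three-way interaction process for
#'   misspecification diagnostics.
#' @name simulators
NULL

# Each generator draws from an RNG stream derived from (seed, variant), so
# adding generators or reordering calls never perturbs existing fixtures.
variant_seed <- function(seed, variant) {
  off <- match(variant, c("quadratic", "xor", "drift", "interaction"))
  as.integer((as.numeric(seed) %% 1203793L) * 1783L + off)
}

finish_sim <- function(X, y, variant) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  list(X = X, y = as.numeric(y), variant = variant)
}

#' Quadratic-form process: non-linear dependence invisible to covariance
#'
#' Features are independent uniform on `[-1, 1]` and the response is the
#' quadratic form `y = sum_j a_j x_j^2`. Because the odd moments of the
#' uniform vanish, `Cov(Y, X_j) = 0` for every feature: the dependence is
#' purely non-linear.
#'
#' @param n Sample size.
#' @param a Numeric vector, the diagonal of the quadratic form; its length
#'   sets the number of features. Default `c(0, 2, 4, 6, 8)`.
#' @param seed Integer seed.
#' @return A list with an `n x d` feature matrix `X` (columns `x1..xd`) and
#'   label vector `y`.
#' @export
simulate_quadratic <- function(n, a = c(0, 2, 4, 6, 8), seed = 1L) {
  stopifnot(n >= 1, is.numeric(a), length(a) >= 1)
  d <- length(a)
  with_seed(variant_seed(seed, "quadratic"), {
    X <- matrix(stats::runif(n * d, -1, 1), nrow = n, ncol = d)
    finish_sim(X, X^2 %*% a, "quadratic")
  })
}

#' XOR process: mutual dependence without pairwise dependence
#'
#' Two independent Bernoulli(1/2) features and the response
#' `y = x1 (1 - x2) + x2 (1 - x1)`, i.e. their exclusive-or. The response is
#' statistically independent of each feature alone yet a deterministic
#' function of the pair. Features are emitted as real-valued 0/1 columns so
#' every dependence measure applies without a categorical code path.
#'
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A list with `X` (`n x 2`) and `y` in `{0, 1}`.
#' @export
simulate_xor <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_seed(variant_seed(seed, "xor"), {
    X <- matrix(stats::rbinom(n * 2L, 1L, 0.5), nrow = n, ncol = 2L)
    finish_sim(X, X[, 1L] * (1 - X[, 2L]) + X[, 2L] * (1 - X[, 1L]), "xor")
  })
}

#' Concept-drift process: 50 features with time-varying coefficients
#'
#' `y = x1 + x2 + (1 + t/10) x3 + (1 - t/10) x4 + sum_{i>=5} x_i`, with
#' `x1..x4 ~ N(0, 4)` and `x5..x50 ~ N(0, 0.05)` (variance parameterisation
#' by default, see `param`). As `t` runs from 0 to 10 the influence of `x3`
#' grows and that of `x4` decays to zero; the response is an exact linear
#' function of the features at every `t`.
#'
#' @param n Sample size.
#' @param t Non-negative temporal increment.
#' @param seed Integer seed.
#' @param param `"variance"` (default) reads `N(0, v)` as variance `v`;
#'   `"sd"` reads it as standard deviation, for sensitivity checks.
#' @return A list with `X` (`n x 50`) and `y`.
#' @export
simulate_drift <- function(n, t = 0, seed = 1L,
                           param = c("variance", "sd")) {
  stopifnot(n >= 1)
  if (t < 0) stop("t must be non-negative")
  param <- match.arg(param)
  sd_big <- if (param == "variance") 2 else 4
  sd_small <- if (param == "variance") sqrt(0.05) else 0.05
  with_seed(variant_seed(seed, "drift"), {
    X <- cbind(matrix(stats::rnorm(n * 4L, 0, sd_big), nrow = n),
               matrix(stats::rnorm(n * 46L, 0, sd_small), nrow = n))
    beta <- c(1, 1, 1 + t / 10, 1 - t / 10, rep(1, 46L))
    finish_sim(X, X %*% beta, "drift")
  })
}

#' Three-way interaction process for misspecification diagnostics
#'
#' `y = x1 + x2 + 5 x3 x4 x5 + eps` with `x1, x2, x3 ~ N(0, 1)` continuous,
#' `x4, x5 ~ Bernoulli(1/2)` binary and `eps ~ N(0, noise_var)` a small
#' error. The effect of `x3` is gated by `x4` and `x5`: it contributes only
#' on the quarter of rows where both are 1, which a main-effects linear
#' model cannot represent.
#'
#' @param n Sample size.
#' @param noise_sd Standard deviation of the error; default `sqrt(0.1)`,
#'   reading the nominal `N(0, 0.1)` as variance 0.1 (see `param` of
#'   [simulate_drift()] for the convention).
#' @param seed Integer seed.
#' @return A list with `X` (`n x 5`) and `y`.
#' @export
simulate_interaction <- function(n, noise_sd = sqrt(0.1), seed = 1L) {
  stopifnot(n >= 1, noise_sd > 0)
  with_seed(variant_seed(seed, "interaction"), {
    X <- cbind(matrix(stats::rnorm(n * 3L), nrow = n),
               matrix(stats::rbinom(n * 2L, 1L, 0.5), nrow = n))
    eps <- stats::rnorm(n, 0, noise_sd)
    finish_sim(X, X[, 1L] + X[, 2L] + 5 * X[, 3L] * X[, 4L] * X[, 5L] + eps,
               "interaction")
  })
}

#' Dispatch a simulator by variant name
#'
#' @param variant One of `"quadratic"`, `"xor"`, `"drift"`, `"interaction"`.
#' @param n Sample size.
#' @param seed Integer seed.
#' @param ... Variant-specific parameters (`a`, `t`, `noise_sd`, `param`).
#' @return A list with `X` and `y`; see the individual generators.
#' @export
simulate_dgp <- function(variant = c("quadratic", "xor", "drift",
                                     "interaction"),
                         n, seed = 1L, ...) {
  variant <- match.arg(variant)
  switch(variant,
         quadratic = simulate_quadratic(n, seed = seed, ...),
         xor = simulate_xor(n, seed = seed, ...),
         drift = simulate_drift(n, seed = seed, ...),
         interaction = simulate_interaction(n, seed = seed, ...))
}
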