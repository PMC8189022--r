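#' @title Empirical non-linear dependence measures
#' @description Distance correlation, affine-invariant distance correlation,
#'   Hilbert-Schmidt independence criterion and multiple-correlation R^2,
#'   with characteristic-function wrappers for Shapley decomposition.
#' @name dependence
NULL

as_data_matrix <- function(W, what = "input") {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (nrow(W) < 2L) stop(sprintf("%s must have at least 2 rows", what))
  if (!all(is.finite(W))) {
    bad <- which(!is.finite(W), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s has a non-finite value at row %d, column %d",
                 what, bad[1L], bad[2L]))
  }
  W
}

# Row-block size keeping each block x n kernel slab around 80 MB.
dist_block_rows <- function(n) max(256L, min(n, as.integer(1e7 / n)))

#' Pairwise Euclidean distance matrix
#'
#' @param W Numeric matrix (observations in rows) or vector (one column).
#' @return An `n x n` symmetric matrix of pairwise Euclidean distances with
#'   zero diagonal.
#' @export
pairwise_distance_matrix <- function(W) {
  W <- as_data_matrix(W, "W")
  B <- as.matrix(stats::dist(W))
  dimnames(B) <- NULL
  B
}

#' Double-centre a distance matrix
#'
#' Subtracts each row mean and column mean and adds back the grand mean, so
#' every row and column of the result sums to zero. This is the centring used
#' by the empirical distance covariance.
#'
#' @param B An `n x n` distance matrix.
#' @return The centred matrix.
#' @export
double_center <- function(B) {
  B <- as.matrix(B)
  rm <- rowMeans(B)
  cm <- colMeans(B)
  B - outer(rm, rep(1, ncol(B))) - outer(rep(1, nrow(B)), cm) + mean(B)
}

# Shared engine: accumulates Sxy = sum(A(Y)*A(X)), Syy, Sxx with A(W) the
# double-centred distance matrix of W. Compiled with O(n) memory: distances
# are recomputed pair by pair rather than materialised as n x n matrices,
# so n = 10,000 runs in seconds without large allocations.
dcov_sums <- function(Y, X) .dcov_sums_cpp(Y, X)

check_aligned <- function(Y, X) {
  if (nrow(Y) != nrow(X)) {
    stop(sprintf("row-count mismatch: Y has %d rows, X has %d",
                 nrow(Y), nrow(X)))
  }
}

#' Empirical (squared) distance covariance
#'
#' The raw double-centred sum `sum_ij A(Y)_ij A(X)_ij`, a V-statistic. Note
#' this deliberately carries no `1/n^2` factor: the scaling cancels in the
#' distance-correlation ratio, which is the quantity the package decomposes.
#' Conventional implementations divide by `n^2`; multiply accordingly when
#' comparing.
#'
#' @param Y,X Numeric matrices or vectors with equal row counts.
#' @return A non-negative scalar (up to floating-point round-off).
#' @export
dcov2 <- function(Y, X) {
  Y <- as_data_matrix(Y, "Y"); X <- as_data_matrix(X, "X")
  check_aligned(Y, X)
  dcov_sums(Y, X)$sxy
}

#' Empirical distance correlation
#'
#' The ratio of the distance covariance of `(Y, X)` to the geometric mean of
#' the two distance variances; zero by convention when either distance
#' variance vanishes (e.g. a constant input). Lies in `[0, 1]`, equalling 1
#' only under an exact linear relationship of equal-dimension supports.
#'
#' @param Y,X Numeric matrices or vectors with equal row counts.
#' @param squared If `TRUE` return the squared correlation; the default is
#'   the unsquared root, the scale on which the package reports attributions.
#' @return A scalar in `[0, 1]`.
#' @export
dcor <- function(Y, X, squared = FALSE) {
  Y <- as_data_matrix(Y, "Y"); X <- as_data_matrix(X, "X")
  check_aligned(Y, X)
  s <- dcov_sums(Y, X)
  denom <- s$syy * s$sxx
  if (denom <= 0) return(0)
  r2 <- s$sxy / sqrt(denom)
  r2 <- min(max(r2, 0), 1)
  if (squared) r2 else sqrt(r2)
}

# Inverse symmetric square root of the sample covariance of W.
whiten <- function(W, what = "W") {
  S <- stats::cov(W)
  e <- eigen(S, symmetric = TRUE)
  tol <- 1e-12 * max(abs(e$values), 1e-300)
  if (min(e$values) <= tol) {
    stop(sprintf(paste0(
      "sample covariance of %s is singular (rank-deficient block); ",
      "remove constant or linearly dependent columns"), what))
  }
  W %*% e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Affine-invariant distance correlation
#'
#' Whitens `Y` and `X` by the inverse symmetric square roots of their sample
#' covariance matrices before computing the distance correlation, making the
#' statistic invariant under invertible affine transformations of either
#' block. Singular covariance (a constant or duplicated column) is an error,
#' not a silent pseudo-inverse.
#'
#' @inheritParams dcor
#' @return A scalar in `[0, 1]`.
#' @export
aidc <- function(Y, X, squared = FALSE) {
  Y <- as_data_matrix(Y, "Y"); X <- as_data_matrix(X, "X")
  check_aligned(Y, X)
  dcor(whiten(Y, "Y"), whiten(X, "X"), squared = squared)
}

#' Median-heuristic Gaussian bandwidth
#'
#' The median of the `n(n-1)/2` pairwise Euclidean distances. If the median
#' is 0 (heavily tied data) the mean of the strictly positive distances is
#' used; if every distance is 0 (constant data) the bandwidth is 1, under
#' which the kernel matrix is all-ones and the HSIC vanishes regardless.
#'
#' @param W Numeric matrix or vector.
#' @return A strictly positive bandwidth.
#' @export
median_bandwidth <- function(W) {
  W <- as_data_matrix(W, "W")
  dv <- as.numeric(stats::dist(W))
  med <- stats::median(dv)
  if (med > 0) return(med)
  pos <- dv[dv > 0]
  if (length(pos) > 0) return(mean(pos))
  1
}

#' Gaussian kernel specification for the HSIC
#'
#' @param bandwidth_rule `"median_heuristic"` (default; bandwidths computed
#'   separately for each input from its own pairwise distances) or `"fixed"`.
#' @param bandwidth Positive bandwidth, required when `bandwidth_rule` is
#'   `"fixed"`; applied to both inputs.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(bandwidth_rule = c("median_heuristic", "fixed"),
                        bandwidth = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (bandwidth_rule == "fixed") {
    if (is.null(bandwidth) || !is.numeric(bandwidth) || bandwidth <= 0) {
      stop("a positive bandwidth is required when bandwidth_rule = \"fixed\"")
    }
  }
  structure(list(family = "gaussian", bandwidth_rule = bandwidth_rule,
                 bandwidth = bandwidth),
            class = "kernel_spec")
}

kernel_bandwidth <- function(W, kernel) {
  if (kernel$bandwidth_rule == "fixed") kernel$bandwidth else median_bandwidth(W)
}

gauss_kernel_block <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Empirical Hilbert-Schmidt independence criterion
#'
#' The three-term Gaussian-kernel V-statistic
#' `(1/n^2) sum_ij k_ij l_ij + (1/n^4) sum_ij k_ij sum_qr l_qr
#'  - (2/n^3) sum_i (sum_j k_ij)(sum_q l_iq)`,
#' with `K` built from `X` and `L` from `Y` and bandwidths chosen per
#' `kernel` (median heuristic by default, separately for each input).
#'
#' @inheritParams dcor
#' @param kernel A [kernel_spec()].
#' @return A non-negative scalar (up to round-off of order 1e-12).
#' @export
hsic <- function(Y, X, kernel = kernel_spec()) {
  Y <- as_data_matrix(Y, "Y"); X <- as_data_matrix(X, "X")
  check_aligned(Y, X)
  stopifnot(inherits(kernel, "kernel_spec"))
  n <- nrow(Y)
  sy <- kernel_bandwidth(Y, kernel)
  sx <- kernel_bandwidth(X, kernel)
  blk <- dist_block_rows(n)
  skl <- sk <- sl <- 0
  cross <- 0
  for (s in seq(1L, n, by = blk)) {
    I <- s:min(s + blk - 1L, n)
    K <- gauss_kernel_block(X[I, , drop = FALSE], X, sx)
    L <- gauss_kernel_block(Y[I, , drop = FALSE], Y, sy)
    skl <- skl + sum(K * L)
    kr <- rowSums(K); lr <- rowSums(L)
    sk <- sk + sum(kr); sl <- sl + sum(lr)
    cross <- cross + sum(kr * lr)
  }
  skl / n^2 + (sk * sl) / n^4 - 2 * cross / n^3
}

#' Coefficient of multiple correlation (R-squared)
#'
#' `1 - det(rho(y, X_S)) / det(rho(X_S))` with `rho` the empirical Pearson
#' correlation matrix; equals the OLS coefficient of determination of `y`
#' regressed on the columns of `XS`. Measures only linear dependence.
#'
#' @param y Single-column response.
#' @param XS Feature matrix (the subset under evaluation).
#' @return A scalar in `[0, 1]` (clipped against round-off).
#' @export
r2_multiple <- function(y, XS) {
  y <- as_data_matrix(y, "y")
  if (ncol(y) != 1L) stop("y must be a single column")
  XS <- as_data_matrix(XS, "XS")
  check_aligned(y, XS)
  Z <- cbind(y, XS)
  sds <- apply(Z, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate input: column %d of (y, XS) has zero variance",
                 which(sds == 0)[1L]))
  }
  rho_full <- stats::cor(Z)
  rho_x <- rho_full[-1L, -1L, drop = FALSE]
  det_x <- det(rho_x)
  if (abs(det_x) < 1e-12) {
    stop("degenerate input: correlation matrix of XS is (near) singular")
  }
  min(max(1 - det(rho_full) / det_x, 0), 1)
}

measure_names <- c("dcor", "dcor_squared", "aidc", "aidc_squared",
                   "hsic", "r2")

measure_fun <- function(measure, kernel = NULL) {
  measure <- match.arg(measure, measure_names)
  switch(measure,
    dcor = function(y, XS) dcor(y, XS, squared = FALSE),
    dcor_squared = function(y, XS) dcor(y, XS, squared = TRUE),
    aidc = function(y, XS) aidc(y, XS, squared = FALSE),
    aidc_squared = function(y, XS) aidc(y, XS, squared = TRUE),
    hsic = {
      k <- if (is.null(kernel)) kernel_spec() else kernel
      function(y, XS) hsic(y, XS, kernel = k)
    },
    r2 = function(y, XS) r2_multiple(y, XS)
  )
}

#' Build a dependence game from data
#'
#' Wraps a dependence measure into a characteristic function over feature
#' subsets: `C(S)` is the measure between the label column `y` and the
#' columns of `X` indexed by `S`, with `C(empty) = 0`. Evaluations are lazy
#' and memoised, so an exact Shapley decomposition touches each of the `2^d`
#' subsets once.
#'
#' @param measure One of `"dcor"`, `"dcor_squared"`, `"aidc"`,
#'   `"aidc_squared"`, `"hsic"`, `"r2"`. Unsquared distance correlation is
#'   the default reporting scale throughout the package.
#' @param y Single-column label (or prediction / residual) vector.
#' @param X Feature matrix with `d >= 1` columns.
#' @param kernel Optional [kernel_spec()] for `measure = "hsic"`.
#' @return A [char_fun()] over `d = ncol(X)` players.
#' @export
make_characteristic <- function(measure, y, X, kernel = NULL) {
  y <- as_data_matrix(y, "y")
  if (ncol(y) != 1L) stop("y must be a single column")
  X <- as_data_matrix(X, "X")
  check_aligned(y, X)
  f <- measure_fun(measure, kernel)
  char_fun(function(S) {
    tryCatch(f(y, X[, S, drop = FALSE]),
             error = function(e) {
               stop(sprintf("measure failed on subset {%s}: %s",
                            paste(S, collapse = ","), conditionMessage(e)),
                    call. = FALSE)
             })
  }, d = ncol(X))
}
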