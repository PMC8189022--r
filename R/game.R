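#' Construct a characteristic function (cooperative game)
#'
#' A characteristic function maps a coalition of players -- here, a subset of
#' feature indices -- to a real payoff. By convention the empty coalition
#' always receives payoff 0, so the efficiency axiom reads "the Shapley values
#' sum to the payoff of the full feature set". Subset evaluations are memoised
#' so an exact decomposition over `d` features costs `2^d` distinct
#' evaluations rather than `d * 2^(d-1)`.
#'
#' @param fun Function of one argument, an integer vector of 1-based player
#'   indices (never empty), returning a single finite numeric payoff.
#' @param d Number of players (ground-set size), a positive integer.
#' @param memoize Cache payoffs keyed by the sorted subset (default `TRUE`).
#'   Requires `fun` to be deterministic for a fixed subset.
#' @return An object of class `char_fun` with elements `d`, `fun` and the
#'   memo environment.
#' @seealso [cf_eval()], [shapley_exact()], [make_characteristic()]
#' @examples
#' C <- char_fun(function(S) length(S), d = 3)
#' cf_eval(C, c(1, 3))
#' @export
char_fun <- function(fun, d, memoize = TRUE) {
  stopifnot(is.function(fun), length(d) == 1L, d >= 1, d == as.integer(d))
  structure(
    list(fun = fun, d = as.integer(d), memoize = isTRUE(memoize),
         cache = new.env(parent = emptyenv())),
    class = "char_fun"
  )
}

#' Evaluate a characteristic function on a feature subset
#'
#' @param C A [char_fun()] object.
#' @param S Integer vector of distinct player indices in `1:C$d`; may be
#'   empty, in which case the payoff is 0 by convention.
#' @return A single numeric payoff.
#' @export
cf_eval <- function(C, S) {
  stopifnot(inherits(C, "char_fun"))
  S <- as.integer(S)
  if (length(S) == 0L) return(0)
  if (anyDuplicated(S)) stop("subset contains duplicate indices")
  if (any(S < 1L) || any(S > C$d)) {
    stop(sprintf("subset indices must lie in 1..%d", C$d))
  }
  S <- sort(S)
  if (C$memoize) {
    key <- paste(S, collapse = ",")
    if (!is.null(v <- C$cache[[key]])) return(v)
    v <- C$fun(S)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("characteristic function returned a non-finite payoff on subset {%s}",
                   paste(S, collapse = ",")))
    }
    C$cache[[key]] <- v
    return(v)
  }
  C$fun(S)
}

#' Number of distinct subsets a characteristic function has evaluated
#' @param C A [char_fun()] object.
#' @return Integer count of cached non-empty subsets, plus one for the empty
#'   coalition (whose payoff is fixed at 0).
#' @keywords internal
cf_n_cached <- function(C) length(ls(C$cache)) + 1L

#' Marginal contribution of a player to a coalition
#'
#' Returns `C(S + {v}) - C(S)`, the payoff gain from adding player `v` to the
#' coalition `S`.
#'
#' @param C A [char_fun()] object.
#' @param S Integer vector, coalition excluding `v` (possibly empty).
#' @param v Single player index, not already in `S`.
#' @return A single numeric marginal contribution.
#' @export
marginal_contribution <- function(C, S, v) {
  v <- as.integer(v)
  stopifnot(length(v) == 1L)
  if (v %in% S) stop(sprintf("player %d is already in the coalition", v))
  if (v < 1L || v > C$d) stop(sprintf("player index %d outside 1..%d", v, C$d))
  cf_eval(C, c(S, v)) - cf_eval(C, S)
}

new_shapley_decomposition <- function(values, payoff_full, method,
                                      n_evaluations, n_permutations = NULL,
                                      seed = NULL) {
  structure(
    list(values = values, payoff_full = payoff_full, method = method,
         n_evaluations = n_evaluations, n_permutations = n_permutations,
         seed = seed),
    class = "shapley_decomposition"
  )
}

#' @export
print.shapley_decomposition <- function(x, ...) {
  cat(sprintf("Shapley decomposition (%s), d = %d\n", x$method,
              length(x$values)))
  print(round(x$values, 6))
  cat(sprintf("full-coalition payoff: %.6g  (sum of values: %.6g)\n",
              x$payoff_full, sum(x$values)))
  cat(sprintf("characteristic evaluations: %d", x$n_evaluations))
  if (!is.null(x$n_permutations)) {
    cat(sprintf("; permutations: %d", x$n_permutations))
  }
  cat("\n")
  invisible(x)
}

#' Exact Shapley decomposition by power-set enumeration
#'
#' Computes the exact Shapley value of every player: the average over all
#' coalition sizes `k` of the mean marginal contribution of the player to
#' coalitions of size `k` that exclude it. All `2^d` subsets are evaluated
#' once (memoised), so the cost is exponential in `d`; a configurable cap
#' fails fast instead of hanging.
#'
#' @param C A [char_fun()] object.
#' @param cap Maximum `d` for exact enumeration (default 20).
#' @return A `shapley_decomposition` with `method = "exact"`. The values sum
#'   to the full-coalition payoff (efficiency).
#' @examples
#' C <- char_fun(function(S) length(S), d = 3)
#' shapley_exact(C)$values  # (1, 1, 1)
#' @export
shapley_exact <- function(C, cap = 20L) {
  stopifnot(inherits(C, "char_fun"))
  d <- C$d
  if (d > cap) {
    stop(sprintf(paste0(
      "d = %d exceeds the exact-enumeration cap (%d): 2^d subset ",
      "evaluations would be required. Use shapley_mc() or, when features ",
      "partition into independent blocks, shapley_blocks()."), d, cap))
  }
  n_sub <- bitwShiftL(1L, d)
  masks <- 0:(n_sub - 1L)
  popcnt <- integer(n_sub)
  for (v in seq_len(d)) {
    popcnt <- popcnt + (bitwAnd(masks, bitwShiftL(1L, v - 1L)) > 0L)
  }
  payoff <- numeric(n_sub)
  for (m in masks[-1L]) {
    payoff[m + 1L] <- cf_eval(C, which(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) > 0L))
  }
  values <- numeric(d)
  for (v in seq_len(d)) {
    bit <- bitwShiftL(1L, v - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    k <- popcnt[without + 1L]
    w <- 1 / (d * choose(d - 1L, k))
    values[v] <- sum(w * (payoff[without + bit + 1L] - payoff[without + 1L]))
  }
  new_shapley_decomposition(values, payoff[n_sub], "exact",
                            n_evaluations = n_sub)
}

#' Monte Carlo Shapley decomposition by permutation sampling
#'
#' Samples `m` uniformly random orderings of the players; for each ordering
#' every player's marginal contribution to its set of predecessors is
#' accumulated, and the per-player means estimate the Shapley values. A
#' consistent estimator as `m` grows; reproducible given `seed`.
#'
#' @param C A [char_fun()] object.
#' @param m Number of permutations, at least 1.
#' @param seed Integer seed for the permutation stream.
#' @return A `shapley_decomposition` with `method = "monte_carlo"` and
#'   `n_permutations = m`.
#' @export
shapley_mc <- function(C, m, seed = 1L) {
  stopifnot(inherits(C, "char_fun"))
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("m must be a positive permutation count")
  }
  m <- as.integer(m)
  d <- C$d
  totals <- numeric(d)
  with_seed(seed, {
    for (r in seq_len(m)) {
      perm <- sample.int(d)
      prev <- 0
      S <- integer(0)
      for (v in perm) {
        cur <- cf_eval(C, c(S, v))
        totals[v] <- totals[v] + (cur - prev)
        prev <- cur
        S <- c(S, v)
      }
    }
  })
  new_shapley_decomposition(totals / m, cf_eval(C, seq_len(d)), "monte_carlo",
                            n_evaluations = cf_n_cached(C),
                            n_permutations = m, seed = seed)
}

#' Blockwise Shapley decomposition under cross-block independence
#'
#' When the features partition into blocks that are mutually independent (an
#' assumption the caller asserts; it is not checked from data), the global
#' decomposition factorises: each block's game is decomposed exactly on its
#' own, and the per-block values are assembled into the global index order.
#' Three blocks of five features cost `3 * 2^5 = 96` subset evaluations (240
#' within-block marginal contributions) instead of `2^15 = 32768`.
#'
#' @param block_games List of [char_fun()] objects, one per block; the i-th
#'   game must be the dependence game restricted to the i-th block's features
#'   (indexed `1..length(blocks[[i]])` within the block).
#' @param blocks List of integer vectors partitioning `1:d` (global indices).
#' @param cap Passed to [shapley_exact()] per block.
#' @return A `shapley_decomposition` with `method = "blockwise"`;
#'   `payoff_full` is the sum of the block full-coalition payoffs and
#'   `n_evaluations` the sum of `2^{|block|}`.
#' @export
shapley_blocks <- function(block_games, blocks, cap = 20L) {
  stopifnot(is.list(block_games), is.list(blocks),
            length(block_games) == length(blocks))
  idx <- unlist(blocks)
  d <- length(idx)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(d))) {
    stop("blocks must form a partition of 1..d (no overlap, no gaps)")
  }
  for (i in seq_along(blocks)) {
    if (block_games[[i]]$d != length(blocks[[i]])) {
      stop(sprintf("block %d game has d = %d but the block holds %d features",
                   i, block_games[[i]]$d, length(blocks[[i]])))
    }
  }
  values <- numeric(d)
  payoff_full <- 0
  n_eval <- 0L
  for (i in seq_along(blocks)) {
    dec <- shapley_exact(block_games[[i]], cap = cap)
    values[blocks[[i]]] <- dec$values
    payoff_full <- payoff_full + dec$payoff_full
    n_eval <- n_eval + dec$n_evaluations
  }
  new_shapley_decomposition(values, payoff_full, "blockwise",
                            n_evaluations = n_eval)
}

#' Evaluation-count arithmetic for exact decompositions
#'
#' @param d Number of features, at least 1.
#' @param mode `"subsets"` for the number of distinct characteristic-function
#'   evaluations (`2^d`, the cost of a memoised exact decomposition) or
#'   `"marginal_contributions"` for the number of distinct marginal
#'   contributions (`d * 2^(d-1)`).
#' @return A count (numeric, exact for `d` up to 50).
#' @examples
#' count_evaluations(5, "marginal_contributions")  # 80
#' count_evaluations(15, "subsets")                # 32768
#' @export
count_evaluations <- function(d, mode = c("subsets", "marginal_contributions")) {
  mode <- match.arg(mode)
  stopifnot(length(d) == 1L, d >= 1, d == as.integer(d))
  switch(mode,
         subsets = 2^d,
         marginal_contributions = d * 2^(d - 1))
}

#' Normalise a Shapley decomposition by its full-coalition payoff
#'
#' Rescales the values so they sum to 1 (for exact decompositions), making
#' decompositions of different dependence measures comparable on one axis.
#'
#' @param dec A `shapley_decomposition`.
#' @return Numeric vector `dec$values / dec$payoff_full`.
#' @export
normalize_decomposition <- function(dec) {
  stopifnot(inherits(dec, "shapley_decomposition"))
  if (dec$payoff_full == 0) {
    stop("degenerate game: full-coalition payoff is 0, cannot normalise")
  }
  dec$values / dec$payoff_full
}

# Run code under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
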