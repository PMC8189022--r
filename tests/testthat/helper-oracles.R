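# Independent oracles, written as plain double loops / full enumeration so
# they share no code path with the package implementation.

# Conventional (1/n^2-scaled) squared distance covariance, by explicit loops.
naive_dcov2_conventional <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  By <- matrix(0, n, n); Bx <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    By[i, j] <- sqrt(sum((Y[i, ] - Y[j, ])^2))
    Bx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  center <- function(B) {
    A <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      A[i, j] <- B[i, j] - mean(B[i, ]) - mean(B[, j]) + mean(B)
    }
    A
  }
  Ay <- center(By); Ax <- center(Bx)
  sum(Ay * Ax) / n^2
}

naive_dcor <- function(Y, X) {
  num <- naive_dcov2_conventional(Y, X)
  den <- naive_dcov2_conventional(Y, Y) * naive_dcov2_conventional(X, X)
  if (den <= 0) return(0)
  sqrt(max(num, 0) / sqrt(den))
}

# All permutations of 1:d (d small).
all_perms <- function(d) {
  if (d == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(d - 1L)) {
    for (pos in 0:(d - 1L)) {
      out[[length(out) + 1L]] <- append(p, d, after = pos)
    }
  }
  out
}

# Shapley values as the average over all d! orderings of each player's
# marginal contribution to its predecessors.
permutation_shapley <- function(C) {
  d <- C$d
  perms <- all_perms(d)
  vals <- numeric(d)
  for (perm in perms) {
    prev <- 0
    S <- integer(0)
    for (v in perm) {
      cur <- cf_eval(C, c(S, v))
      vals[v] <- vals[v] + (cur - prev)
      prev <- cur
      S <- c(S, v)
    }
  }
  vals / length(perms)
}

# A game with arbitrary fixed payoffs drawn once from a seeded stream.
random_game <- function(d, seed) {
  set.seed(seed)
  payoff <- c(0, stats::runif(2^d - 1L, -1, 1))
  char_fun(function(S) {
    payoff[sum(2^(S - 1L)) + 1L]
  }, d = d)
}

# The XOR payoff game implied by the pairwise zeros and the full-set value.
xor_payoff_game <- function(full = 0.53) {
  char_fun(function(S) if (length(S) == 2L) full else 0, d = 2L)
}

# Balanced replication of the four XOR support points.
xor_support <- function(k = 25L) {
  X <- do.call(rbind, replicate(
    k, matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE),
    simplify = FALSE))
  list(X = X, y = (X[, 1] + X[, 2]) %% 2)
}

# Closed-form population XOR distance correlation (exact enumeration).
xor_population_dcor <- function() sqrt((sqrt(2) - 1) / sqrt(5 - 2 * sqrt(2)))

# HSIC via the centred-trace identity (1/n^2) tr(K H L H), H = I - J/n.
naive_hsic_trace <- function(K, L) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  sum(diag(K %*% H %*% L %*% H)) / n^2
}

gaussian_gram <- function(W, sigma) {
  W <- as.matrix(W)
  n <- nrow(W)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- exp(-sum((W[i, ] - W[j, ])^2) / (2 * sigma^2))
  }
  K
}
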