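# Independent oracles used to cross-check the package implementations.
# Deliberately coded with different algorithms/styles than the package paths.

# Minimum l1 norm of any solution to A z = y, by exhaustively enumerating
# candidate supports and solving each restricted least-squares system.
oracle_l1_min <- function(A, y) {
  n <- ncol(A)
  m <- nrow(A)
  best <- Inf
  yscale <- max(1, max(abs(y)))
  if (max(abs(y)) < 1e-12) return(0)
  for (s in seq_len(min(n, m))) {
    for (S in utils::combn(n, s, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      z <- tryCatch(qr.solve(As, y), error = function(e) NULL)
      if (is.null(z)) next
      if (max(abs(As %*% z - y)) < 1e-7 * yscale) best <- min(best, sum(abs(z)))
    }
  }
  best
}

# Brute-force expansion slack: neighbor sets built as explicit index lists
# and unioned, instead of the package's rowSums counting.
oracle_epsilon <- function(mat, k) {
  n <- ncol(mat)
  d <- sum(mat[, 1])
  supports <- lapply(seq_len(n), function(j) which(mat[, j] == 1))
  worst <- 1
  for (s in seq_len(k)) {
    for (S in utils::combn(n, s, simplify = FALSE)) {
      nb <- length(unique(unlist(supports[S])))
      worst <- min(worst, nb / (d * s))
    }
  }
  1 - worst
}

# The reference paper-scale design used across tests: 12 pools x 15 samples,
# left degree 2. Its column supports are pairwise distinct by construction,
# which certifies it as a (2, 1/4) expander.
ref_design <- function() build_design(n_samples = 15, n_pools = 12,
                                      left_degree = 2, seed = 7)

# Hand-built design from explicit column supports (pools x samples).
design_from_supports <- function(n_pools, supports) {
  m <- matrix(0L, n_pools, length(supports))
  for (j in seq_along(supports)) m[supports[[j]], j] <- 1L
  dimnames(m) <- list(paste0("P", seq_len(n_pools)),
                      paste0("S", seq_along(supports)))
  smartpool:::new_pooling_design(m, left_degree = length(supports[[1]]))
}
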