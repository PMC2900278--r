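# Dense two-phase primal simplex for the small linear programs produced by the
# l1 decoder:  minimize cost'x  subject to  A x = b, x >= 0.
#
# Problems here are tiny (tens of rows/columns) but often degenerate: pooled
# measurement vectors contain exact zeros, so many basic variables sit at zero.
# Bland's smallest-index rule is used throughout, which guarantees termination
# without the numerical fragility of big-M formulations at microarray
# intensity scales (~1e4). Phase 1 starts from an all-artificial basis;
# leftover artificials are driven out and redundant rows dropped, so rank-
# deficient designs (linearly dependent pools) are handled.

lp_standard <- function(A, b, cost, tol = 1e-9, max_iter = 100000L) {
  stopifnot(is.matrix(A), nrow(A) == length(b), ncol(A) == length(cost))
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  scale <- max(1, abs(b))

  pivot <- function(tab, basis, r, j) {
    tab[r, ] <- tab[r, ] / tab[r, j]
    other <- setdiff(seq_len(nrow(tab)), r)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[r, ])
    basis[r] <- j
    # snap basic columns to exact unit vectors to stop drift accumulating
    tab[, basis] <- 0
    tab[cbind(seq_len(nrow(tab)), basis)] <- 1
    list(tab = tab, basis = basis)
  }

  iterate <- function(tab, basis, cobj, ncols) {
    rhs_col <- ncol(tab)
    for (it in seq_len(max_iter)) {
      cb <- cobj[basis]
      red <- cobj[seq_len(ncols)] -
        as.vector(crossprod(tab[, seq_len(ncols), drop = FALSE], cb))
      red[basis] <- 0
      improving <- which(red < -tol * max(1, abs(cobj[seq_len(ncols)])))
      if (!length(improving)) {
        return(list(status = "optimal", tab = tab, basis = basis))
      }
      j <- improving[1L] # Bland: smallest entering index
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(status = "unbounded", tab = tab, basis = basis))
      }
      ratio <- tab[pos, rhs_col] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol * scale]
      r <- cand[which.min(basis[cand])] # Bland: smallest leaving basis index
      step <- pivot(tab, basis, r, j)
      tab <- step$tab
      basis <- step$basis
    }
    list(status = "maxiter", tab = tab, basis = basis)
  }

  # phase 1: minimize sum of artificials
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  ph1 <- iterate(tab, basis, c(rep(0, n), rep(1, m)), n + m)
  if (ph1$status != "optimal") {
    return(list(status = ph1$status, x = NULL, value = NA_real_))
  }
  tab <- ph1$tab
  basis <- ph1$basis
  infeas <- sum(tab[basis > n, ncol(tab)])
  if (infeas > 1e-7 * scale) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }

  # drive remaining (zero-valued) artificials out of the basis; an all-zero
  # row means the original constraint was redundant and is dropped
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    j <- which(abs(tab[r, seq_len(n)]) > tol)
    if (length(j)) {
      step <- pivot(tab, basis, r, j[1L])
      tab <- step$tab
      basis <- step$basis
    } else {
      drop_rows <- c(drop_rows, r)
    }
  }
  if (length(drop_rows)) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  # phase 2 over the original columns only
  tab2 <- tab[, c(seq_len(n), ncol(tab)), drop = FALSE]
  ph2 <- iterate(tab2, basis, cost, n)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  }
  x <- numeric(n)
  x[ph2$basis] <- ph2$tab[, ncol(ph2$tab)]
  x[x < 0 & x > -tol * scale] <- 0
  list(status = "optimal", x = x, value = sum(cost * x))
}
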