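#' Options controlling the l1 decoder
#'
#' @param nonnegative constrain the decoded profile to `x >= 0`. Off by
#'   default: the basis-pursuit program imposes only measurement consistency
#'   and minimal l1 norm, and down-spikes below the baseline are legitimate.
#' @param noise_tolerance relaxation `delta >= 0`. With `delta = 0` the
#'   decoder solves the equality-constrained program `min ||z||_1` subject to
#'   `Phi z = y`; with `delta > 0` the constraint relaxes to
#'   `sum |Phi z - y| <= delta` for noisy measurements.
#' @param solver_tolerance feasibility/optimality tolerance used to judge the
#'   returned solution; must be positive.
#' @param scale declared scale of the incoming measurements. `"log2"` inputs
#'   are exponentiated (base 2) before decoding, since pooling is additive in
#'   linear intensity; results are then reported in both scales by
#'   [decode_matrix()].
#' @param center_baseline estimate a shared baseline from the measurements
#'   (see [estimate_baseline()]), decode the median-centered residual
#'   profile, and add the baseline back. Needed for exact recovery of
#'   near-constant profiles whose sparsity is about the median rather than
#'   about zero; off by default so the raw program matches the classic
#'   equality-constrained decoder.
#' @return A `decode_options` list.
#' @export
decode_options <- function(nonnegative = FALSE, noise_tolerance = 0,
                           solver_tolerance = 1e-8,
                           scale = c("linear", "log2"),
                           center_baseline = FALSE) {
  scale <- match.arg(scale)
  if (!is.numeric(noise_tolerance) || noise_tolerance < 0) {
    stop_("noise_tolerance (delta) must be >= 0")
  }
  if (!is.numeric(solver_tolerance) || solver_tolerance <= 0) {
    stop_("solver_tolerance must be > 0")
  }
  structure(
    list(
      nonnegative = isTRUE(nonnegative),
      noise_tolerance = noise_tolerance,
      solver_tolerance = solver_tolerance,
      scale = scale,
      center_baseline = isTRUE(center_baseline)
    ),
    class = "decode_options"
  )
}

#' Pool a per-sample profile into measurements
#'
#' The forward operator of the pooled experiment: for one gene with
#' nonnegative per-sample intensities `x`, the pooled measurement vector is
#' `y = Phi x`, i.e. pool `i` reads the sum of the intensities of the samples
#' it contains. Optional `weights` replace the binary entries (e.g. a
#' row-normalized design modelling equal total mRNA mass per chip) but must
#' keep the design's zero pattern.
#'
#' @param profile nonnegative numeric vector of length `n_samples`.
#' @param design a [pooling_design].
#' @param weights optional numeric matrix, same shape as the design matrix,
#'   with zeros exactly where the design has zeros.
#' @return Named numeric vector of length `n_pools`.
#' @examples
#' d <- build_design(15, 12, 2, seed = 7)
#' y <- pool_profile(c(rep(0, 2), 1000, rep(0, 12)), d)
#' which(y > 0) # the two pools containing sample 3
#' @export
pool_profile <- function(profile, design, weights = NULL) {
  stopifnot(inherits(design, "pooling_design"))
  if (!is.numeric(profile) || length(profile) != design$n_samples) {
    stop_("profile must be numeric of length n_samples = %d", design$n_samples)
  }
  if (any(!is.finite(profile))) stop_("profile entries must be finite")
  if (any(profile < 0)) stop_("profile entries must be nonnegative intensities")
  W <- design$matrix
  if (!is.null(weights)) {
    if (!is.matrix(weights) || !all(dim(weights) == dim(W))) {
      stop_("weights must be a matrix with the same shape as the design matrix")
    }
    if (!all((weights != 0) == (W == 1L))) {
      stop_("weights must be zero exactly where the design has zeros")
    }
    W <- weights
  }
  y <- as.vector(W %*% profile)
  names(y) <- design$pool_labels
  y
}

#' Shared-baseline estimate from pooled measurements
#'
#' For a near-constant profile `x = c * 1`, every pool reads
#' `y_i = c * rowsum_i`, so `c` is recovered as the (lower) median of the
#' per-pool ratios `y_i / rowsum_i`. With `k` spikes at left degree `d`, at
#' most `k * d` pools are perturbed, so the median ratio remains exactly the
#' baseline whenever the unperturbed pools are in the majority.
#'
#' @param y numeric measurement vector of length `n_pools`.
#' @param design a binary [pooling_design]; every row must contain at least
#'   one sample.
#' @return Scalar baseline estimate.
#' @export
estimate_baseline <- function(y, design) {
  stopifnot(inherits(design, "pooling_design"))
  if (length(y) != design$n_pools) {
    stop_("y must have length n_pools = %d", design$n_pools)
  }
  rs <- rowSums(design$matrix)
  if (any(rs == 0)) {
    stop_("design has an empty pool (zero row sum); baseline ratios undefined")
  }
  lower_median(y / rs)
}

# Assemble and solve the basis-pursuit LP in standard form.
# Layouts (all variables >= 0):
#   signed:            z = u - v, columns [Phi, -Phi]
#   nonnegative:       x = w,     columns [Phi]
#   nonneg + centered: z = p - q with q_j <= baseline (so x = baseline + z >= 0),
#                      enforced via q_j + t_j = baseline slack rows
# With delta > 0 the measurement rows gain a split residual r+ - r- and one
# budget row sum(r+ + r-) + s = delta.
l1_decode_lp <- function(Phi, y_target, nonnegative, baseline, delta, tol) {
  m <- nrow(Phi)
  n <- ncol(Phi)
  centered <- !is.null(baseline)
  if (nonnegative && centered) {
    Ax <- cbind(Phi, -Phi, matrix(0, m, n))
    cost <- c(rep(1, 2L * n), rep(0, n))
    extra <- cbind(matrix(0, n, n), diag(n), diag(n))
    extra_b <- rep(baseline, n)
  } else if (nonnegative) {
    Ax <- Phi
    cost <- rep(1, n)
    extra <- NULL
    extra_b <- NULL
  } else {
    Ax <- cbind(Phi, -Phi)
    cost <- rep(1, 2L * n)
    extra <- NULL
    extra_b <- NULL
  }
  nx <- ncol(Ax)
  if (delta > 0) {
    meas <- cbind(Ax, -diag(m), diag(m), 0)
    rows <- meas
    if (!is.null(extra)) {
      rows <- rbind(rows, cbind(extra, matrix(0, nrow(extra), 2L * m), 0))
    }
    rows <- rbind(rows, c(rep(0, nx), rep(1, 2L * m), 1))
    A <- rows
    b <- c(y_target, extra_b, delta)
    cost <- c(cost, rep(0, 2L * m), 0)
  } else {
    A <- if (is.null(extra)) Ax else rbind(Ax, extra)
    b <- c(y_target, extra_b)
  }
  sol <- lp_standard(A, b, cost, tol = tol)
  if (sol$status != "optimal") {
    return(list(status = sol$status, x = rep(NA_real_, n), objective = NA_real_))
  }
  x <- if (nonnegative && centered) {
    baseline + sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  } else if (nonnegative) {
    sol$x[seq_len(n)]
  } else {
    z <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
    if (centered) baseline + z else z
  }
  list(status = "optimal", x = x, objective = sol$value)
}

#' Decode one gene's profile from its pooled measurements
#'
#' Solves the basis-pursuit linear program
#' `min sum_j |z_j|` subject to `Phi z = y` (or `sum_i |Phi z - y|_i <= delta`
#' when `noise_tolerance > 0`), implemented by splitting `z` into nonnegative
#' positive and negative parts. The pooled system is underdetermined
#' (`m < n`); the l1 objective selects the sparsest-about-zero consistent
#' profile, which the expander certification guarantees is the true profile
#' for sufficiently sparse genes. Ties between optimal vertices are resolved
#' by the solver; the optimal l1 norm and residual are unique even when the
#' argmin is not.
#'
#' @param design a [pooling_design].
#' @param y measurement vector of length `n_pools` (scale per
#'   `options$scale`).
#' @param options a [decode_options()] list.
#' @return A `decode_result`: `x_hat` (named, linear scale), `l1_norm`
#'   (`sum |x_hat|`), `residual_l1` (`sum |Phi x_hat - y|`), `status`,
#'   `baseline` (NA unless centering was on), `objective` (the LP optimum).
#' @examples
#' d <- build_design(15, 12, 2, seed = 7)
#' x <- numeric(15); x[3] <- 1000
#' fit <- decode_profile(d, pool_profile(x, d))
#' max(abs(fit$x_hat - x)) < 1e-6
#' @export
decode_profile <- function(design, y, options = decode_options()) {
  stopifnot(inherits(design, "pooling_design"))
  if (!is.numeric(y) || length(y) != design$n_pools) {
    stop_("y must be numeric of length n_pools = %d", design$n_pools)
  }
  if (any(!is.finite(y))) stop_("measurement values must be finite")
  if (!inherits(options, "decode_options")) options <- do.call(decode_options, options)
  if (options$scale == "log2") y <- 2^y
  Phi <- design$matrix
  storage.mode(Phi) <- "double"
  baseline <- NULL
  if (options$center_baseline) {
    # empty pools (zero row sum) carry no baseline information; their y_i = 0
    # rows are still enforced by the LP, so only the ratio median skips them
    rs <- rowSums(design$matrix)
    if (all(rs == 0)) stop_("design has no nonempty pool; cannot center")
    baseline <- lower_median((y / rs)[rs > 0])
  }
  y_target <- if (is.null(baseline)) y else y - baseline * rowSums(Phi)
  fit <- l1_decode_lp(Phi, y_target,
                      nonnegative = options$nonnegative,
                      baseline = baseline,
                      delta = options$noise_tolerance,
                      tol = 1e-9)
  x_hat <- fit$x
  names(x_hat) <- design$sample_labels
  status <- fit$status
  residual <- NA_real_
  if (status == "optimal") {
    residual <- sum(abs(Phi %*% x_hat - y))
    feas_tol <- options$solver_tolerance * max(1, sum(abs(y)))
    if (residual > max(options$noise_tolerance, feas_tol) + feas_tol) {
      status <- "tolerance_exceeded"
    }
  }
  structure(
    list(
      x_hat = x_hat,
      l1_norm = if (all(is.finite(x_hat))) sum(abs(x_hat)) else NA_real_,
      residual_l1 = residual,
      status = status,
      baseline = if (is.null(baseline)) NA_real_ else baseline,
      objective = fit$objective
    ),
    class = "decode_result"
  )
}

#' Decode a gene-by-pool measurement matrix
#'
#' Applies [decode_profile()] independently to each gene (row). With
#' `options$scale = "log2"` the matrix is exponentiated (base 2) once before
#' decoding and the decoded expression is returned in both scales (the log2
#' copy as `log2(pmax(x, 0) + 1)` to accommodate exact zeros). Gene order and
#' identifiers are preserved. Missing values are an error naming the gene —
#' no imputation.
#'
#' @param design a [pooling_design].
#' @param measurements numeric matrix or data frame, genes as rows, exactly
#'   `n_pools` columns.
#' @param options a [decode_options()] list.
#' @return A `decoded_matrix`: `expression` (genes x samples, linear scale),
#'   `expression_log2` (when input was log2), and a `diagnostics` data frame
#'   with per-gene `l1_norm`, `residual_l1`, `status`, `baseline`.
#' @export
decode_matrix <- function(design, measurements, options = decode_options()) {
  stopifnot(inherits(design, "pooling_design"))
  if (is.data.frame(measurements)) measurements <- as.matrix(measurements)
  if (!is.matrix(measurements) || !is.numeric(measurements)) {
    stop_("measurements must be a numeric matrix (genes x pools)")
  }
  if (ncol(measurements) != design$n_pools) {
    stop_("measurements must have n_pools = %d columns, got %d",
          design$n_pools, ncol(measurements))
  }
  if (!inherits(options, "decode_options")) options <- do.call(decode_options, options)
  genes <- rownames(measurements)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(measurements)))
  na_rows <- which(apply(measurements, 1L, anyNA))
  if (length(na_rows)) {
    stop_("missing values in measurements for gene '%s' (row %d); no imputation is performed",
          genes[na_rows[1L]], na_rows[1L])
  }
  input_log2 <- options$scale == "log2"
  meas_lin <- if (input_log2) 2^measurements else measurements
  row_options <- options
  row_options$scale <- "linear"
  n_genes <- nrow(meas_lin)
  expr <- matrix(NA_real_, n_genes, design$n_samples,
                 dimnames = list(genes, design$sample_labels))
  diag_df <- data.frame(
    gene = genes,
    l1_norm = NA_real_,
    residual_l1 = NA_real_,
    status = NA_character_,
    baseline = NA_real_,
    stringsAsFactors = FALSE
  )
  for (g in seq_len(n_genes)) {
    fit <- decode_profile(design, meas_lin[g, ], row_options)
    expr[g, ] <- fit$x_hat
    diag_df$l1_norm[g] <- fit$l1_norm
    diag_df$residual_l1[g] <- fit$residual_l1
    diag_df$status[g] <- fit$status
    diag_df$baseline[g] <- fit$baseline
  }
  out <- list(
    expression = expr,
    diagnostics = diag_df,
    options = options
  )
  if (input_log2) out$expression_log2 <- log2(pmax(expr, 0) + 1)
  structure(out, class = "decoded_matrix")
}

#' @export
print.decoded_matrix <- function(x, ...) {
  cat(sprintf("Decoded expression: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  tab <- table(x$diagnostics$status)
  cat("  solver status:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: status %s, l1 norm %.6g, residual l1 %.3g\n",
              x$status, x$l1_norm, x$residual_l1))
  invisible(x)
}
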