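#' Sum of absolute differences between two profiles
#'
#' The l1 decoding error between a true and a decoded profile.
#'
#' @param x_true,x_hat numeric vectors of equal length.
#' @return Scalar `sum(|x_true - x_hat|)`.
#' @export
l1_error <- function(x_true, x_hat) {
  if (length(x_true) != length(x_hat)) {
    stop_("length mismatch: %d vs %d", length(x_true), length(x_hat))
  }
  sum(abs(x_true - x_hat))
}

#' Sparsity profile of a vector
#'
#' Identifies `S`, the indices of the `k` largest-magnitude entries of
#' `x - c` (with center `c = 0` or the lower median of `x`), and the l1 mass
#' left outside `S` — the "tail" that bounds the decoding error of an
#' expander design certified for `k` spikes. Ties in magnitude are broken by
#' lowest index. `tail_l1` is zero exactly when `x` is `k`-sparse about the
#' center.
#'
#' @param x numeric vector.
#' @param k number of spikes considered, `0 <= k <= length(x)`.
#' @param center `"none"` (deviations from zero) or `"median"` (deviations
#'   from the lower median of `x`).
#' @return A `sparsity_profile` list: `k`, `S` (increasing indices),
#'   `tail_l1`, `center_value`.
#' @examples
#' sparsity_tail(c(3, 1, 1), 1)$tail_l1 # 2
#' @export
sparsity_tail <- function(x, k, center = c("none", "median")) {
  center <- match.arg(center)
  if (!is_count(k, 0L) || k > length(x)) {
    stop_("k must be a count with 0 <= k <= length(x)")
  }
  c0 <- if (center == "median") lower_median(x) else 0
  dev <- x - c0
  ord <- order(-abs(dev), seq_along(dev)) # magnitude desc, ties by lowest index
  S <- sort(ord[seq_len(k)])
  tail_idx <- setdiff(seq_along(x), S)
  structure(
    list(
      k = as.integer(k),
      S = S,
      tail_l1 = sum(abs(dev[tail_idx])),
      center_value = c0
    ),
    class = "sparsity_profile"
  )
}

#' Check the sparse-recovery error bound
#'
#' For a design certified as a `(2k, epsilon)` expander, the l1 decoding
#' error is bounded by a design-dependent constant times the l1 mass of the
#' true profile outside its `k` largest entries:
#' `||x_true - x_hat||_1 <= C * tail_l1(x_true, k)`. With an exactly
#' `k`-sparse truth the tail is zero and decoding must be exact up to solver
#' tolerance, hence the absolute `tolerance` term.
#'
#' @param x_true,x_hat numeric vectors of equal length.
#' @param k sparsity level of the certification.
#' @param C positive bound constant (empirically calibrated; the theoretical
#'   constant depends on the design's expansion slack).
#' @param center centering mode passed to [sparsity_tail()].
#' @param tolerance absolute slack, scaled by `max(1, ||x_true||_1)`, for the
#'   noiseless exact case.
#' @return List: `holds`, `margin` (`bound - error`), `error`, `bound`,
#'   `tail_l1`.
#' @export
check_error_bound <- function(x_true, x_hat, k, C, center = "none",
                              tolerance = 1e-8) {
  if (!is.numeric(C) || C <= 0) stop_("C must be > 0")
  err <- l1_error(x_true, x_hat)
  tail <- sparsity_tail(x_true, k, center)$tail_l1
  bound <- C * tail + tolerance * max(1, sum(abs(x_true)))
  list(holds = err <= bound, margin = bound - err, error = err,
       bound = bound, tail_l1 = tail)
}

#' Call spikes in a decoded profile
#'
#' A sample is called a spike when its decoded intensity deviates from the
#' profile's (lower) median by at least `threshold_log2` on the
#' `log2(x + 1)` scale; the +1 offset keeps exact zeros finite. Signs mark
#' up- versus down-regulation. This is an evaluation convention for scoring
#' recovery, not a differential-expression test.
#'
#' @param x_hat nonnegative decoded profile.
#' @param threshold_log2 positive detection threshold in log2 units.
#' @return Data frame with columns `sample` (index) and `sign` (+1/-1).
#' @export
spike_calls <- function(x_hat, threshold_log2 = 1) {
  if (!is.numeric(threshold_log2) || threshold_log2 <= 0) {
    stop_("threshold_log2 must be > 0")
  }
  med <- lower_median(x_hat)
  dev <- log2(pmax(x_hat, 0) + 1) - log2(max(med, 0) + 1)
  idx <- which(abs(dev) >= threshold_log2)
  data.frame(sample = idx, sign = ifelse(dev[idx] > 0, 1L, -1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concordance between a reference and a decoded expression matrix
#'
#' Per-sample Pearson correlation on the `log2(x + 1)` scale, per-gene l1
#' errors on the linear scale, and a long paired table ready for scatter
#' plots, mirroring how directly measured and decoded experiments are
#' compared.
#'
#' @param reference,decoded numeric matrices with identical dimensions and
#'   dimnames (genes x samples, linear scale).
#' @return List: `per_sample` (`sample`, `pearson_log2`), `per_gene`
#'   (`gene`, `l1_error`), `pairs` (`gene`, `sample`, `reference`,
#'   `decoded`).
#' @export
compare_matrices <- function(reference, decoded) {
  if (is.data.frame(reference)) reference <- as.matrix(reference)
  if (is.data.frame(decoded)) decoded <- as.matrix(decoded)
  if (!all(dim(reference) == dim(decoded))) {
    stop_("reference and decoded must have identical dimensions")
  }
  if (!identical(dimnames(reference), dimnames(decoded))) {
    stop_("reference and decoded must carry identical gene/sample labels")
  }
  lr <- log2(pmax(reference, 0) + 1)
  ld <- log2(pmax(decoded, 0) + 1)
  per_sample <- data.frame(
    sample = colnames(reference),
    pearson_log2 = vapply(seq_len(ncol(reference)), function(j) {
      if (stats::sd(lr[, j]) == 0 || stats::sd(ld[, j]) == 0) {
        return(NA_real_)
      }
      stats::cor(lr[, j], ld[, j])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  per_gene <- data.frame(
    gene = rownames(reference),
    l1_error = vapply(seq_len(nrow(reference)), function(i) {
      l1_error(reference[i, ], decoded[i, ])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    gene = rep(rownames(reference), times = ncol(reference)),
    sample = rep(colnames(reference), each = nrow(reference)),
    reference = as.vector(reference),
    decoded = as.vector(decoded),
    stringsAsFactors = FALSE
  )
  list(per_sample = per_sample, per_gene = per_gene, pairs = pairs)
}
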