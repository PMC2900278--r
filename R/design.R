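#' Pooling designs from unbalanced expander graphs
#'
#' A pooling design is an `m x n` binary matrix \eqn{\Phi}: rows are pools
#' (one microarray chip each), columns are samples, and a 1 in cell
#' \eqn{(i, j)} means sample \eqn{j} is mixed into pool \eqn{i}. Equivalently
#' it is the adjacency matrix of a left-`d`-regular bipartite graph with the
#' samples on the left and the pools on the right; each sample is assayed in
#' exactly `d` different pools. Good designs are expanders: small sample
#' subsets touch many distinct pools, which is what makes the pooled linear
#' system invertible on sparse profiles.
#'
#' @name pooling_design
#' @seealso [build_design()], [verify_expansion()], [design_for_guarantee()]
NULL

new_pooling_design <- function(matrix, left_degree, seed = NA_integer_,
                               guarantee_k = NA_integer_, epsilon = NA_real_) {
  structure(
    list(
      matrix = matrix,
      n_samples = ncol(matrix),
      n_pools = nrow(matrix),
      left_degree = as.integer(left_degree),
      guarantee_k = as.integer(guarantee_k),
      epsilon = epsilon,
      seed = seed,
      sample_labels = colnames(matrix),
      pool_labels = rownames(matrix)
    ),
    class = "pooling_design"
  )
}

validate_design <- function(design) {
  m <- design$matrix
  if (!is.matrix(m) || !all(m %in% c(0L, 1L))) {
    stop_("design matrix entries must all be 0 or 1")
  }
  cs <- colSums(m)
  if (length(unique(cs)) != 1L || cs[1L] != design$left_degree) {
    stop_("every column must have exactly left_degree = %d ones", design$left_degree)
  }
  if (design$n_pools < design$left_degree) {
    stop_("n_pools (%d) must be >= left_degree (%d)", design$n_pools, design$left_degree)
  }
  invisible(design)
}

#' Construct a random left-regular pooling design
#'
#' Each sample (column) is assigned a uniformly random set of `left_degree`
#' pools; a draw colliding with an already-used pool set is resampled, so all
#' column supports are pairwise distinct. Distinct supports make every design
#' a (1, 0)-expander: each sample alone touches exactly `left_degree` pools.
#'
#' @param n_samples number of samples `n` (columns).
#' @param n_pools number of pools `m` (rows); `m < n` gives compression.
#' @param left_degree number `d` of pools each sample enters.
#' @param seed integer seed; the construction is deterministic given the seed.
#' @return A `pooling_design` object.
#' @examples
#' d <- build_design(n_samples = 15, n_pools = 12, left_degree = 2, seed = 7)
#' colSums(as.matrix(d)) # all 2
#' @export
build_design <- function(n_samples, n_pools, left_degree = 2, seed = 1) {
  if (!is_count(n_samples, 1L)) stop_("n_samples must be a positive count")
  if (!is_count(n_pools, 1L)) stop_("n_pools must be a positive count")
  if (!is_count(left_degree, 1L) || left_degree > n_pools) {
    stop_("left_degree must satisfy 1 <= left_degree <= n_pools")
  }
  n_supports <- choose(n_pools, left_degree)
  if (n_supports < n_samples) {
    stop_(paste0(
      "infeasible design: only choose(%d, %d) = %.0f distinct pool subsets ",
      "of size %d exist, fewer than the %d distinct column supports required"
    ), n_pools, left_degree, n_supports, left_degree, n_samples)
  }
  mat <- with_seed(seed, {
    m <- matrix(0L, n_pools, n_samples)
    seen <- character(0)
    for (j in seq_len(n_samples)) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        s <- sort(sample.int(n_pools, left_degree))
        key <- paste(s, collapse = ",")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          m[s, j] <- 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_("could not draw a fresh pool subset for column %d after 10000 attempts", j)
      }
    }
    m
  })
  dimnames(mat) <- list(
    paste0("P", seq_len(n_pools)),
    paste0("S", seq_len(n_samples))
  )
  validate_design(new_pooling_design(mat, left_degree, seed = as.integer(seed)))
}

#' Verify the expansion property of a pooling design
#'
#' Exhaustively enumerates every sample subset `X` with `|X| <= k` and counts
#' its pool neighborhood `N(X)` (pools receiving at least one sample of `X`).
#' The design is a `(k, epsilon)`-unbalanced expander iff
#' `|N(X)| >= (1 - epsilon) * d * |X|` for all such `X`. The smallest slack
#' actually achieved, `epsilon_achieved = 1 - min |N(X)| / (d |X|)`, is
#' reported together with a worst subset attaining it.
#'
#' Enumeration is exact by design: there is no sampling fallback. If the
#' number of subsets exceeds `subset_budget` the call fails and the caller
#' must lower `k` or raise the budget explicitly.
#'
#' @param design a [pooling_design].
#' @param k maximum subset size to check (`k <= n_samples`).
#' @param epsilon requested expansion slack in `[0, 1)`.
#' @param subset_budget maximum number of subsets to enumerate.
#' @return An `expansion_report`: `k_checked`, `epsilon_requested`,
#'   `epsilon_achieved`, `worst_set` (sample indices), `is_expander`,
#'   `n_subsets_checked`.
#' @examples
#' d <- build_design(6, 6, 1, seed = 1)
#' verify_expansion(d, k = 3, epsilon = 0)$epsilon_achieved # 0
#' @export
verify_expansion <- function(design, k, epsilon = 0.25, subset_budget = 1e6) {
  stopifnot(inherits(design, "pooling_design"))
  if (!is_count(k, 1L) || k > design$n_samples) {
    stop_("k must be a count with 1 <= k <= n_samples")
  }
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon >= 1) {
    stop_("epsilon must lie in [0, 1)")
  }
  n <- design$n_samples
  d <- design$left_degree
  total <- sum(choose(n, seq_len(k)))
  if (total > subset_budget) {
    stop_(paste0(
      "subset budget exceeded: checking all subsets up to size %d needs %.0f ",
      "enumerations but subset_budget = %.0f; lower k or raise subset_budget"
    ), k, total, subset_budget)
  }
  mat <- design$matrix
  worst_ratio <- 1
  worst_set <- integer(0)
  for (s in seq_len(k)) {
    sets <- utils::combn(n, s)
    for (i in seq_len(ncol(sets))) {
      X <- sets[, i]
      nb <- sum(rowSums(mat[, X, drop = FALSE]) > 0L)
      ratio <- nb / (d * s)
      if (ratio < worst_ratio) {
        worst_ratio <- ratio
        worst_set <- X
      }
    }
  }
  structure(
    list(
      k_checked = as.integer(k),
      epsilon_requested = epsilon,
      epsilon_achieved = 1 - worst_ratio,
      worst_set = worst_set,
      is_expander = worst_ratio >= (1 - epsilon) - 1e-12,
      n_subsets_checked = total
    ),
    class = "expansion_report"
  )
}

#' Search for a design certified to recover k spikes
#'
#' The l1 decoder's recovery guarantee for `k`-sparse profiles requires the
#' design to be a `(2k, epsilon)`-unbalanced expander. This searches over an
#' increasing number of pools `m`, drawing up to `max_attempts` random
#' designs at each `m` and returning the first one that [verify_expansion()]
#' certifies at `(2k, epsilon)`. The returned design records `guarantee_k = k`
#' and the certification `epsilon`.
#'
#' @inheritParams build_design
#' @param k number of spikes the design must certify.
#' @param epsilon expansion slack used for certification.
#' @param max_attempts random draws per pool count.
#' @param max_pools largest `m` to try; defaults to `4 * n_samples` (small
#'   `epsilon` at `k >= 2` typically needs `m > n`).
#' @param subset_budget passed to [verify_expansion()].
#' @return A certified `pooling_design`.
#' @examples
#' d <- design_for_guarantee(n_samples = 15, k = 1, epsilon = 0.25, seed = 3)
#' d$n_pools # <= 12
#' @export
design_for_guarantee <- function(n_samples, k = 1, epsilon = 0.25,
                                 left_degree = 2, seed = 1, max_attempts = 50,
                                 max_pools = NULL, subset_budget = 1e6) {
  if (!is_count(k, 1L)) stop_("k must be a positive count")
  if (2L * k > n_samples) stop_("certification needs 2k <= n_samples")
  if (is.null(max_pools)) max_pools <- max(left_degree, 4L * n_samples)
  sub_seeds <- with_seed(seed, {
    sample.int(.Machine$integer.max, (max_pools - left_degree + 1L) * max_attempts)
  })
  idx <- 0L
  for (m in seq.int(left_degree, max_pools)) {
    for (attempt in seq_len(max_attempts)) {
      idx <- idx + 1L
      if (choose(m, left_degree) < n_samples) next
      cand <- build_design(n_samples, m, left_degree, seed = sub_seeds[idx])
      rep <- verify_expansion(cand, k = 2L * k, epsilon = epsilon,
                              subset_budget = subset_budget)
      if (rep$is_expander) {
        cand$guarantee_k <- as.integer(k)
        cand$epsilon <- epsilon
        cand$seed <- as.integer(seed)
        return(cand)
      }
    }
  }
  stop_(paste0(
    "no (2k, epsilon) = (%d, %.3f) certified design found with left_degree %d ",
    "for n_samples = %d after trying up to m = %d pools"
  ), 2L * k, epsilon, left_degree, n_samples, max_pools)
}

#' Approximate number of chips needed for a pooled experiment
#'
#' Asymptotic sizing rule for expander-based pooling: recovering `k` spikes
#' among `n` samples needs on the order of `k * log(n / k)` pooled chips
#' (natural log, rounded to the nearest integer). This is a noise-free lower
#' bound on the experiment size, not the exact pool count of a constructed
#' design.
#'
#' @param n_samples number of samples.
#' @param k_spikes expected spikes per gene profile; must be at least 1.
#' @return Integer chip count.
#' @examples
#' chips_needed(100, 10) # 23
#' @export
chips_needed <- function(n_samples, k_spikes) {
  if (!is_count(n_samples, 1L)) stop_("n_samples must be a positive count")
  if (!is_count(k_spikes, 1L)) {
    stop_("k_spikes must be >= 1: with no spikes there is no information target")
  }
  if (k_spikes > n_samples) stop_("k_spikes cannot exceed n_samples")
  as.integer(round(k_spikes * log(n_samples / k_spikes)))
}

#' @export
as.matrix.pooling_design <- function(x, ...) x$matrix

#' @export
print.pooling_design <- function(x, ...) {
  cat(sprintf("Pooling design: %d pools x %d samples, left degree %d\n",
              x$n_pools, x$n_samples, x$left_degree))
  if (!is.na(x$guarantee_k)) {
    cat(sprintf("  certified (2k, eps) expander: k = %d spikes, eps = %.3f\n",
                x$guarantee_k, x$epsilon))
  }
  if (!is.na(x$seed)) cat(sprintf("  construction seed: %d\n", x$seed))
  invisible(x)
}

#' @export
print.expansion_report <- function(x, ...) {
  cat(sprintf("Expansion check up to |X| = %d (%.0f subsets)\n",
              x$k_checked, x$n_subsets_checked))
  cat(sprintf("  requested epsilon: %.4f  achieved: %.4f  expander: %s\n",
              x$epsilon_requested, x$epsilon_achieved, x$is_expander))
  if (length(x$worst_set)) {
    cat("  worst subset (sample indices):", paste(x$worst_set, collapse = ", "), "\n")
  }
  invisible(x)
}
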