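#' Configuration for the sparse-profile simulator
#'
#' The generator emulates the data model behind smart pooling: each gene is
#' near-constant across samples at a gene-specific baseline intensity, with a
#' small number of "spike" samples deviating up or down from that baseline,
#' and pooled measurements carry multiplicative (log-normal) noise whose
#' relative magnitude grows at low intensity, mimicking the decaying
#' signal-to-noise of array assays near background.
#'
#' @param n_samples samples per gene profile.
#' @param n_genes number of genes to simulate.
#' @param k_spikes spikes per gene: a single count, or a probability vector
#'   over spike counts `0, 1, 2, ...` (element `i` is the probability of
#'   `i - 1` spikes) from which each gene's count is drawn.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline intensity is
#'   `2^b` with `b ~ Normal(mean, sd)` (log2 units; defaults 8 and 2 resemble
#'   RMA-scale array intensities).
#' @param spike_log2_magnitude spike effect size in log2 units: a spiked
#'   sample's log2 intensity is the baseline plus or minus this value.
#' @param down_spike_fraction probability a spike is a down-spike. Down-spiked
#'   intensities stay positive under the multiplicative model, so the
#'   bounded-below-by-zero constraint holds by construction.
#' @param noise_log2_sd standard deviation of the multiplicative measurement
#'   noise exponent (log2 units); 0 disables noise.
#' @param low_intensity_noise_boost factor multiplying the noise sd for
#'   measurements below `low_intensity_threshold` (linear scale), emulating
#'   the extra relative noise of low-expression signals.
#' @param low_intensity_threshold linear intensity below which the noise
#'   boost applies.
#' @param seed RNG seed; every stochastic stage derives its stream from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 15, n_genes = 100, k_spikes = 1,
                              baseline_log2_mean = 8, baseline_log2_sd = 2,
                              spike_log2_magnitude = 3,
                              down_spike_fraction = 0.5,
                              noise_log2_sd = 0.25,
                              low_intensity_noise_boost = 2,
                              low_intensity_threshold = 64,
                              seed = 1) {
  if (!is_count(n_samples, 1L)) stop_("n_samples must be a positive count")
  if (!is_count(n_genes, 1L)) stop_("n_genes must be a positive count")
  if (length(k_spikes) == 1L) {
    if (!is_count(k_spikes, 0L)) stop_("k_spikes must be a nonnegative count")
    if (k_spikes > n_samples) stop_("k_spikes cannot exceed n_samples")
  } else {
    if (any(k_spikes < 0) || sum(k_spikes) <= 0) {
      stop_("a k_spikes distribution needs nonnegative weights with positive sum")
    }
    if (length(k_spikes) - 1L > n_samples) {
      stop_("k_spikes distribution assigns mass to counts above n_samples")
    }
  }
  if (baseline_log2_sd < 0 || noise_log2_sd < 0) stop_("sds must be >= 0")
  if (down_spike_fraction < 0 || down_spike_fraction > 1) {
    stop_("down_spike_fraction must lie in [0, 1]")
  }
  if (low_intensity_noise_boost < 0) stop_("low_intensity_noise_boost must be >= 0")
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_genes = as.integer(n_genes),
      k_spikes = k_spikes,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      spike_log2_magnitude = spike_log2_magnitude,
      down_spike_fraction = down_spike_fraction,
      noise_log2_sd = noise_log2_sd,
      low_intensity_noise_boost = low_intensity_noise_boost,
      low_intensity_threshold = low_intensity_threshold,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate sparse per-sample expression profiles
#'
#' Each gene draws a baseline log2 intensity once and replicates it across
#' all samples; `k` spike positions (sampled uniformly without replacement)
#' are shifted by plus or minus `spike_log2_magnitude` in log2 space. The
#' returned intensities are linear scale (`2^log2`), hence strictly positive,
#' and each profile minus its median is exactly `k`-sparse. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A `sim_profiles` list: `expression` (genes x samples, linear
#'   scale), `spikes` (data frame `gene`, `sample`, `sign` with +1 up, -1
#'   down), and the `config`.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  g <- config$n_genes
  with_seed(config$seed, {
    expr <- matrix(NA_real_, g, n,
                   dimnames = list(sprintf("g%04d", seq_len(g)),
                                   paste0("S", seq_len(n))))
    spike_rows <- vector("list", g)
    for (i in seq_len(g)) {
      b <- stats::rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
      k <- if (length(config$k_spikes) == 1L) {
        config$k_spikes
      } else {
        sample.int(length(config$k_spikes), 1L, prob = config$k_spikes) - 1L
      }
      prof <- rep(b, n)
      if (k > 0) {
        pos <- sample.int(n, k)
        sgn <- ifelse(stats::runif(k) < config$down_spike_fraction, -1L, 1L)
        prof[pos] <- b + sgn * config$spike_log2_magnitude
        spike_rows[[i]] <- data.frame(
          gene = rownames(expr)[i], sample = pos, sign = sgn,
          stringsAsFactors = FALSE
        )
      }
      expr[i, ] <- pmax(2^prof, 0)
    }
    spikes <- do.call(rbind, spike_rows)
    if (is.null(spikes)) {
      spikes <- data.frame(gene = character(0), sample = integer(0),
                           sign = integer(0), stringsAsFactors = FALSE)
    }
    structure(list(expression = expr, spikes = spikes, config = config),
              class = "sim_profiles")
  })
}

#' Noiseless synthetic multiplex measurements
#'
#' Computes the in-silico pooled experiment: each gene's per-sample profile
#' is multiplied by the pooling design, exactly as physical pooling would mix
#' the samples if intensities were perfectly additive. Isolates the sparsity
#' assumption from measurement noise.
#'
#' @param monoplex genes x samples matrix of linear-scale intensities (or a
#'   `sim_profiles` object).
#' @param design a [pooling_design].
#' @return Genes x pools measurement matrix.
#' @export
synthetic_multiplex <- function(monoplex, design) {
  stopifnot(inherits(design, "pooling_design"))
  if (inherits(monoplex, "sim_profiles")) monoplex <- monoplex$expression
  if (is.data.frame(monoplex)) monoplex <- as.matrix(monoplex)
  if (!is.matrix(monoplex) || !is.numeric(monoplex)) {
    stop_("monoplex must be a numeric genes x samples matrix")
  }
  if (ncol(monoplex) != design$n_samples) {
    stop_("monoplex has %d columns but the design expects n_samples = %d",
          ncol(monoplex), design$n_samples)
  }
  if (any(monoplex < 0)) stop_("monoplex intensities must be nonnegative")
  y <- monoplex %*% t(design$matrix)
  colnames(y) <- design$pool_labels
  y
}

#' Add multiplicative measurement noise
#'
#' Each measurement is multiplied by `2^e` with
#' `e ~ Normal(0, noise_log2_sd)`; entries below
#' `low_intensity_threshold` use the sd inflated by
#' `low_intensity_noise_boost`, so relative noise grows as expression
#' approaches background. Nonnegativity is preserved for any nonnegative
#' input. Deterministic given the seed (derived from `config$seed` by
#' default so the noise stream differs from the profile stream).
#'
#' @param measurements numeric matrix of nonnegative measurements.
#' @param config a [simulation_config()].
#' @param seed RNG seed for the noise stream; defaults to `config$seed + 1`.
#' @return Matrix of the same shape.
#' @export
add_measurement_noise <- function(measurements, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.data.frame(measurements)) measurements <- as.matrix(measurements)
  if (!is.matrix(measurements) || !is.numeric(measurements)) {
    stop_("measurements must be a numeric matrix")
  }
  if (is.null(seed)) seed <- config$seed + 1L
  if (config$noise_log2_sd == 0) return(measurements)
  with_seed(seed, {
    sd_mat <- config$noise_log2_sd *
      ifelse(measurements < config$low_intensity_threshold,
             config$low_intensity_noise_boost, 1)
    e <- stats::rnorm(length(measurements)) * sd_mat
    measurements * 2^matrix(e, nrow(measurements), ncol(measurements))
  })
}

#' Run a full simulated pooling-and-decoding experiment
#'
#' Pipeline: simulate sparse profiles, pool them through the design, add
#' multiplicative noise (when `config$noise_log2_sd > 0`), decode every gene
#' with the l1 linear program, and score recovery. Decoding defaults to
#' median-baseline centering, matching the generator's sparsity-about-the-
#' median data model.
#'
#' @param config a [simulation_config()].
#' @param design a [pooling_design].
#' @param options [decode_options()] for the decoder; defaults to centered,
#'   equality-constrained decoding.
#' @param exact_tolerance relative l1 error below which a gene counts as
#'   exactly recovered (default `1e-4`, driven by solver tolerance in the
#'   noiseless case).
#' @param spike_threshold_log2 threshold passed to [spike_calls()] when
#'   scoring spike detection.
#' @return A `recovery_report`: `per_gene` data frame (true/decoded l1
#'   error, relative error, exact flag, spike counts), `aggregates` (exact
#'   recovery rate, mean/median l1 error, spike precision/recall), plus the
#'   simulation inputs. `truth`, `measurements`, `decoded` matrices are
#'   attached for downstream comparison.
#' @export
run_experiment <- function(config, design,
                           options = decode_options(center_baseline = TRUE),
                           exact_tolerance = 1e-4,
                           spike_threshold_log2 = 1) {
  stopifnot(inherits(config, "simulation_config"), inherits(design, "pooling_design"))
  if (config$n_samples != design$n_samples) {
    stop_("config$n_samples (%d) does not match design n_samples (%d)",
          config$n_samples, design$n_samples)
  }
  sim <- simulate_profiles(config)
  y <- synthetic_multiplex(sim$expression, design)
  if (config$noise_log2_sd > 0) y <- add_measurement_noise(y, config)
  dec <- decode_matrix(design, y, options)
  truth <- sim$expression
  xhat <- dec$expression
  g <- nrow(truth)
  true_spikes <- split(sim$spikes$sample, sim$spikes$gene)
  per_gene <- data.frame(
    gene = rownames(truth),
    k_true = 0L, l1_error = NA_real_, rel_error = NA_real_, exact = NA,
    n_true_spikes = 0L, n_called = 0L, true_positive = 0L,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(g)) {
    tv <- truth[i, ]
    dv <- xhat[i, ]
    err <- sum(abs(tv - dv))
    denom <- max(sum(abs(tv)), .Machine$double.eps)
    ts <- true_spikes[[rownames(truth)[i]]]
    if (is.null(ts)) ts <- integer(0)
    calls <- spike_calls(pmax(dv, 0), spike_threshold_log2)
    per_gene$k_true[i] <- length(ts)
    per_gene$l1_error[i] <- err
    per_gene$rel_error[i] <- err / denom
    per_gene$exact[i] <- err / denom < exact_tolerance
    per_gene$n_true_spikes[i] <- length(ts)
    per_gene$n_called[i] <- nrow(calls)
    per_gene$true_positive[i] <- sum(calls$sample %in% ts)
  }
  tp <- sum(per_gene$true_positive)
  n_called <- sum(per_gene$n_called)
  n_true <- sum(per_gene$n_true_spikes)
  aggregates <- list(
    exact_recovery_rate = mean(per_gene$exact),
    mean_l1_error = mean(per_gene$l1_error),
    median_l1_error = stats::median(per_gene$l1_error),
    spike_precision = if (n_called > 0) tp / n_called else NA_real_,
    spike_recall = if (n_true > 0) tp / n_true else NA_real_,
    exact_tolerance = exact_tolerance,
    spike_threshold_log2 = spike_threshold_log2
  )
  structure(
    list(
      per_gene = per_gene,
      aggregates = aggregates,
      truth = truth,
      measurements = y,
      decoded = xhat,
      spikes = sim$spikes,
      config = config,
      options = options,
      design_dims = c(n_pools = design$n_pools, n_samples = design$n_samples)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("Recovery report: %d genes, %d pools x %d samples\n",
              nrow(x$per_gene), x$design_dims["n_pools"], x$design_dims["n_samples"]))
  cat(sprintf("  exact recovery rate: %.3f (rel l1 < %g)\n",
              a$exact_recovery_rate, a$exact_tolerance))
  cat(sprintf("  mean / median l1 error: %.4g / %.4g\n",
              a$mean_l1_error, a$median_l1_error))
  cat(sprintf("  spike precision / recall: %.3f / %.3f (|log2 FC| >= %g)\n",
              a$spike_precision, a$spike_recall, a$spike_threshold_log2))
  invisible(x)
}
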