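test_that("simulated profiles follow the spike-about-the-median model", {
  cfg0 <- simulation_config(n_genes = 20, k_spikes = 0, seed = 3)
  sim0 <- simulate_profiles(cfg0)
  expect_true(all(apply(sim0$expression, 1, function(r) length(unique(r)) == 1)))
  expect_identical(nrow(sim0$spikes), 0L)

  cfg1 <- simulation_config(n_genes = 50, k_spikes = 1, seed = 4)
  sim1 <- simulate_profiles(cfg1)
  expect_true(all(sim1$expression >= 0))
  # each profile minus its median is exactly 1-sparse
  for (i in seq_len(50)) {
    r <- sim1$expression[i, ]
    dev <- r - median(r)
    expect_identical(sum(abs(dev) > 1e-9), 1L)
  }
  # annotations point at the deviating sample
  expect_identical(nrow(sim1$spikes), 50L)
  for (i in seq_len(50)) {
    row <- sim1$spikes[sim1$spikes$gene == rownames(sim1$expression)[i], ]
    r <- sim1$expression[i, ]
    expect_identical(unname(which.max(abs(r - median(r)))), row$sample)
    expect_equal(unname(sign(r[row$sample] - median(r))), as.numeric(row$sign))
  }
})

test_that("the generator is deterministic given its seed", {
  cfg <- simulation_config(n_genes = 30, k_spikes = 2, seed = 99)
  s1 <- simulate_profiles(cfg)
  s2 <- simulate_profiles(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$spikes, s2$spikes)
  d <- ref_design()
  m <- synthetic_multiplex(s1, d)
  expect_identical(add_measurement_noise(m, cfg), add_measurement_noise(m, cfg))
})

test_that("k_spikes distributions and invalid configs are handled", {
  cfg <- simulation_config(n_genes = 200, k_spikes = c(0.5, 0.3, 0.2), seed = 5)
  sim <- simulate_profiles(cfg)
  counts <- table(factor(tabulate(
    match(sim$spikes$gene, rownames(sim$expression)), nbins = 200),
    levels = 0:2))
  expect_true(all(counts > 0)) # all three spike counts occur
  expect_error(simulation_config(n_samples = 5, k_spikes = 6), "exceed")
  expect_error(simulation_config(down_spike_fraction = 1.5), "down_spike_fraction")
})

test_that("synthetic multiplex is the linear forward map of the design", {
  d <- ref_design()
  cfg <- simulation_config(n_genes = 10, seed = 6)
  sim <- simulate_profiles(cfg)
  y <- synthetic_multiplex(sim, d)
  expect_identical(dim(y), c(10L, 12L))
  expect_equal(y[1, ], pool_profile(sim$expression[1, ], d))
  expect_equal(synthetic_multiplex(2 * sim$expression, d), 2 * y)
  expect_equal(synthetic_multiplex(matrix(0, 3, 15), d), matrix(0, 3, 12,
    dimnames = list(NULL, d$pool_labels)))
  expect_error(synthetic_multiplex(matrix(1, 3, 9), d), "n_samples")
})

test_that("measurement noise is multiplicative with the configured log2 sd", {
  cfg <- simulation_config(noise_log2_sd = 0.25, low_intensity_noise_boost = 1,
                           seed = 8)
  m <- matrix(1000, 100, 100) # 1e4 entries, all above the low-intensity floor
  noisy <- add_measurement_noise(m, cfg)
  expect_true(all(noisy >= 0))
  ratios <- log2(noisy / m)
  expect_equal(sd(ratios), 0.25, tolerance = 0.05) # within 5% relative
  # zero sd is the identity
  cfg0 <- simulation_config(noise_log2_sd = 0, seed = 8)
  expect_identical(add_measurement_noise(m, cfg0), m)
  # low-intensity entries get boosted noise
  cfgb <- simulation_config(noise_log2_sd = 0.1, low_intensity_noise_boost = 3,
                            low_intensity_threshold = 64, seed = 9)
  low <- matrix(10, 60, 60)
  high <- matrix(1000, 60, 60)
  expect_gt(sd(log2(add_measurement_noise(low, cfgb) / low)),
            sd(log2(add_measurement_noise(high, cfgb) / high)))
})

test_that("noiseless 1-spike experiments on a certified design recover exactly", {
  d <- ref_design()
  cfg <- simulation_config(n_genes = 120, k_spikes = 1, noise_log2_sd = 0,
                           seed = 21)
  rep <- run_experiment(cfg, d)
  expect_equal(rep$aggregates$exact_recovery_rate, 1.0)
  expect_equal(rep$aggregates$spike_recall, 1.0)
  expect_true(all(rep$per_gene$rel_error < 1e-4))
  # aggregates are consistent with the per-gene records
  expect_equal(rep$aggregates$mean_l1_error, mean(rep$per_gene$l1_error))
  expect_true(rep$aggregates$exact_recovery_rate >= 0 &&
              rep$aggregates$exact_recovery_rate <= 1)
})

test_that("noise degrades recovery and nonnegative decoding stays nonnegative", {
  d <- ref_design()
  cfg0 <- simulation_config(n_genes = 80, k_spikes = 1, noise_log2_sd = 0,
                            seed = 31)
  cfgN <- simulation_config(n_genes = 80, k_spikes = 1, noise_log2_sd = 0.4,
                            seed = 31)
  r0 <- run_experiment(cfg0, d)
  rN <- run_experiment(cfgN, d)
  expect_lte(rN$aggregates$exact_recovery_rate, r0$aggregates$exact_recovery_rate)
  expect_gt(rN$aggregates$mean_l1_error, r0$aggregates$mean_l1_error)
  # down-spike-heavy nonnegative decoding: no negative estimates
  cfgD <- simulation_config(n_genes = 40, k_spikes = 1, down_spike_fraction = 1,
                            noise_log2_sd = 0, seed = 32)
  rD <- run_experiment(cfgD, d,
                       decode_options(center_baseline = TRUE, nonnegative = TRUE))
  expect_true(all(rD$decoded >= -1e-9))
  expect_equal(rD$aggregates$exact_recovery_rate, 1.0)
})
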