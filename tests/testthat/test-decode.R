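test_that("pool_profile routes a single sample into exactly its pools", {
  d <- ref_design()
  supp3 <- which(as.matrix(d)[, 3] == 1)
  x <- numeric(15)
  x[3] <- 1000
  y <- pool_profile(x, d)
  expect_equal(unname(which(y > 0)), unname(supp3))
  expect_equal(unname(y[supp3]), c(1000, 1000))
  expect_equal(unname(pool_profile(numeric(15), d)), numeric(12))
  expect_equal(unname(pool_profile(rep(1, 15), d)),
               unname(rowSums(as.matrix(d))))
})

test_that("the forward operator is linear and rejects invalid input", {
  d <- ref_design()
  set.seed(42)
  for (i in 1:20) {
    x <- runif(15, 0, 1e4)
    w <- runif(15, 0, 1e4)
    a <- runif(1, 0, 5)
    b <- runif(1, 0, 5)
    expect_equal(pool_profile(a * x + b * w, d),
                 a * pool_profile(x, d) + b * pool_profile(w, d),
                 tolerance = 1e-12)
  }
  expect_error(pool_profile(c(-1, rep(0, 14)), d), "nonnegative")
  expect_error(pool_profile(rep(0, 10), d), "length")
  bad_w <- matrix(1, 12, 15) # nonzero where the design is zero
  expect_error(pool_profile(rep(1, 15), d, weights = bad_w), "zero")
  good_w <- as.matrix(d) * 0.5
  expect_equal(pool_profile(rep(2, 15), d, weights = good_w),
               pool_profile(rep(1, 15), d))
})

test_that("decode_profile solves the known small program exactly", {
  # columns {1,2},{3,4},{1,3},{2,4}: feasible set is 1-dimensional and
  # |5 - t| + 3|t| is minimized at t = 0, so x = (5, 0, 0, 0)
  d <- design_from_supports(4, list(c(1, 2), c(3, 4), c(1, 3), c(2, 4)))
  fit <- decode_profile(d, c(5, 5, 0, 0))
  expect_equal(unname(fit$x_hat), c(5, 0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$l1_norm, 5, tolerance = 1e-9)
  expect_equal(fit$residual_l1, 0, tolerance = 1e-7)
  expect_identical(fit$status, "optimal")

  # zero measurements decode to the zero profile
  z <- decode_profile(d, rep(0, 4))
  expect_equal(unname(z$x_hat), numeric(4))
  expect_equal(z$l1_norm, 0)
})

test_that("1-sparse profiles are recovered across four orders of magnitude", {
  d <- ref_design()
  expect_true(verify_expansion(d, 2, 0.25)$is_expander)
  for (mag in c(0.5, 5, 50, 500, 5000)) {
    for (sgn in c(1, -1)) {
      for (j in c(1, 8, 15)) {
        x <- numeric(15)
        x[j] <- sgn * mag
        fit <- decode_profile(d, pool_profile(abs(x), d) * sgn)
        expect_lt(max(abs(fit$x_hat - x)), 1e-6 * mag)
      }
    }
  }
})

test_that("the decoded optimum matches the exhaustive support oracle", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    m <- sample(3:6, 1)
    A <- matrix(rbinom(m * n, 1, 0.45), m, n)
    k <- sample(1:2, 1)
    x <- numeric(n)
    x[sample(n, k)] <- rnorm(k, 0, 10)
    y <- as.vector(A %*% x)
    fit <- smartpool:::l1_decode_lp(A, y, nonnegative = FALSE, baseline = NULL,
                                    delta = 0, tol = 1e-9)
    expect_identical(fit$status, "optimal")
    expect_equal(fit$objective, oracle_l1_min(A, y), tolerance = 1e-6)
    # the true generator is feasible, so the optimum cannot exceed its norm
    expect_lte(fit$objective, sum(abs(x)) + 1e-8)
  }
})

test_that("nonnegative and relaxed decoding behave as documented", {
  d <- ref_design()
  x <- numeric(15)
  x[4] <- 100
  y <- pool_profile(x, d)
  nn <- decode_profile(d, y, decode_options(nonnegative = TRUE))
  expect_true(all(nn$x_hat >= 0))
  expect_equal(unname(nn$x_hat), x, tolerance = 1e-8)
  # delta-relaxed decoding of slightly perturbed measurements stays feasible;
  # perturb only non-empty pools so the equality program remains consistent
  y_noisy <- y + c(0, 0.5, -0.5, rep(0, 9))
  rel <- decode_profile(d, y_noisy, decode_options(noise_tolerance = 2))
  expect_identical(rel$status, "optimal")
  expect_lte(rel$residual_l1, 2 + 1e-6)
  # and its l1 norm can only be smaller than the equality-constrained fit
  eq <- decode_profile(d, y_noisy)
  expect_lte(rel$l1_norm, eq$l1_norm + 1e-8)
})

test_that("baseline estimation recovers shared constants", {
  d6 <- build_design(15, 6, 2, seed = 1) # all 15 supports used: no empty pool
  const <- rep(3.25, 15)
  expect_equal(estimate_baseline(pool_profile(const, d6), d6), 3.25)
  expect_equal(estimate_baseline(rep(0, 6), d6), 0)
  # 1 spike on zero background touches d = 2 pools; 10 of 12 ratios are zero
  d_cov <- design_from_supports(12, lapply(1:12, function(i) {
    c(i, i %% 12 + 1)
  })) # cyclic cover, no empty pools
  y2 <- pool_profile(c(777, rep(0, 11)), d_cov)
  expect_equal(estimate_baseline(y2, d_cov), 0)
  # empty pools are an explicit error
  d <- ref_design() # seed-7 design happens to leave pools 1 and 9 empty
  expect_error(estimate_baseline(pool_profile(numeric(15), d), d), "empty pool")
})

test_that("centered decoding recovers baseline-plus-spike profiles exactly", {
  d <- ref_design()
  x <- rep(256, 15)
  x[9] <- 2048 # up spike
  fit <- decode_profile(d, pool_profile(x, d),
                        decode_options(center_baseline = TRUE))
  expect_lt(max(abs(fit$x_hat - x)), 1e-6)
  expect_equal(fit$baseline, 256, tolerance = 1e-9)
  x[9] <- 32 # down spike
  fit2 <- decode_profile(d, pool_profile(x, d),
                         decode_options(center_baseline = TRUE))
  expect_lt(max(abs(fit2$x_hat - x)), 1e-6)
  # nonnegative + centered never dips below zero
  fit3 <- decode_profile(d, pool_profile(x, d),
                         decode_options(center_baseline = TRUE,
                                        nonnegative = TRUE))
  expect_true(all(fit3$x_hat >= -1e-9))
})

test_that("decode_matrix is row-wise consistent and preserves order", {
  d <- ref_design()
  x1 <- numeric(15); x1[2] <- 50
  x2 <- numeric(15); x2[11] <- 900
  meas <- rbind(a = pool_profile(x1, d), b = pool_profile(x2, d))
  dec <- decode_matrix(d, meas)
  expect_identical(rownames(dec$expression), c("a", "b"))
  one <- decode_profile(d, meas[1, ])
  expect_equal(dec$expression[1, ], one$x_hat)
  # permuting gene rows permutes results identically
  dec_p <- decode_matrix(d, meas[c(2, 1), ])
  expect_equal(dec_p$expression, dec$expression[c(2, 1), ])
  # missing values are an error naming the gene
  meas_na <- meas
  meas_na[2, 3] <- NA
  expect_error(decode_matrix(d, meas_na), "gene 'b'")
})

test_that("log2-scale measurements are linearized before decoding", {
  d <- ref_design()
  # strictly positive profile so every pooled measurement has a finite log2
  x <- rep(4, 15); x[5] <- 1024
  y <- pool_profile(x, d)
  meas_log <- matrix(log2(y), 1, 12, dimnames = list("g1", names(y)))
  dec <- decode_matrix(d, meas_log,
                       decode_options(scale = "log2", center_baseline = TRUE))
  expect_equal(unname(dec$expression[1, ]), x, tolerance = 1e-6)
  expect_true(!is.null(dec$expression_log2))
  expect_equal(dec$expression_log2, log2(pmax(dec$expression, 0) + 1))
})
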