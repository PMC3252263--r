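test_that("a noiseless quadratic is recovered exactly and classified Type I", {
  true_c <- c(0, -0.3, 0.3)  # -0.3 * phi * (1 - phi)
  gen <- prc_model(true_c, coupling_sign = "excitatory")
  samples <- generate_measurements(gen, n_samples = 1000, seed = 5)
  fit <- fit_prc(samples)
  expect_equal(attr(fit, "fit_degree"), 2L)
  # binning leaves a small Jensen gap (bin mean of f vs f at the bin center)
  expect_lt(max(abs(fit$mean_coeffs - true_c)), 1e-3)
  expect_identical(fit$prc_type, "I")
})

test_that("fit coefficients equal a normal-equations solution on the binned means", {
  gen <- make_template("exc_II")
  samples <- generate_measurements(gen, n_samples = 2000, seed = 11)
  fit <- fit_prc(samples)
  deg <- attr(fit, "fit_degree")

  # independent oracle: rebuild the binned means (applying the same
  # excitatory late-delay filter) and solve X'X b = X'y directly
  rec <- samples$records
  rec <- rec[!(rec$phase > 0.9 & rec$resetting > 0), ]
  bins <- bin_resetting(rec$phase, rec$resetting)
  X <- outer(bins$phase, 0:deg, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% bins$mean)[, 1]
  expect_lt(max(abs(fit$mean_coeffs - unname(beta))), 1e-8)

  # and the fit recovers the generating curve within the noise scale (away
  # from the causal-limit region, clamped from ~0.66 for this shape, where
  # rejection truncation biases the measurements upward)
  grid <- seq(0.02, 0.6, length.out = 200)
  expect_lt(max(abs(evaluate_prc(fit, grid) - evaluate_prc(gen, grid))), 0.04)
})

test_that("Type II structure survives fitting from noisy samples", {
  gen <- make_template("exc_II")
  samples <- generate_measurements(gen, n_samples = 2000, seed = 21)
  fit <- fit_prc(samples)
  expect_identical(fit$prc_type, "II")
  expect_gte(attr(fit, "fit_degree"), 3L)
})

test_that("fitting is idempotent on noiseless resamples of a fitted model", {
  fit1 <- fit_prc(generate_measurements(make_template("inh_II"),
                                        n_samples = 2000, seed = 31))
  noiseless <- prc_model(fit1$mean_coeffs, coupling_sign = "inhibitory")
  fit2 <- fit_prc(generate_measurements(noiseless, n_samples = 1500,
                                        seed = 32))
  grid <- seq(0.01, 0.99, length.out = 200)
  expect_lt(max(abs(evaluate_prc(fit2, grid) - evaluate_prc(fit1, grid))),
            2e-3)
})

test_that("too few samples or unfillable bins are refused", {
  gen <- make_template("exc_I")
  expect_error(generate_measurements(gen, n_samples = 299), "n_samples")
  s <- generate_measurements(gen, n_samples = 400, seed = 1)
  s$records <- s$records[1:250, ]
  expect_error(fit_prc(s), "at least 300")
  expect_error(bin_resetting(c(0.1, 0.9), c(0, 0)), "merging")
})

test_that("sparse phase regions are pooled with neighbors instead of failing", {
  gen <- make_template("inh_I")
  set.seed(7)
  phase <- stats::rbeta(600, 2, 2)  # thin coverage near 0 and 1
  resetting <- sample_noisy_resetting(gen, phase)
  fit <- fit_prc(prc_measurements(phase, resetting, "inhibitory"))
  expect_gt(attr(fit, "n_bins_merged"), 0L)
  expect_identical(fit$prc_type, "I")
})

test_that("spurious late delays are dropped from excitatory fits only", {
  gen <- make_template("exc_I")
  samples <- generate_measurements(gen, n_samples = 1500, seed = 9)
  # contaminate late phases with small positive (delay) values
  spur <- prc_measurements(
    c(samples$records$phase, stats::runif(30, 0.92, 0.99)),
    c(samples$records$resetting, stats::runif(30, 0.01, 0.05)),
    coupling_sign = "excitatory")
  fit <- fit_prc(spur)
  expect_gte(attr(fit, "n_dropped_spurious"), 30L)
  expect_identical(fit$prc_type, "I")

  inh <- generate_measurements(make_template("inh_I"), n_samples = 1500,
                               seed = 10)
  expect_identical(attr(fit_prc(inh), "n_dropped_spurious"), 0L)
})

test_that("fitted envelopes bracket the mean and sigma is non-negative", {
  for (nm in c("exc_I", "inh_II")) {
    fit <- fit_prc(generate_measurements(make_template(nm),
                                         n_samples = 2000, seed = 13))
    expect_true(attr(fit, "envelope_ok"))
    grid <- seq(0, 0.999, length.out = 400)
    expect_true(all(prc_sigma(fit, grid) >= 0))
  }
})
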