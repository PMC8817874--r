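test_that("scale weight follows alpha * log(r + 1) / r and decreases in r", {
  expect_equal(scale_weight(1, 1), log(2))
  expect_equal(scale_weight(2, 1), log(3) / 2)
  expect_equal(scale_weight(1, 2), 2 * log(2))
  w <- scale_weight(1:8, 1)
  expect_true(all(diff(w) < 0))
  expect_error(scale_weight(0), "scale index")
  expect_error(scale_weight(1, alpha = -1), "alpha")
})

test_that("MAD noise estimator is robust, homogeneous and accurate", {
  expect_equal(estimate_global_noise_std(matrix(0, 8, 8)), 0)
  x <- nsstkad:::with_seed(5, matrix(stats::rnorm(512^2, 0, 10), 512, 512))
  est <- estimate_global_noise_std(x)
  expect_lt(abs(est - 10) / 10, 0.03)
  expect_equal(estimate_global_noise_std(3 * x), 3 * est)
  # pooling over a list of subbands
  expect_equal(estimate_global_noise_std(list(x, x)), est)
  expect_error(estimate_global_noise_std(list()), "at least one")
})

test_that("subband variance is the mean squared coefficient", {
  expect_equal(subband_noise_variance(matrix(0, 4, 4)), 0)
  expect_equal(subband_noise_variance(matrix(c(1, -1, 1, -1), 2)), 1)
  expect_equal(subband_noise_variance(matrix(c(3, 4), 1)), 12.5)
})

test_that("threshold rules give their closed-form values", {
  pb <- threshold_params(phi = 1, rule = "bayes")
  # bayes rule: S = theta * W(r) * phi^2 / sigma_signal
  expect_equal(compute_threshold(1, pb, subband_var = 2), log(2))
  # noiseless limit: nothing thresholded
  p0 <- threshold_params(phi = 0, rule = "bayes")
  expect_equal(compute_threshold(1, p0, subband_var = 5), 0)
  # pure-noise subband: fully suppressed
  expect_identical(compute_threshold(1, pb, subband_var = 0.5), Inf)
  # literal rule: S = theta * W(r) * phi * sqrt(var)
  pl <- threshold_params(phi = 2, rule = "literal")
  expect_equal(compute_threshold(2, pl, subband_var = 9),
               scale_weight(2) * 2 * 3)
  # universal rule: finest scale gets the full universal threshold
  pu <- threshold_params(phi = 3)
  expect_equal(compute_threshold(1, pu, subband_var = 1, n_coeff = 4096),
               3 * sqrt(2 * log(4096)))
  # decreasing in scale, scaling in theta
  s1 <- compute_threshold(1, pu, 1, n_coeff = 4096)
  s2 <- compute_threshold(2, pu, 1, n_coeff = 4096)
  expect_lt(s2, s1)
  pu2 <- threshold_params(theta = 2, phi = 3)
  expect_equal(compute_threshold(1, pu2, 1, n_coeff = 4096), 2 * s1)
  expect_error(compute_threshold(1, pu, 1), "n_coeff")
})

test_that("hard thresholding keeps, zeroes and is idempotent", {
  x <- matrix(c(3, -0.5, 2), 1)
  expect_equal(hard_threshold(x, 2), matrix(c(3, 0, 2), 1))
  expect_identical(hard_threshold(x, 0), x)
  expect_equal(hard_threshold(x, Inf), matrix(c(0, 0, 0), 1))
  y <- random_image(32, seed = 2, lo = -50, hi = 50)
  t1 <- hard_threshold(y, 10)
  expect_identical(hard_threshold(t1, 10), t1)
  # nothing survives with magnitude in (0, S)
  expect_false(any(abs(t1) > 0 & abs(t1) < 10))
  # monotone suppression in S
  counts <- vapply(c(0, 5, 10, 20, 50), function(S)
    sum(hard_threshold(y, S) != 0), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("thresholding a noiseless phantom is a near no-op end to end", {
  ph <- make_phantom(size = 128)
  fb <- nsst_filterbank(c(128, 128), 3, c(8, 8, 4))
  sb <- nsst_forward(ph, fb)
  th <- threshold_subbands(sb, threshold_params(), noise_gain = fb$noise_gain)
  rec <- nsst_inverse(th$coeffs, fb)
  # near no-op: the thresholded reconstruction stays far above 50 dB
  expect_gt(psnr(ph, rec), 50)
  # with clean input the estimated noise level is tiny
  expect_lt(th$phi, 0.5)
})

test_that("the global threshold variant uses one threshold everywhere", {
  sb <- nsst_forward(random_image(64, seed = 9), nsst_filterbank(c(64, 64), 2, c(4, 4)))
  th <- threshold_subbands(sb, threshold_params(phi = 5), scale_weighted = FALSE)
  expect_true(all(unlist(th$thresholds) == 15))
})
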