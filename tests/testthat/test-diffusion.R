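test_that("kernel similarity is Gaussian in the gray difference", {
  expect_equal(kernel_value(5, 5, 2), 1)
  expect_equal(kernel_value(0, 1.5, 1.5), exp(-1 / 2))
  expect_equal(kernel_value(3, 7, 2.2), kernel_value(7, 3, 2.2))
  expect_error(kernel_value(0, 1, h = 0), "h")
})

test_that("feature-space gradient modulus matches a brute-force oracle", {
  J <- random_image(32, seed = 13)
  for (nb in c(4, 8)) {
    g <- kernel_gradient_modulus(J, h = 20, neighborhood = nb)
    expect_lt(max(abs(g - naive_kernel_gradient(J, 20, nb))), 1e-12)
    expect_true(all(g >= 0 & g <= sqrt(2) + 1e-12))
  }
})

test_that("gradient modulus limits: flat is zero, huge steps saturate", {
  expect_equal(kernel_gradient_modulus(matrix(7, 16, 16), h = 1),
               matrix(0, 16, 16))
  # single differing pixel of height h, 4-neighbourhood: the pixel next to
  # it has one neighbour at kernel distance 2 - 2 exp(-1/2)
  J <- matrix(0, 16, 16); J[8, 8] <- 3
  g <- kernel_gradient_modulus(J, h = 3, neighborhood = 4)
  expect_equal(g[8, 7], sqrt((2 - 2 * exp(-1 / 2)) / 4))
  # extreme step: modulus approaches sqrt(2) at the spike itself
  J[8, 8] <- 1e9
  g <- kernel_gradient_modulus(J, h = 1, neighborhood = 4)
  expect_equal(g[8, 8], sqrt(2))
})

test_that("diffusion threshold is a floored MAD, shift invariant", {
  expect_equal(diffusion_threshold(matrix(3, 5, 5), tau_floor = 1e-6), 1e-6)
  expect_equal(diffusion_threshold(c(1, 2, 3, 4, 100)), 1)
  f <- random_image(16, seed = 4)
  expect_equal(diffusion_threshold(f + 17), diffusion_threshold(f))
})

test_that("conductivity is 1 in flat regions and decays at edges", {
  expect_equal(diffusion_coefficient(0, 1, 1), 1)
  expect_equal(diffusion_coefficient(2, 0, 1), 1)
  expect_equal(diffusion_coefficient(2, 1, 1), exp(-1))
  m <- seq(0, 1.4, by = 0.1)
  expect_true(all(diff(diffusion_coefficient(m, 1, 0.5)) < 0))
  expect_lt(diffusion_coefficient(1e6, 1, 1), 1e-10)
  expect_error(diffusion_coefficient(1, 1, tau = 0), "tau")
})

test_that("local variance matches a brute-force sliding-window oracle", {
  expect_equal(local_grayscale_variance(matrix(9, 16, 16), 3),
               matrix(0, 16, 16))
  J <- random_image(20, seed = 6)
  for (w in c(3, 5)) {
    expect_lt(max(abs(local_grayscale_variance(J, w) -
                        naive_local_variance(J, w))), 1e-9)
  }
  # checkerboard, interior value known from the oracle
  cb <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)
  expect_equal(local_grayscale_variance(cb, 3)[6, 6],
               stats::var(as.vector(cb[5:7, 5:7])))
  # normalized field has mean one
  expect_equal(mean(local_grayscale_variance(J, 5, normalize = TRUE)), 1)
})

test_that("local variance field translates with the image", {
  J <- random_image(24, seed = 8)
  v <- local_grayscale_variance(J, 3)
  Js <- J[, c(2:24, 24)]  # shift left by one column (interior comparison)
  vs <- local_grayscale_variance(Js, 3)
  expect_equal(vs[3:22, 2:20], v[3:22, 3:21])
})

test_that("diffusion conserves the mean and respects the extremum principle", {
  ph <- make_phantom(size = 64)
  for (seed in 1:5) {
    noisy <- add_gaussian_noise(ph, 15, seed = seed)
    out <- kad_diffuse(noisy, kad_params(h = 20, iterations = 10))
    expect_lt(abs(mean(out) - mean(noisy)) / abs(mean(noisy)), 1e-9)
    expect_gte(min(out), min(noisy) - 1e-9)
    expect_lte(max(out), max(noisy) + 1e-9)
    expect_true(all(is.finite(out)))
  }
  # constant input is a fixed point
  const <- matrix(42, 32, 32)
  expect_equal(kad_diffuse(const, kad_params(h = 1, iterations = 5)), const)
})

test_that("with huge bandwidth the scheme reduces to linear heat diffusion", {
  # independent closed form: the linear 5-point explicit scheme has the
  # exact DFT multiplier (1 - dt + dt/2 (cos w1 + cos w2))^n on a periodic
  # domain; a centred delta keeps boundary effects below rounding.
  n <- 64; iters <- 10; dt <- 0.15
  x <- matrix(0, n, n); x[33, 33] <- 1
  out <- kad_diffuse(x, kad_params(h = 1e12, iterations = iters, dt = dt,
                                   window = 3))
  w <- nsstkad:::fft_freqs(n)
  mult <- (1 - dt + (dt / 2) * (outer(cos(w), cos(w), `+`)))^iters
  oracle <- Re(nsstkad:::ifft2(nsstkad:::fft2(x) * mult))
  # note: with h -> Inf the modulus is ~0 so conductivity is 1 everywhere
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("diffusion smooths monotonically and keeps edges in place", {
  # noisy step edge, heights 50/150
  nsstkad:::with_seed(42, {
    img <- matrix(50, 64, 64); img[, 33:64] <- 150
    img <- img + matrix(stats::rnorm(64 * 64, 0, 10), 64, 64)
  }) -> noisy
  tv <- function(m) sum(abs(m[, -1] - m[, -ncol(m)]))
  J <- noisy
  prev_tv <- tv(J)
  for (i in 1:10) {
    J <- kad_diffuse(J, kad_params(h = 15, iterations = 1))
    expect_lte(tv(J), prev_tv + 1e-9)
    prev_tv <- tv(J)
  }
  # within-region variance strictly decreases
  expect_lt(stats::var(as.vector(J[, 1:28])), stats::var(as.vector(noisy[, 1:28])))
  expect_lt(stats::var(as.vector(J[, 37:64])), stats::var(as.vector(noisy[, 37:64])))
  # the 50% crossing of the mean edge profile stays within 1 pixel
  crossing <- function(m) {
    prof <- colMeans(m)
    stats::approx(prof[30:36], 30:36, xout = 100)$y
  }
  expect_lt(abs(crossing(J) - crossing(noisy)), 1)
})

test_that("parameter validation rejects unstable or degenerate settings", {
  expect_error(kad_params(dt = 0.5), "dt")
  expect_error(kad_params(h = -1), "h")
  expect_error(kad_params(window = 4), "window")
  expect_error(kad_params(neighborhood = 6), "neighborhood")
  expect_error(kad_params(iterations = 0), "iterations")
})
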