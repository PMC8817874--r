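# The transform's correctness rests on two frame properties: the squared
# analysis windows tile the frequency plane (partition of unity) and the
# forward/inverse pair is a perfect-reconstruction tight frame.

shipped_configs <- list(
  list(shape = c(64, 64), scales = 3, dirs = c(8, 8, 4)),
  list(shape = c(128, 128), scales = 3, dirs = c(8, 8, 4)),
  list(shape = c(64, 96), scales = 2, dirs = c(4, 4)),
  list(shape = c(65, 64), scales = 1, dirs = 8)
)

test_that("filter bank squared windows sum to one at every frequency", {
  for (cf in shipped_configs) {
    fb <- nsst_filterbank(cf$shape, cf$scales, cf$dirs)
    expect_lt(partition_residual(fb), 1e-6)
  }
})

test_that("filter bank has the requested window count and validates input", {
  fb <- nsst_filterbank(c(64, 64), 3, c(8, 8, 4))
  expect_identical(vapply(fb$windows, length, 0L), c(8L, 8L, 4L))
  expect_identical(dim(fb$lowpass), c(64L, 64L))
  expect_error(nsst_filterbank(c(16, 16), 3, c(8, 8, 4)), "too small")
  expect_error(nsst_filterbank(c(64, 64), 2, c(8, 6)), "powers of two")
  expect_error(nsst_filterbank(c(64, 64), 2, c(8)), "one entry per scale")
})

test_that("directional windows mirror across the frequency diagonal", {
  fb <- nsst_filterbank(c(64, 64), 2, c(8, 4))
  for (j in 1:2) {
    d <- fb$directions[j]
    for (k in seq_len(d)) {
      km <- nsstkad:::mirror_direction(k, d)
      expect_lt(max(abs(t(fb$windows[[j]][[k]]) - fb$windows[[j]][[km]])),
                1e-10)
    }
  }
})

test_that("constants live entirely in the low-pass subband", {
  fb <- nsst_filterbank(c(64, 64), 3, c(8, 8, 4))
  sb <- nsst_forward(matrix(100, 64, 64), fb)
  hi_max <- max(vapply(unlist(sb$high, recursive = FALSE),
                       function(m) max(abs(m)), 0))
  expect_lt(hi_max, 1e-8 * 100)
  rec <- nsst_inverse(sb, fb)
  expect_lt(max(abs(rec - 100)), 1e-8)
})

test_that("forward transform is linear", {
  fb <- nsst_filterbank(c(64, 64), 2, c(4, 4))
  x <- random_image(64, seed = 11)
  y <- random_image(64, seed = 12)
  a <- 2.5; b <- -0.75
  s1 <- nsst_forward(a * x + b * y, fb)
  sx <- nsst_forward(x, fb)
  sy <- nsst_forward(y, fb)
  expect_lt(max(abs(s1$low - (a * sx$low + b * sy$low))), 1e-9 * 255)
  for (j in 1:2) for (k in 1:4)
    expect_lt(max(abs(s1$high[[j]][[k]] -
                        (a * sx$high[[j]][[k]] + b * sy$high[[j]][[k]]))),
              1e-9 * 255)
})

test_that("the frame is tight: subband energies sum to the image energy", {
  fb <- nsst_filterbank(c(64, 64), 3, c(8, 8, 4))
  # impulse image
  x <- matrix(0, 64, 64); x[32, 32] <- 1
  sb <- nsst_forward(x, fb)
  e <- sum(sb$low^2) + sum(vapply(unlist(sb$high, recursive = FALSE),
                                  function(m) sum(m^2), 0))
  expect_equal(e, sum(x^2), tolerance = 1e-9)
  # and for a generic image
  y <- random_image(64, seed = 21)
  sby <- nsst_forward(y, fb)
  ey <- sum(sby$low^2) + sum(vapply(unlist(sby$high, recursive = FALSE),
                                    function(m) sum(m^2), 0))
  expect_equal(ey / sum(y^2), 1, tolerance = 1e-9)
})

test_that("forward/inverse round trip is exact to 1e-6", {
  for (cf in shipped_configs) {
    fb <- nsst_filterbank(cf$shape, cf$scales, cf$dirs)
    x <- random_image(cf$shape[1], cf$shape[2], seed = sum(cf$shape))
    expect_lt(max(abs(nsst_inverse(nsst_forward(x, fb), fb) - x)), 1e-6)
  }
  # and on a structured phantom
  fb <- nsst_filterbank(c(128, 128), 3, c(8, 8, 4))
  ph <- make_phantom(size = 128)
  expect_lt(max(abs(nsst_inverse(nsst_forward(ph, fb), fb) - ph)), 1e-6)
})

test_that("all-zero coefficients reconstruct the zero image", {
  fb <- nsst_filterbank(c(64, 64), 2, c(4, 4))
  sb <- nsst_forward(random_image(64, seed = 3), fb)
  sb$low[] <- 0
  for (j in seq_along(sb$high))
    for (k in seq_along(sb$high[[j]])) sb$high[[j]][[k]][] <- 0
  expect_equal(nsst_inverse(sb, fb), matrix(0, 64, 64))
})

test_that("incompatible shapes and banks are rejected", {
  fb <- nsst_filterbank(c(64, 64), 2, c(4, 4))
  expect_error(nsst_forward(matrix(0, 32, 32), fb), "shape")
  sb <- nsst_forward(matrix(0, 64, 64), fb)
  fb2 <- nsst_filterbank(c(64, 64), 2, c(8, 8))
  expect_error(nsst_inverse(sb, fb2), "incompatible")
})

test_that("an oriented edge concentrates energy in the nearest directions", {
  fb <- nsst_filterbank(c(64, 64), 1, 8)
  img <- matrix(0, 64, 64)
  img[, 33:64] <- 100  # vertical step edge
  sb <- nsst_forward(img, fb)
  en <- vapply(sb$high[[1]], function(m) sum(m^2), 0)
  top3 <- sum(sort(en, decreasing = TRUE)[1:3])
  expect_gt(top3 / sum(en), 0.5)
})
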