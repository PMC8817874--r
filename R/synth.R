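#' Synthetic test images and noise generators
#'
#' The package ships no binary image data; every input used in examples,
#' tests and benchmarks is generated procedurally. Two families are
#' provided: a textured natural-image stand-in (smooth shading, step edges,
#' periodic stripes to stress edge preservation) and an ultrasound-like
#' kidney phantom with a hyperechoic stone and its acoustic shadow.
#' Images are numeric matrices on the 0--255 intensity scale; intermediate
#' values are kept in floating point and only clipped at I/O boundaries.
#'
#' @name synth
NULL

#' Add i.i.d. Gaussian white noise to a grayscale image
#'
#' Corrupts `img` with additive zero-mean Gaussian noise of standard
#' deviation `sigma` (on the 0--255 intensity scale) and clips the result
#' to \[0, 255\]. With a fixed `seed` the output is bit-identical across
#' calls; the caller's RNG stream is left untouched.
#'
#' @param img Numeric matrix, grayscale image on the 0--255 scale.
#' @param sigma Noise standard deviation, `>= 0`.
#' @param seed Integer seed controlling the noise realisation.
#' @param clip Clip the result to \[0, 255\]? Set `FALSE` to inspect the
#'   unclipped field (e.g. when measuring noise statistics).
#' @return Noisy image, same dimensions as `img`.
#' @seealso [add_speckle_noise()]
#' @export
#' @examples
#' ph <- make_phantom(size = 128)
#' noisy <- add_gaussian_noise(ph, sigma = 15, seed = 1)
add_gaussian_noise <- function(img, sigma, seed = 1L, clip = TRUE) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(img)
  noise <- with_seed(seed, matrix(stats::rnorm(length(img), 0, sigma),
                                  nrow(img), ncol(img)))
  out <- img + noise
  if (clip) out <- clip255(out)
  out
}

#' Add unit-mean multiplicative speckle noise
#'
#' Multiplies each pixel by an i.i.d. Gamma-distributed factor with mean 1
#' and standard deviation `sigma / 255`, a fully-developed-speckle style
#' approximation of the granular interference seen in coherent ultrasound.
#' The Gamma shape is `k = (255 / sigma)^2` so that `sd(n) = sigma / 255`.
#'
#' @inheritParams add_gaussian_noise
#' @param sigma Controls multiplier spread: `sd(multiplier) = sigma / 255`.
#' @return Speckled image, same dimensions as `img`.
#' @export
add_speckle_noise <- function(img, sigma, seed = 1L, clip = TRUE) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(img)
  rel <- sigma / 255
  shape <- 1 / rel^2
  mult <- with_seed(seed, matrix(stats::rgamma(length(img), shape = shape,
                                               rate = shape),
                                 nrow(img), ncol(img)))
  out <- img * mult
  if (clip) out <- clip255(out)
  out
}

#' Ultrasound-like kidney phantom
#'
#' Deterministic noiseless phantom emulating the sonographic appearance of
#' urolithiasis: an elliptical organ on a darker background, a bright
#' (hyperechoic) disc for the stone and a darker column beneath it for the
#' acoustic shadow the stone casts. Intensity ordering
#' `stone_level > organ_level > shadow_level` is enforced. A light smoothing
#' softens region borders so edges span a couple of pixels, as in real
#' B-mode imagery.
#'
#' @param size Image side length in pixels, between 64 and 1024.
#' @param background_level,organ_level,stone_level,shadow_level Region
#'   intensities on the 0--255 scale.
#' @param stone_center Length-2 numeric, (row, col) of the stone centre in
#'   pixels; default just above the organ centre.
#' @param stone_radius Stone radius in pixels; default `0.055 * size`.
#' @return `size` x `size` numeric matrix.
#' @export
#' @examples
#' ph <- make_phantom(size = 128)
#' mean(ph)
make_phantom <- function(size = 256,
                         background_level = 30,
                         organ_level = 110,
                         stone_level = 220,
                         shadow_level = 55,
                         stone_center = NULL,
                         stone_radius = NULL) {
  if (size < 64 || size > 1024)
    stop("`size` must be between 64 and 1024", call. = FALSE)
  if (!(stone_level > organ_level && organ_level > shadow_level))
    stop("need stone_level > organ_level > shadow_level", call. = FALSE)
  if (is.null(stone_center)) stone_center <- c(0.42, 0.5) * size
  if (is.null(stone_radius)) stone_radius <- 0.055 * size
  if (stone_center[1] - stone_radius < 1 || stone_center[1] + stone_radius > size ||
      stone_center[2] - stone_radius < 1 || stone_center[2] + stone_radius > size)
    stop("stone geometry falls outside the image", call. = FALSE)

  r <- matrix(seq_len(size), size, size)
  cc <- t(r)
  img <- matrix(background_level, size, size)

  # organ: tilted ellipse centred in the frame
  cy <- 0.5 * size; cx <- 0.5 * size
  a <- 0.40 * size; b <- 0.30 * size
  th <- pi / 9
  u <- (r - cy) * cos(th) + (cc - cx) * sin(th)
  v <- -(r - cy) * sin(th) + (cc - cx) * cos(th)
  organ <- (u / a)^2 + (v / b)^2 <= 1
  img[organ] <- organ_level

  # acoustic shadow: column below the stone, clipped to the organ footprint
  half_w <- stone_radius
  shadow <- r >= stone_center[1] &
    abs(cc - stone_center[2]) <= half_w & organ
  img[shadow] <- shadow_level

  # hyperechoic stone drawn last so it sits on top of its own shadow
  stone <- (r - stone_center[1])^2 + (cc - stone_center[2])^2 <= stone_radius^2
  img[stone] <- stone_level

  # soften borders over ~2 px
  k <- c(0.25, 0.5, 0.25)
  conv_sep(img, k)
}

#' Procedural textured test image
#'
#' Deterministic grayscale target combining smooth shading, high-contrast
#' step edges (discs and a diagonal split) and a periodic stripe patch, so
#' denoisers are stressed on both flat regions and fine oriented texture.
#' A seeded low-pass random texture adds mild irregularity. The dynamic
#' range spans more than half of 0--255 and the disc edges have contrast
#' above 64 levels by construction.
#'
#' @param size Side length in pixels, `>= 64`.
#' @param seed Integer seed for the low-pass texture component.
#' @return `size` x `size` numeric matrix on the 0--255 scale.
#' @export
make_natural_test_image <- function(size = 512, seed = 1L) {
  if (size < 64) stop("`size` must be at least 64", call. = FALSE)
  r <- matrix(seq_len(size), size, size)
  cc <- t(r)
  s <- size

  # smooth diagonal shading 60..170
  img <- 60 + 110 * (r + cc) / (2 * s)

  # diagonal step edge across the lower-left triangle
  img[cc < 0.35 * s & r > 0.6 * s] <- 40

  # two high-contrast discs
  d1 <- (r - 0.3 * s)^2 + (cc - 0.3 * s)^2 <= (0.12 * s)^2
  img[d1] <- 215
  d2 <- (r - 0.72 * s)^2 + (cc - 0.7 * s)^2 <= (0.09 * s)^2
  img[d2] <- 35

  # periodic stripe patch (period 8 px) in the upper-right quadrant
  patch <- r < 0.45 * s & cc > 0.55 * s
  img[patch] <- img[patch] + 45 * sin(2 * pi * (r[patch] + 2 * cc[patch]) / 8)

  # seeded smooth texture, low-pass filtered white noise
  tex <- with_seed(seed, matrix(stats::rnorm(s * s), s, s))
  g <- exp(-0.5 * ((-6:6) / 2.5)^2); g <- g / sum(g)
  tex <- conv_sep(tex, g)
  img <- img + 10 * tex / stats::sd(tex)

  clip255(img)
}
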