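#' Image-quality metrics: PSNR, SSIM, EPI
#'
#' Full-reference metrics used to score denoising results against a clean
#' reference: peak signal-to-noise ratio (dB), the structural similarity
#' index (Gaussian-weighted 11x11 windows, standard stabilizer constants)
#' and an edge-preservation index defined as the Pearson correlation of
#' Laplacian high-pass versions of the two images. Because the transform
#' stages filter periodically, metrics accept a `crop` argument that
#' excludes a border before scoring.
#'
#' @name metrics
NULL

crop_border <- function(img, crop) {
  if (crop <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (2 * crop >= min(nr, nc))
    stop("`crop` leaves no pixels", call. = FALSE)
  img[(crop + 1):(nr - crop), (crop + 1):(nc - crop), drop = FALSE]
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; identical images give `Inf`.
#'
#' @param ref,test Numeric matrices of identical shape.
#' @param peak Peak intensity (default 255 for 8-bit data).
#' @param crop Border width in pixels to exclude.
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
#' @examples
#' psnr(matrix(0, 8, 8), matrix(16, 8, 8))  # ~24.05 dB
psnr <- function(ref, test, peak = 255, crop = 0) {
  assert_gray(ref, "ref"); assert_gray(test, "test")
  assert_same_shape(ref, test)
  if (peak <= 0) stop("`peak` must be > 0", call. = FALSE)
  ref <- crop_border(ref, crop); test <- crop_border(test, crop)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

gaussian_kernel_1d <- function(sigma = 1.5, radius = 5) {
  x <- (-radius):radius
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (`sigma = 1.5`),
#' stabilizers `C1 = (0.01 * peak)^2`, `C2 = (0.03 * peak)^2`, population
#' (not sample) covariances, mirrored boundaries, and a half-window border
#' excluded from the final average -- the common reference formulation.
#' Symmetric in its two arguments; equals 1 exactly for identical images.
#'
#' @inheritParams psnr
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(ref, test, peak = 255, crop = 0) {
  assert_gray(ref, "ref"); assert_gray(test, "test")
  assert_same_shape(ref, test)
  ref <- crop_border(ref, crop); test <- crop_border(test, crop)
  if (min(dim(ref)) < 11)
    stop("images must be at least 11 pixels in each dimension", call. = FALSE)
  k <- gaussian_kernel_1d(1.5, 5)
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  ux <- conv_sep(ref, k)
  uy <- conv_sep(test, k)
  uxx <- conv_sep(ref * ref, k)
  uyy <- conv_sep(test * test, k)
  uxy <- conv_sep(ref * test, k)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  vxy <- uxy - ux * uy
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(crop_border(S, 5))
}

laplacian_filter <- function(img) {
  shift_clamp(img, -1, 0) + shift_clamp(img, 1, 0) +
    shift_clamp(img, 0, -1) + shift_clamp(img, 0, 1) - 4 * img
}

#' Edge preservation index
#'
#' Pearson correlation between 3x3 Laplacian high-pass versions of the
#' reference and test images (mirrored boundary, mean-centred). Equals 1
#' for identical images and is invariant to constant intensity offsets;
#' blurring the test image drives it toward 0.
#'
#' @inheritParams psnr
#' @return EPI in `[-1, 1]`, or `NA` when either high-pass field has zero
#'   variance (degenerate constant images).
#' @export
epi <- function(ref, test, crop = 0) {
  assert_gray(ref, "ref"); assert_gray(test, "test")
  assert_same_shape(ref, test)
  ref <- crop_border(ref, crop); test <- crop_border(test, crop)
  hr <- laplacian_filter(ref)
  ht <- laplacian_filter(test)
  hr <- hr - mean(hr)
  ht <- ht - mean(ht)
  den <- sqrt(sum(hr^2) * sum(ht^2))
  if (den == 0) return(NA_real_)
  sum(hr * ht) / den
}

#' All three quality metrics at once
#'
#' @inheritParams psnr
#' @return A one-row data frame with columns `psnr_db`, `ssim`, `epi`.
#' @export
quality_report <- function(ref, test, peak = 255, crop = 0) {
  data.frame(psnr_db = psnr(ref, test, peak, crop),
             ssim = ssim(ref, test, peak, crop),
             epi = epi(ref, test, crop))
}
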