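# Comparison denoisers: Laplacian-pyramid nonlinear diffusion (LPND),
# plain shearlet thresholding, image-domain kernel diffusion, and a 3x3
# median filter. These are best-faith standard formulations used for
# relative benchmarking, not re-derivations of any particular published
# variant.

# Classic Perona-Malik diffusion with exponential conductivity
# c = exp(-(d/K)^2) on per-edge differences, zero-flux boundaries. K is
# re-estimated each iteration as a robust scale of the pooled differences.
pm_diffuse <- function(J, iterations = 10, dt = 0.15, K = NULL) {
  offs <- neighbor_offsets(4)
  for (it in seq_len(iterations)) {
    diffs <- lapply(offs, function(o) shift_clamp(J, o[1], o[2]) - J)
    Ki <- K
    if (is.null(Ki)) {
      Ki <- 1.4826 * stats::median(abs(unlist(diffs, use.names = FALSE)))
      if (Ki <= 0) Ki <- 1e-6 * max(diff(range(J)), 1)
    }
    flux <- matrix(0, nrow(J), ncol(J))
    for (d in diffs) flux <- flux + exp(-(d / Ki)^2) * d
    J <- J + dt * flux / length(offs)
  }
  J
}

# Nonsubsampled Laplacian pyramid: radial bandpass windows only (the NSST
# pyramid stage without the directional split).
pyramid_decompose <- function(img, n_scales) {
  nr <- nrow(img); nc <- ncol(img)
  wr <- matrix(fft_freqs(nr), nr, nc)
  wc <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  rr <- sqrt(wr^2 + wc^2)
  ft <- fft2(img)
  prev <- matrix(1, nr, nc)
  bands <- vector("list", n_scales)
  wins <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    lj <- radial_lowpass(rr, pi / 2^j, pi / 2^(j - 1))
    wins[[j]] <- sqrt(pmax(prev^2 - lj^2, 0))
    bands[[j]] <- Re(ifft2(ft * wins[[j]]))
    prev <- lj
  }
  list(bands = bands, low = Re(ifft2(ft * prev)),
       windows = wins, lowpass = prev)
}

pyramid_reconstruct <- function(dec) {
  acc <- fft2(dec$low) * dec$lowpass
  for (j in seq_along(dec$bands))
    acc <- acc + fft2(dec$bands[[j]]) * dec$windows[[j]]
  Re(ifft2(acc))
}

#' Laplacian-pyramid nonlinear diffusion baseline (LPND)
#'
#' Decomposes the image into a nonsubsampled Laplacian pyramid (radial
#' frequency bands) and runs Perona--Malik diffusion independently on each
#' band and on the low-pass residual, then recombines. Deterministic given
#' its configuration.
#'
#' @param img Numeric matrix on the 0--255 scale.
#' @param config A [denoise_config()]; its `nsst$scales`, `kad$iterations`
#'   and `kad$dt` fields are used.
#' @return Denoised image, same shape.
#' @export
denoise_lpnd <- function(img, config = denoise_config()) {
  assert_gray(img)
  dec <- pyramid_decompose(img, config$nsst$scales)
  it <- config$kad$iterations
  dt <- config$kad$dt
  dec$bands <- lapply(dec$bands, pm_diffuse, iterations = it, dt = dt)
  dec$low <- pm_diffuse(dec$low, iterations = it, dt = dt)
  pyramid_reconstruct(dec)
}

#' Plain shearlet hard-thresholding baseline
#'
#' Traditional NSST denoising: forward transform, one global hard
#' threshold `3 * theta * phi` applied to every directional subband
#' (no scale weighting), untouched low band, inverse transform.
#'
#' @inheritParams denoise_lpnd
#' @return Denoised image, same shape.
#' @export
denoise_nsst_only <- function(img, config = denoise_config()) {
  assert_gray(img)
  bank <- nsst_filterbank(dim(img), config$nsst$scales, config$nsst$directions)
  sb <- nsst_forward(img, bank)
  th <- threshold_subbands(sb, config$threshold, scale_weighted = FALSE)
  nsst_inverse(th$coeffs, bank)
}

#' Image-domain kernel-diffusion baseline (KDA)
#'
#' Runs [kad_diffuse()] directly on the image. When the configured
#' bandwidth is `NULL` it is set to `1.5 *` the image's estimated noise
#' standard deviation.
#'
#' @inheritParams denoise_lpnd
#' @return Denoised image, same shape.
#' @export
denoise_kda_only <- function(img, config = denoise_config()) {
  assert_gray(img)
  kad_diffuse(img, config$kad)
}

# 3x3 median filter with replicated borders.
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  stack <- matrix(0, nr * nc, 9L)
  i <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    i <- i + 1L
    stack[, i] <- shift_clamp(img, dr, dc)
  }
  matrix(apply(stack, 1L, stats::median), nr, nc)
}
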