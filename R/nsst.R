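#' Nonsubsampled shearlet transform (NSST)
#'
#' Shift-invariant multiscale, multidirectional image decomposition. The
#' frequency plane is partitioned by Meyer-type smooth windows: a radial
#' pyramid (nonsubsampled Laplacian pyramid realised in the Fourier domain)
#' splits scales, and smooth angular wedges -- the cone-adapted directional
#' windows of the shearlet system -- split each bandpass annulus into
#' oriented subbands. Squared analysis windows sum to one at every
#' frequency (a partition of unity), which makes the frame tight: applying
#' the same windows in synthesis reconstructs the image exactly, and all
#' subbands stay at full image resolution (no subsampling, hence no
#' pseudo-Gibbs shift artifacts).
#'
#' Windows are symmetric under frequency negation, so coefficients of a
#' real image are real. Filtering is periodic (native to FFT filtering);
#' border artifacts can be excluded from metrics via their `crop` argument.
#'
#' @name nsst
NULL

# Meyer smooth step: nu(0)=0, nu(1)=1, nu(t)+nu(1-t)=1, C^3 at the ends.
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Smooth radial low-pass: 1 on [0,a], cosine-Meyer transition on (a,b), 0 beyond.
radial_lowpass <- function(r, a, b) {
  out <- matrix(0, nrow(r), ncol(r))
  out[r <= a] <- 1
  tr <- r > a & r < b
  out[tr] <- cos(pi / 2 * meyer_nu((r[tr] - a) / (b - a)))
  out
}

fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  2 * pi * k / n
}

# Enforce conjugate symmetry W(xi) = W(-xi) on the DFT grid by averaging
# squared magnitudes with the frequency-negated copy. Needed because the
# +/- Nyquist identification on even-sized grids breaks the evenness of the
# continuous angular windows there; squared averaging keeps the partition
# of unity exact and makes filtered real images exactly real.
conj_symmetrize <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  flip <- w[c(1, nr:2), c(1, nc:2), drop = FALSE]
  sqrt((w^2 + flip^2) / 2)
}

# Angular window k of d: Meyer bump in orientation (angle mod pi), spacing
# pi/d, support two spacings wide, adjacent squared windows summing to 1.
angular_window <- function(phi, k, d) {
  delta <- pi / d
  centre <- (k - 0.5) * delta
  dist <- ((phi - centre + pi / 2) %% pi) - pi / 2
  t <- abs(dist) / delta
  out <- matrix(0, nrow(phi), ncol(phi))
  inside <- t < 1
  out[inside] <- cos(pi / 2 * meyer_nu(t[inside]))
  out
}

#' Build an NSST analysis/synthesis filter bank
#'
#' Constructs the frequency-domain windows for a given image shape:
#' one low-pass window plus `sum(directions_per_scale)` directional
#' windows. Scale 1 is the finest (highest-frequency annulus). The bank
#' satisfies the partition of unity
#' `lowpass^2 + sum over (scale, direction) of window^2 = 1` at every
#' frequency, which [nsst_inverse()] relies on for perfect reconstruction.
#'
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param n_scales Number of bandpass scales, `>= 1`.
#' @param directions_per_scale Integer vector, one power of two `>= 2` per
#'   scale (finest first).
#' @return An object of class `nsst_filterbank`: windows plus metadata,
#'   including each band's noise gain `mean(window^2)` (the variance factor
#'   mapping white image noise into that subband).
#' @export
#' @examples
#' fb <- nsst_filterbank(c(128, 128), n_scales = 3, directions_per_scale = c(8, 8, 4))
#' fb
nsst_filterbank <- function(image_shape, n_scales = 3,
                            directions_per_scale = c(8, 8, 4)) {
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop("`image_shape` must give two dimensions of at least 8 pixels",
         call. = FALSE)
  if (n_scales < 1)
    stop("`n_scales` must be at least 1", call. = FALSE)
  if (length(directions_per_scale) != n_scales)
    stop("`directions_per_scale` needs one entry per scale", call. = FALSE)
  d <- as.integer(directions_per_scale)
  if (any(d < 2) || any(bitwAnd(d, d - 1L) != 0L))
    stop("direction counts must be powers of two >= 2", call. = FALSE)
  if (min(image_shape) < 2^(n_scales + 2))
    stop(sprintf(
      "image of shape %dx%d is too small for %d scales (need min dim >= %d)",
      image_shape[1], image_shape[2], n_scales, 2^(n_scales + 2)),
      call. = FALSE)

  nr <- image_shape[1]; nc <- image_shape[2]
  wr <- matrix(fft_freqs(nr), nr, nc)
  wc <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  rr <- sqrt(wr^2 + wc^2)
  phi <- atan2(wc, wr) %% pi

  lows <- vector("list", n_scales)
  prev <- matrix(1, nr, nc)
  high <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    lj <- radial_lowpass(rr, pi / 2^j, pi / 2^(j - 1))
    band <- sqrt(pmax(prev^2 - lj^2, 0))
    high[[j]] <- lapply(seq_len(d[j]), function(k)
      conj_symmetrize(band * angular_window(phi, k, d[j])))
    lows[[j]] <- lj
    prev <- lj
  }

  bank <- structure(
    list(
      shape = as.integer(image_shape),
      n_scales = as.integer(n_scales),
      directions = d,
      lowpass = prev,
      windows = high,
      noise_gain = list(
        low = mean(prev^2),
        high = lapply(high, function(sc) vapply(sc, function(w) mean(w^2), 0))
      )
    ),
    class = "nsst_filterbank"
  )
  bank
}

#' @export
print.nsst_filterbank <- function(x, ...) {
  cat(sprintf(
    "NSST filter bank: %dx%d, %d scales, directions [%s], %d windows + lowpass\n",
    x$shape[1], x$shape[2], x$n_scales,
    paste(x$directions, collapse = ", "), sum(x$directions)))
  invisible(x)
}

#' Evaluate the bank's partition-of-unity residual
#'
#' Returns the maximum absolute deviation of
#' `lowpass^2 + sum |window|^2` from 1 over all frequencies. Values below
#' `1e-6` certify the tight-frame (perfect reconstruction) property.
#'
#' @param bank An [nsst_filterbank()].
#' @return Single number, the max-abs residual.
#' @export
partition_residual <- function(bank) {
  acc <- bank$lowpass^2
  for (sc in bank$windows)
    for (w in sc) acc <- acc + w^2
  max(abs(acc - 1))
}

# Index of the directional window mirrored across the frequency diagonal.
mirror_direction <- function(k, d) {
  ((d / 2 + 1 - k - 1) %% d) + 1
}

#' Forward NSST: decompose an image into subbands
#'
#' Linear, shift-invariant analysis: each subband is the inverse FFT of the
#' image spectrum multiplied by one analysis window. All subbands have the
#' source image's dimensions.
#'
#' @param img Numeric matrix matching `bank$shape`.
#' @param bank An [nsst_filterbank()].
#' @return Object of class `nsst_subbands`: `low` (matrix) and `high`
#'   (list over scales, each a list over directions of matrices). Scale 1
#'   is the finest.
#' @seealso [nsst_inverse()]
#' @export
nsst_forward <- function(img, bank) {
  assert_gray(img)
  if (!identical(dim(img), bank$shape))
    stop("image shape does not match the filter bank", call. = FALSE)
  ft <- fft2(img)
  high <- lapply(bank$windows, function(sc)
    lapply(sc, function(w) Re(ifft2(ft * w))))
  structure(
    list(low = Re(ifft2(ft * bank$lowpass)), high = high,
         shape = bank$shape, n_scales = bank$n_scales,
         directions = bank$directions),
    class = "nsst_subbands"
  )
}

#' @export
print.nsst_subbands <- function(x, ...) {
  cat(sprintf(
    "NSST subbands: %dx%d, %d scales, directions [%s]\n",
    x$shape[1], x$shape[2], x$n_scales,
    paste(x$directions, collapse = ", ")))
  invisible(x)
}

#' Inverse NSST: reconstruct an image from subbands
#'
#' Synthesis applies the same windows again and sums spectra; because the
#' squared windows form a partition of unity,
#' `nsst_inverse(nsst_forward(x, bank), bank)` equals `x` to within
#' floating-point rounding (max-abs error well below 1e-6).
#'
#' @param coeffs An `nsst_subbands` object from [nsst_forward()] (possibly
#'   with modified coefficient matrices of unchanged shape).
#' @param bank The [nsst_filterbank()] the coefficients were produced with
#'   (same shape, scales and direction counts).
#' @return Reconstructed image matrix.
#' @export
nsst_inverse <- function(coeffs, bank) {
  if (!inherits(coeffs, "nsst_subbands"))
    stop("`coeffs` must be an nsst_subbands object", call. = FALSE)
  if (!identical(coeffs$shape, bank$shape) ||
      !identical(coeffs$n_scales, bank$n_scales) ||
      !identical(coeffs$directions, bank$directions))
    stop("subbands and filter bank are incompatible", call. = FALSE)
  acc <- fft2(coeffs$low) * bank$lowpass
  for (j in seq_len(bank$n_scales))
    for (k in seq_along(bank$windows[[j]]))
      acc <- acc + fft2(coeffs$high[[j]][[k]]) * bank$windows[[j]][[k]]
  Re(ifft2(acc))
}
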