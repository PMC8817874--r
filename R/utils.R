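# Internal helpers shared across modules: image validation, symmetric
# padding, separable convolution, seeded RNG scoping.

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg),
         call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
  invisible(NULL)
}

clip255 <- function(img) pmin(pmax(img, 0), 255)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Symmetric (edge-duplicating mirror) padding: a b c -> b a | a b c | c b.
pad_symmetric <- function(img, p) {
  nr <- nrow(img); nc <- ncol(img)
  if (p >= nr || p >= nc)
    stop("padding width must be smaller than the image", call. = FALSE)
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  img[ri, ci, drop = FALSE]
}

# Separable correlation with a symmetric 1D kernel and mirrored boundary.
# Kernel length must be odd; identical to convolution for symmetric kernels.
conv_sep <- function(img, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  x <- pad_symmetric(img, p)
  nr <- nrow(img); nc <- ncol(img)
  # rows pass
  acc <- matrix(0, nr, nc + 2L * p)
  for (i in seq_len(k))
    acc <- acc + kernel[i] * x[(i - 1L) + seq_len(nr), , drop = FALSE]
  # columns pass
  out <- matrix(0, nr, nc)
  for (i in seq_len(k))
    out <- out + kernel[i] * acc[, (i - 1L) + seq_len(nc), drop = FALSE]
  out
}

# Moving-window sum over a w x w window with mirrored boundary.
box_sum <- function(img, w) {
  conv_sep_uniform(img, w)
}

conv_sep_uniform <- function(img, w) {
  conv_sep(img, rep(1, w))
}

# Shift a matrix by (dr, dc) with mirrored (edge-reflecting) boundary, so
# that out[i, j] = img[i + dr, j + dc] with out-of-range indices reflected.
shift_mirror <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  ri[ri < 1L] <- 2L - ri[ri < 1L]
  ri[ri > nr] <- 2L * nr - ri[ri > nr]
  ci[ci < 1L] <- 2L - ci[ci < 1L]
  ci[ci > nc] <- 2L * nc - ci[ci > nc]
  img[ri, ci, drop = FALSE]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Half-up rounding to `digits` decimals (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
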