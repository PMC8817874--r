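# Shared fixtures: all images are generated in code, none are stored.

random_image <- function(n, m = n, seed = 1, lo = 0, hi = 255) {
  nsstkad:::with_seed(seed, matrix(stats::runif(n * m, lo, hi), n, m))
}

# Brute-force w x w sliding-window sample variance with mirrored
# (edge-duplicating) boundary; independent oracle for
# local_grayscale_variance().
naive_local_variance <- function(J, w) {
  p <- (w - 1) %/% 2
  Jp <- nsstkad:::pad_symmetric(J, p)
  out <- matrix(0, nrow(J), ncol(J))
  for (i in seq_len(nrow(J)))
    for (j in seq_len(ncol(J)))
      out[i, j] <- stats::var(as.vector(Jp[i:(i + 2 * p), j:(j + 2 * p)]))
  out
}

# Brute-force per-pixel feature-space gradient modulus; independent oracle
# for kernel_gradient_modulus().
naive_kernel_gradient <- function(J, h, neighborhood = 4) {
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (neighborhood == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  nr <- nrow(J); nc <- ncol(J)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (o in offs) {
      vi <- min(max(i + o[1], 1), nr)
      vj <- min(max(j + o[2], 1), nc)
      Fuu <- 1; Fvv <- 1
      Fuv <- exp(-(J[i, j] - J[vi, vj])^2 / (2 * h^2))
      acc <- acc + (Fuu + Fvv - 2 * Fuv)
    }
    out[i, j] <- sqrt(acc / length(offs))
  }
  out
}
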