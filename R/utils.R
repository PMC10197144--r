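# Internal numerical helpers shared across modules.

# Orthonormal 2-D DFT pair: Parseval holds exactly (sum|x|^2 == sum|X|^2).
ft2 <- function(x) stats::fft(x) / sqrt(length(x))
ift2 <- function(X) stats::fft(X, inverse = TRUE) / sqrt(length(X))

# Move the DC sample between corner (index 1,1) and lattice center
# (index N%/%2 + 1). For even N the two are involutions of each other.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((n1 %/% 2 + 1):n1, seq_len(n1 %/% 2))
  i2 <- c((n2 %/% 2 + 1):n2, seq_len(n2 %/% 2))
  m[i1, i2, drop = FALSE]
}
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((n1 - n1 %/% 2 + 1):n1, seq_len(n1 - n1 %/% 2))
  i2 <- c((n2 - n2 %/% 2 + 1):n2, seq_len(n2 - n2 %/% 2))
  m[i1, i2, drop = FALSE]
}

# Centered coordinate vector for an N-sample lattice with spacing d:
# zero at index N %/% 2 + 1 (exact center for odd N).
centered_axis <- function(n, d) (seq_len(n) - 1 - n %/% 2) * d

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Otsu's threshold on a numeric matrix/vector (256-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}
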