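# Run expr with a local RNG state seeded from `seed`; the caller's
# .Random.seed is untouched, so every operation is a pure function of
# (inputs, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream-specific child seed so that independent stages fed from
# one user seed do not share random streams.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 69069 + sum(utf8ToInt(as.character(stream)))) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Teager-Kaiser energy operator, psi(x)_i = x_i^2 - x_{i-1} x_{i+1}
tkeo <- function(x) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
}

# Normalized Shannon entropy of a histogram of x over `bins` equal-width
# bins; 0 for a point mass, 1 for uniform occupancy.
norm_entropy <- function(x, bins = 30L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (diff(range(x)) <= 1e-9 * max(abs(x), 1)) return(0)
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log(p)) / log(bins)
}

# Analytic-signal magnitude via FFT (Hilbert envelope).
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Zero-phase FFT brick-wall bandpass, [lo, hi] in Hz.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)            # two-sided frequency axis
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

# Raw autocorrelation sum_t x_t x_{t+tau} for tau = 0..n-1, via FFT.
autocorr_fft <- function(x) {
  n <- length(x)
  xp <- c(x, numeric(n))
  Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE))[seq_len(n)] / (2 * n)
}

# LPC coefficients by Levinson-Durbin on the biased autocorrelation.
# Returns list(a = prediction coefficients (length p, sign so that
# residual = x - sum a_k x_{t-k}), k = reflection coefficients, g = gain).
# Optional lag windowing (Gaussian, `bw_hz` bandwidth expansion at sample
# rate `fs`) and white-noise correction keep the all-pole model away from
# the unit circle, as speech codecs do.
lpc_autocor <- function(x, p, bw_hz = 0, fs = 8000, wn_corr = 0) {
  n <- length(x)
  stopifnot(n > p)
  r <- autocorr_fft(x)[1:(p + 1L)]
  if (r[1] <= 0) return(list(a = numeric(p), k = numeric(p), g = 0))
  if (wn_corr > 0) r[1] <- r[1] * (1 + wn_corr)
  if (bw_hz > 0)
    r <- r * exp(-0.5 * (2 * pi * bw_hz * (0:p) / fs)^2)
  a <- numeric(p); k <- numeric(p); e <- r[1]
  for (i in seq_len(p)) {
    acc <- r[i + 1L]
    if (i > 1L) acc <- acc - sum(a[1:(i - 1L)] * r[i:2])
    ki <- acc / e
    ki <- max(min(ki, 0.999), -0.999)
    k[i] <- ki
    a_new <- a
    a_new[i] <- ki
    if (i > 1L) a_new[1:(i - 1L)] <- a[1:(i - 1L)] - ki * a[(i - 1L):1]
    a <- a_new
    e <- e * (1 - ki^2)
    if (e <= 0) { e <- 1e-12 }
  }
  list(a = a, k = k, g = sqrt(e / n))
}

# Reflection coefficients -> prediction coefficients (Levinson recursion).
refl_to_lpc <- function(k) {
  a <- numeric(0)
  for (i in seq_along(k)) {
    a_new <- c(a, k[i])
    if (i > 1L) a_new[1:(i - 1L)] <- a - k[i] * rev(a)
    a <- a_new
  }
  a
}
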