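#' Trim to the middle three seconds and normalize
#'
#' Removes vowel onset and offset by keeping exactly the central 3 s of
#' the phonation, then scales to unit maximum absolute amplitude so that
#' measures are comparable across recordings. The sample rate is
#' preserved.
#'
#' @param x a `phonation` of duration at least 3 s.
#' @return the trimmed, normalized `phonation`; `meta$preprocessed` is set.
#' @export
preprocess <- function(x) {
  stopifnot(inherits(x, "phonation"))
  fs <- x$sample_rate
  n3 <- round(3 * fs)
  n <- length(x$samples)
  if (n < n3) stop("phonation shorter than 3 s; cannot preprocess")
  start <- floor((n - n3) / 2)
  s <- x$samples[(start + 1L):(start + n3)]
  mx <- max(abs(s))
  if (mx > 0) s <- s / mx
  out <- x
  out$samples <- s
  out$meta$preprocessed <- TRUE
  out$meta$normalization <- "unit_max_abs"
  out
}

# Normalized-autocorrelation F0 estimate for one frame: the raw
# autocorrelation divided by the energies of the two overlapping segments,
# so an exactly periodic frame scores 1 at its period regardless of lag.
# Returns c(f0, strength).
frame_f0 <- function(seg, fs, f_min = 50, f_max = 500) {
  n <- length(seg)
  seg <- seg - mean(seg)
  if (sum(seg^2) == 0) return(c(NA_real_, 0))
  num <- autocorr_fft(seg)
  cs <- cumsum(seg^2)
  taus <- 0:(n - 1L)
  e0 <- cs[n - taus]
  e1 <- cs[n] - c(0, cs[taus[-1]])
  r <- num / sqrt(pmax(e0 * e1, 1e-30))
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(n - 2L, ceiling(fs / f_min))
  if (lag_max <= lag_min) return(c(NA_real_, 0))
  rr <- r[(lag_min + 1L):(lag_max + 1L)]      # r at lags lag_min..lag_max
  pk <- which.max(rr)
  rmax <- rr[pk]
  # octave guard: multiples of the true period score alike, so take the
  # smallest local maximum within 3% of the best peak
  loc <- which(diff(sign(diff(rr))) == -2) + 1L
  loc <- loc[rr[loc] >= 0.97 * rmax]
  if (length(loc) > 0L && loc[1] < pk) pk <- loc[1]
  lag <- lag_min + pk - 1L
  # parabolic interpolation around the peak
  if (lag > lag_min && lag < lag_max) {
    y1 <- r[lag]; y2 <- r[lag + 1L]; y3 <- r[lag + 2L]
    denom <- y1 - 2 * y2 + y3
    d <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    d <- max(min(d, 0.5), -0.5)
    lag <- lag + d
  }
  c(fs / lag, rr[pk])
}

#' Frame-level F0 contour of a phonation
#'
#' Autocorrelation tracker with parabolic peak interpolation and an
#' octave-error guard; frames of `frame_ms` every `hop_ms`.
#'
#' @param x a `phonation`.
#' @param frame_ms,hop_ms analysis frame and hop in milliseconds.
#' @param f_min,f_max physiological F0 search range in Hz.
#' @param voiced_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return data frame with `time`, `f0`, `strength`, `voiced`.
#' @export
track_f0 <- function(x, frame_ms = 40, hop_ms = 10, f_min = 50, f_max = 500,
                     voiced_threshold = 0.5) {
  fs <- x$sample_rate
  fl <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  n <- length(x$samples)
  starts <- seq(1L, n - fl + 1L, by = hop)
  res <- vapply(starts, function(s0)
    frame_f0(x$samples[s0:(s0 + fl - 1L)], fs, f_min, f_max), numeric(2))
  data.frame(time = (starts + fl / 2) / fs, f0 = res[1, ],
             strength = res[2, ],
             voiced = !is.na(res[1, ]) & res[2, ] >= voiced_threshold)
}

# Period of each cycle as the normalized-cross-correlation-maximizing lag
# between a one-period window at each onset and the following waveform;
# returns one period (samples) per onset pair, NA where matching fails.
measure_periods <- function(s, onsets, fs, t0) {
  n <- length(s)
  L <- max(8L, round(0.8 * t0))
  lag_lo <- max(2L, floor(0.72 * t0))
  lag_hi <- ceiling(1.35 * t0)
  nfft <- 2L^ceiling(log2(L + lag_hi + 2L))
  back <- round(0.55 * L)   # window centered on the peak, inside one cycle
  vapply(seq_len(length(onsets) - 1L), function(i) {
    o <- onsets[i] - back          # center the window on the peak
    if (o < 1L || o + lag_hi + L > n) return(NA_real_)
    w <- s[o:(o + L - 1L)]
    a <- s[o:(o + lag_hi + L - 1L)]
    # cross-correlation c(lag) = sum_t w[t] a[t+lag] for lag = 0..lag_hi
    cc <- Re(stats::fft(Conj(stats::fft(c(w, numeric(nfft - L)))) *
                          stats::fft(c(a, numeric(nfft - length(a)))),
                        inverse = TRUE))[1:(lag_hi + 1L)] / nfft
    cs <- cumsum(c(0, a^2))
    en <- cs[(0:lag_hi) + L + 1L] - cs[(0:lag_hi) + 1L]
    r <- cc / sqrt(pmax(sum(w^2) * en, 1e-30))
    idx <- (lag_lo + 1L):(lag_hi + 1L)
    pk <- idx[which.max(r[idx])]
    if (pk <= 1L || pk >= length(r)) return(NA_real_)
    y1 <- r[pk - 1L]; y2 <- r[pk]; y3 <- r[pk + 1L]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) > 1e-15) 0.5 * (y1 - y3) / den else 0
    (pk - 1L) + max(min(d, 0.5), -0.5)
  }, numeric(1))
}

#' Extract vocal-fold cycles from a preprocessed phonation
#'
#' Marks one glottal cycle per pitch period by peak picking guided by the
#' frame-level F0 contour; measures work directly on the detected cycles
#' rather than fixed-length segments.
#'
#' @param x a preprocessed `phonation`.
#' @param f_min,f_max F0 bounds in Hz.
#' @return a `cycle_sequence`: `onsets` (sample indices), `lengths_s`,
#'   `amplitudes` (peak absolute amplitude per cycle), `f0_contour`
#'   (1/length per cycle), `voiced_fraction`, and `flag` ("ok" or
#'   "unvoiced").
#' @export
extract_cycles <- function(x, f_min = 50, f_max = 500) {
  stopifnot(inherits(x, "phonation"))
  fs <- x$sample_rate
  tr <- track_f0(x, f_min = f_min, f_max = f_max)
  vfrac <- mean(tr$voiced)
  if (vfrac < 0.5 || sum(tr$voiced) < 3L) {
    return(structure(list(onsets = integer(0), lengths_s = numeric(0),
                          amplitudes = numeric(0), f0_contour = numeric(0),
                          voiced_fraction = vfrac, flag = "unvoiced"),
                     class = "cycle_sequence"))
  }
  f0_med <- stats::median(tr$f0[tr$voiced])
  # local period (samples) at any sample position via the nearest frame
  f0_at <- function(pos) {
    i <- which.min(abs(tr$time - pos / fs))
    if (tr$voiced[i]) tr$f0[i] else f0_med
  }
  s <- x$samples
  n <- length(s)
  t0 <- fs / f0_med
  w0 <- s[1:min(n, ceiling(1.5 * t0))]
  cur <- which.max(abs(w0))
  onsets <- integer(0)
  while (cur <= n) {
    onsets <- c(onsets, cur)
    period <- fs / f0_at(cur)
    lo <- cur + floor(0.7 * period)
    hi <- cur + ceiling(1.3 * period)
    if (hi > n) break
    w <- abs(s[lo:hi])
    cur <- lo + which.max(w) - 1L
  }
  if (length(onsets) < 3L) {
    return(structure(list(onsets = onsets, lengths_s = numeric(0),
                          amplitudes = numeric(0), f0_contour = numeric(0),
                          voiced_fraction = vfrac, flag = "unvoiced"),
                     class = "cycle_sequence"))
  }
  # cycle lengths by waveform matching: the period at cycle i is the lag
  # (sub-sample, via parabolic interpolation) that best aligns the cycle
  # with its successor, robust to which ringing lobe the peak picker hit
  lens <- measure_periods(s, onsets, fs, fs / f0_med)
  # keep the longest contiguous run of successful period measurements
  # (failures occur only near the segment edges)
  finite <- is.finite(lens)
  runs <- rle(finite)
  ends <- cumsum(runs$lengths)
  ok_runs <- which(runs$values)
  if (length(ok_runs) == 0L) {
    lens <- numeric(0)
  } else {
    best <- ok_runs[which.max(runs$lengths[ok_runs])]
    i0 <- ends[best] - runs$lengths[best] + 1L
    i1 <- ends[best]
    onsets <- onsets[i0:(i1 + 1L)]
    lens <- lens[i0:i1] / fs
  }
  if (length(lens) < 2L) {
    return(structure(list(onsets = onsets, lengths_s = numeric(0),
                          amplitudes = numeric(0), f0_contour = numeric(0),
                          voiced_fraction = vfrac, flag = "unvoiced"),
                     class = "cycle_sequence"))
  }
  amps <- vapply(seq_len(length(onsets) - 1L), function(i)
    max(abs(s[onsets[i]:(onsets[i + 1L] - 1L)])), numeric(1))
  structure(list(onsets = onsets, lengths_s = lens, amplitudes = amps,
                 f0_contour = 1 / lens, voiced_fraction = vfrac,
                 flag = "ok"),
            class = "cycle_sequence")
}

#' @export
print.cycle_sequence <- function(x, ...) {
  cat(sprintf("<cycle_sequence> %d cycles, flag=%s, voiced %.0f%%\n",
              length(x$lengths_s), x$flag, 100 * x$voiced_fraction))
  if (length(x$f0_contour))
    cat(sprintf("  mean F0 %.1f Hz\n", mean(x$f0_contour)))
  invisible(x)
}
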