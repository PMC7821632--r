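# The dysphonia measure registry: 132 named measures in twelve algorithmic
# families. Family sizes are fixed contracts: 30 jitter, 21 shimmer, 42
# MFCC, 8 F0-related; the remaining 31 are split across HNR (5), glottal
# quotient (4), RPDE/DFA/PPE (1 each), GNE (6), VFER (7) and EMD
# excitation ratios (6). The order below is stable across runs and is the
# order of `extract_all()` output.

.JITTER_NAMES <- c(
  "jitter_local", "jitter_local_abs", "jitter_rap", "jitter_ppq5",
  "jitter_ppq11", "jitter_ddp", "jitter_percent", "jitter_cv",
  "jitter_sd_abs", "jitter_range_frac", "jitter_iqr_frac",
  "jitter_mad_frac", "jitter_p5p95_frac", "jitter_entropy",
  "jitter_diff_p5", "jitter_diff_p95", "jitter_diff_max",
  "jitter_tkeo_mean", "jitter_tkeo_sd", "jitter_tkeo_p5",
  "jitter_tkeo_p95",
  "jitter_f0_local", "jitter_f0_cv", "jitter_f0_rap", "jitter_f0_ppq5",
  "jitter_f0_range_frac", "jitter_f0_entropy", "jitter_f0_tkeo_mean",
  "jitter_f0_tkeo_sd", "jitter_f0_diff_p95")

.SHIMMER_NAMES <- c(
  "shim_local", "shim_db", "shim_apq3", "shim_apq5", "shim_apq11",
  "shim_dda", "shim_cv", "shim_diff_sd", "shim_range_frac",
  "shim_iqr_frac", "shim_mad_frac", "shim_entropy", "shim_diff_p5",
  "shim_diff_p95", "shim_diff_max", "shim_tkeo_mean", "shim_tkeo_sd",
  "shim_tkeo_p5", "shim_tkeo_p95", "shim_db_sd", "shim_log_sd")

.HNR_NAMES <- c("hnr_mean", "hnr_sd", "hnr_median", "hnr_p5", "hnr_p95")
.GQ_NAMES <- c("gq_mean", "gq_sd", "gq_local_var", "gq_range")
.GNE_NAMES <- c("gne_max", "gne_mean", "gne_sd",
                "gne_tkeo_max", "gne_tkeo_mean", "gne_tkeo_sd")
.VFER_NAMES <- c("vfer_snr_energy", "vfer_nsr_energy", "vfer_snr_tkeo",
                 "vfer_nsr_tkeo", "vfer_entropy_signal",
                 "vfer_entropy_noise", "vfer_entropy_ratio")
.EMD_NAMES <- c("emd_snr_energy", "emd_nsr_energy", "emd_snr_tkeo",
                "emd_nsr_tkeo", "emd_snr_entropy", "emd_nsr_entropy")
.MFCC_NAMES <- as.vector(vapply(c("", "_d", "_dd"), function(sfx)
  paste0("mfcc_", c("logE", paste0("c", 0:12)), sfx), character(14)))
.F0_NAMES <- c("f0_mean", "f0_median", "f0_sd", "f0_p5", "f0_p95",
               "f0_range", "f0_rel_dev", "f0_abs_dev")

#' The dysphonia measure registry
#'
#' @return data frame with `index` (1..132), `name` and `family` of every
#'   measure, in extraction order.
#' @export
feature_registry <- function() {
  fam <- c(rep("jitter", 30L), rep("shimmer", 21L), rep("hnr", 5L),
           rep("gq", 4L), "rpde", "dfa", "ppe", rep("gne", 6L),
           rep("vfer", 7L), rep("emd", 6L), rep("mfcc", 42L),
           rep("f0", 8L))
  nm <- c(.JITTER_NAMES, .SHIMMER_NAMES, .HNR_NAMES, .GQ_NAMES,
          "rpde", "dfa", "ppe", .GNE_NAMES, .VFER_NAMES, .EMD_NAMES,
          .MFCC_NAMES, .F0_NAMES)
  stopifnot(length(nm) == 132L, length(fam) == 132L, !anyDuplicated(nm))
  data.frame(index = seq_len(132L), name = nm, family = fam,
             stringsAsFactors = FALSE)
}

missing_family <- function(names, reason) {
  v <- rep(NA_real_, length(names))
  names(v) <- names
  attr(v, "reason") <- reason
  v
}

# Perturbation summaries shared by the jitter and shimmer families:
# dispersion statistics of a positive sequence, all zero for a constant
# sequence and invariant to uniform scaling of the sequence.
perturbation_stats <- function(v) {
  m <- mean(v)
  dv <- abs(diff(v))
  tk <- abs(tkeo(v)) / m^2
  q <- stats::quantile(dv / m, c(0.05, 0.95), names = FALSE)
  list(local = mean(dv) / m,
       local_abs = mean(dv),
       cv = stats::sd(v) / m,
       sd_abs = stats::sd(v),
       range_frac = diff(range(v)) / m,
       iqr_frac = stats::IQR(v) / m,
       mad_frac = stats::mad(v) / m,
       p5p95_frac = diff(stats::quantile(v, c(0.05, 0.95), names = FALSE)) / m,
       entropy = norm_entropy(v),
       diff_p5 = q[1], diff_p95 = q[2], diff_max = max(dv) / m,
       tkeo_mean = mean(tk), tkeo_sd = stats::sd(tk),
       tkeo_p5 = stats::quantile(tk, 0.05, names = FALSE),
       tkeo_p95 = stats::quantile(tk, 0.95, names = FALSE))
}

# k-point period perturbation quotient: mean |v_i - mean(window)| / mean(v)
ppq <- function(v, k) {
  n <- length(v)
  if (n < k) return(0)
  half <- (k - 1L) %/% 2L
  dev <- vapply((half + 1L):(n - half), function(i)
    abs(v[i] - mean(v[(i - half):(i + half)])), numeric(1))
  mean(dev) / mean(v)
}

#' Jitter family: 30 period-perturbation measures
#'
#' Classical local/RAP/PPQ variants plus dispersion, entropy and
#' Teager-energy summaries of the cycle-length sequence and of the
#' per-cycle F0 contour. All measures are nonnegative, zero for perfectly
#' constant cycle lengths, and independent of signal amplitude.
#'
#' @param cycles a `cycle_sequence` with at least 3 cycles.
#' @return named numeric vector of 30 values (NA with a reason attribute
#'   when too few cycles are available).
#' @export
jitter_family <- function(cycles) {
  t_ <- cycles$lengths_s
  if (length(t_) < 3L)
    return(missing_family(.JITTER_NAMES, "too few cycles"))
  ps <- perturbation_stats(t_)
  f0 <- cycles$f0_contour
  pf <- perturbation_stats(f0)
  v <- c(ps$local, ps$local_abs, ppq(t_, 3L), ppq(t_, 5L), ppq(t_, 11L),
         if (length(t_) >= 3L)
           mean(abs(diff(t_, differences = 2L))) / mean(t_) else 0,
         100 * ps$local, ps$cv, ps$sd_abs, ps$range_frac, ps$iqr_frac,
         ps$mad_frac, ps$p5p95_frac, ps$entropy, ps$diff_p5, ps$diff_p95,
         ps$diff_max, ps$tkeo_mean, ps$tkeo_sd, ps$tkeo_p5, ps$tkeo_p95,
         pf$local, pf$cv, ppq(f0, 3L), ppq(f0, 5L), pf$range_frac,
         pf$entropy, pf$tkeo_mean, pf$tkeo_sd, pf$diff_p95)
  names(v) <- .JITTER_NAMES
  v
}

#' Shimmer family: 21 amplitude-perturbation measures
#'
#' Classical local/dB/APQ variants plus dispersion, entropy and
#' Teager-energy summaries of the per-cycle peak-amplitude sequence. All
#' measures are nonnegative, zero for constant amplitudes, invariant to
#' uniform amplitude scaling and independent of the cycle periods.
#'
#' @param cycles a `cycle_sequence` with at least 3 cycles.
#' @return named numeric vector of 21 values.
#' @export
shimmer_family <- function(cycles) {
  a <- cycles$amplitudes
  if (length(a) < 3L)
    return(missing_family(.SHIMMER_NAMES, "too few cycles"))
  ps <- perturbation_stats(a)
  db <- abs(20 * log10(a[-1] / a[-length(a)]))
  v <- c(ps$local, mean(db), ppq(a, 3L), ppq(a, 5L), ppq(a, 11L),
         3 * ppq(a, 3L), ps$cv, stats::sd(abs(diff(a))) / mean(a),
         ps$range_frac, ps$iqr_frac, ps$mad_frac, ps$entropy,
         ps$diff_p5, ps$diff_p95, ps$diff_max, ps$tkeo_mean, ps$tkeo_sd,
         ps$tkeo_p5, ps$tkeo_p95, stats::sd(db), stats::sd(log(a)))
  names(v) <- .SHIMMER_NAMES
  v
}

#' Harmonics-to-noise ratio and glottal quotient families
#'
#' HNR per analysis frame from the normalized cross-correlation `r` at the
#' local pitch period, `10 log10(r / (1 - r))` dB (capped at 60 dB),
#' summarized over voiced frames. The glottal-quotient family summarizes
#' the per-cycle open quotient (fraction of the cycle with amplitude above
#' a quarter of the cycle peak) and its cycle-to-cycle variability.
#'
#' @param x a preprocessed `phonation`.
#' @param cycles the matching `cycle_sequence`.
#' @return named numeric vector of 9 values (5 HNR + 4 GQ).
#' @export
hnr_gq_family <- function(x, cycles) {
  if (cycles$flag == "unvoiced")
    return(missing_family(c(.HNR_NAMES, .GQ_NAMES), "unvoiced"))
  fs <- x$sample_rate
  s <- x$samples
  fl <- round(0.04 * fs); hop <- round(0.01 * fs)
  f0_med <- stats::median(cycles$f0_contour)
  lag <- max(2L, round(fs / f0_med))
  starts <- seq(1L, length(s) - fl - lag, by = hop)
  hnr <- vapply(starts, function(s0) {
    x1 <- s[s0:(s0 + fl - 1L)]
    x2 <- s[(s0 + lag):(s0 + lag + fl - 1L)]
    den <- sqrt(sum(x1^2) * sum(x2^2))
    r <- if (den > 0) sum(x1 * x2) / den else 0
    r <- min(max(r, 1e-6), 1 - 1e-6)
    10 * log10(r / (1 - r))
  }, numeric(1))
  hv <- c(mean(hnr), stats::sd(hnr), stats::median(hnr),
          stats::quantile(hnr, c(0.05, 0.95), names = FALSE))
  on <- cycles$onsets
  oq <- vapply(seq_len(length(on) - 1L), function(i) {
    cyc <- abs(s[on[i]:(on[i + 1L] - 1L)])
    mean(cyc > 0.25 * max(cyc))
  }, numeric(1))
  gq <- c(mean(oq), stats::sd(oq),
          if (length(oq) > 1L) mean(abs(diff(oq))) / mean(oq) else 0,
          diff(range(oq)))
  v <- c(hv, gq)
  names(v) <- c(.HNR_NAMES, .GQ_NAMES)
  v
}

#' Detrended fluctuation analysis scaling exponent
#'
#' First-order DFA of the signal: root-mean-square fluctuation of the
#' linearly detrended integrated series over log-spaced window sizes; the
#' exponent is the log-log slope. White noise gives an exponent near 0.5,
#' Brownian-like turbulence near 1.5.
#'
#' @param x numeric signal.
#' @param scales integer window sizes; defaults to 10 log-spaced scales
#'   between 16 samples and a quarter of the signal length (capped at 1024).
#' @return the raw scaling exponent (unsquashed).
#' @export
dfa_exponent <- function(x, scales = NULL) {
  n <- length(x)
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(16), log(min(n %/% 4, 1024)),
                                   length.out = 10))))
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(L) {
    K <- n %/% L
    Y <- matrix(y[seq_len(K * L)], nrow = L)
    t_ <- seq_len(L)
    B <- cbind(1, t_)
    # residuals of per-window linear fits, all windows at once
    coef <- solve(crossprod(B), crossprod(B, Y))
    R <- Y - B %*% coef
    sqrt(mean(R^2))
  }, numeric(1))
  stats::coef(stats::lm(log(fl) ~ log(scales)))[[2]]
}

#' Recurrence period density entropy
#'
#' Time-delay embeds the (8 kHz, unit-variance) signal, records the first
#' recurrence time into an epsilon-ball around each reference point after
#' the trajectory has left the ball, and returns the normalized Shannon
#' entropy of the recurrence-period histogram. Near 0 for an exactly
#' periodic signal, near 1 for aperiodic noise.
#'
#' @param x numeric signal.
#' @param fs sampling rate of `x` in Hz.
#' @param eps_frac ball radius as a fraction of the embedded signal scale.
#' @param f_min lowest F0 considered, fixing the maximum recurrence period.
#' @return RPDE in \[0, 1\], or NA for a degenerate (constant) signal.
#' @export
rpde <- function(x, fs, eps_frac = 0.12, f_min = 50) {
  if (stats::sd(x) < 1e-12) return(NA_real_)
  if (fs > 11025) {
    dec <- max(1L, round(fs / 8000))
    x <- fft_bandpass(x, fs, 0, fs / (2 * dec) * 0.9)[seq(1, length(x), by = dec)]
    fs <- fs / dec
  }
  x <- (x - mean(x)) / stats::sd(x)
  m <- 3L; tau <- 5L
  n <- length(x) - (m - 1L) * tau
  E <- cbind(x[1:n], x[(1 + tau):(n + tau)], x[(1 + 2 * tau):(n + 2 * tau)])
  t_max <- ceiling(fs / f_min) + 5L
  stride <- 4L
  ref <- seq(1L, n - t_max - 1L, by = stride)
  eps <- eps_frac * sqrt(m)
  left <- rep(FALSE, length(ref))
  ret <- rep(NA_integer_, length(ref))
  active <- rep(TRUE, length(ref))
  for (T in seq_len(t_max)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    d2 <- rowSums((E[ref[idx] + T, , drop = FALSE] -
                     E[ref[idx], , drop = FALSE])^2)
    inside <- d2 < eps^2
    newly_ret <- idx[left[idx] & inside]
    ret[newly_ret] <- T
    active[newly_ret] <- FALSE
    left[idx[!inside]] <- TRUE
  }
  ret <- ret[!is.na(ret)]
  if (length(ret) < 10L) return(1)
  h <- tabulate(ret, nbins = t_max)
  p <- h[h > 0] / sum(h)
  -sum(p * log(p)) / log(t_max)
}

#' Pitch period entropy
#'
#' Entropy of the semitone-scale log-F0 residual after whitening with a
#' low-order autoregressive model, so that smooth, vibrato-like F0
#' movement is discounted and only irregular pitch control contributes.
#'
#' @param cycles a `cycle_sequence`.
#' @return normalized entropy in \[0, 1\]; 0 for a constant F0 contour.
#' @export
ppe <- function(cycles) {
  f0 <- cycles$f0_contour
  if (length(f0) < 10L) return(NA_real_)
  r <- 12 * log2(f0 / stats::median(f0))
  if (stats::sd(r) < 1e-10) return(0)
  fit <- stats::ar(r, order.max = 2L, aic = FALSE, method = "yw")
  res <- fit$resid[!is.na(fit$resid)]
  if (length(res) < 5L || stats::sd(res) < 1e-12) return(0)
  norm_entropy(res, bins = 30L)
}

#' Nonlinear family: RPDE, DFA and PPE
#'
#' @param x a preprocessed `phonation`.
#' @param cycles the matching `cycle_sequence`.
#' @return named numeric vector `c(rpde, dfa, ppe)`; the DFA exponent is
#'   squashed to (0, 1) by the logistic map.
#' @export
nonlinear_family <- function(x, cycles) {
  if (stats::sd(x$samples) < 1e-12)
    return(missing_family(c("rpde", "dfa", "ppe"), "degenerate signal"))
  r <- rpde(x$samples, x$sample_rate)
  d <- 1 / (1 + exp(-dfa_exponent(x$samples)))
  p <- if (cycles$flag == "unvoiced") NA_real_ else ppe(cycles)
  v <- c(rpde = r, dfa = d, ppe = p)
  if (is.na(p)) attr(v, "reason") <- "unvoiced (PPE)"
  v
}

band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1L) / n * fs
  half <- f <= fs / 2
  sum(P[half & f >= lo & f < hi])
}

#' SNR band family: GNE, VFER and EMD excitation ratios
#'
#' GNE: correlations between Hilbert envelopes of 500 Hz bands of the
#' linear-prediction residual (bands at least 1 kHz apart), with a
#' Teager-energy variant. VFER: signal/noise ratios across the 2.5 kHz
#' split (below 2.5 kHz treated as signal, 2.5-4 kHz as noise) on band
#' energy, Teager energy and entropy. EMD-ER: the same ratio concepts with
#' the top (high-frequency) intrinsic mode functions as noise. Analysis
#' runs at 8 kHz; higher-rate input is decimated first, so the noise band
#' is always \[2.5, 4\] kHz.
#'
#' @param x a preprocessed `phonation`.
#' @return named numeric vector of 19 values (6 GNE + 7 VFER + 6 EMD).
#' @export
snr_band_family <- function(x) {
  nm <- c(.GNE_NAMES, .VFER_NAMES, .EMD_NAMES)
  if (stats::sd(x$samples) < 1e-12)
    return(missing_family(nm, "degenerate signal"))
  y <- if (x$sample_rate > 8000) resample_phonation(x, 8000) else x
  s <- y$samples
  fs <- y$sample_rate
  # --- GNE on the LPC residual
  lp <- lpc_autocor(s, 13L)
  resid <- as.numeric(stats::filter(s, c(1, -lp$a), method = "convolution",
                                    sides = 1))
  resid[is.na(resid)] <- 0
  edges <- seq(0, 4000, by = 500)
  envs <- lapply(seq_len(length(edges) - 1L), function(i)
    hilbert_envelope(fft_bandpass(resid, fs, edges[i], edges[i + 1L])))
  pairs <- which(outer(seq_along(envs), seq_along(envs),
                       function(i, j) j - i >= 2), arr.ind = TRUE)
  cors <- apply(pairs, 1L, function(ij)
    suppressWarnings(stats::cor(envs[[ij[1]]], envs[[ij[2]]])))
  cors <- cors[is.finite(cors)]
  envs_tk <- lapply(envs, function(e) abs(tkeo(e)))
  cors_tk <- apply(pairs, 1L, function(ij)
    suppressWarnings(stats::cor(envs_tk[[ij[1]]], envs_tk[[ij[2]]])))
  cors_tk <- cors_tk[is.finite(cors_tk)]
  gne <- c(max(cors), mean(cors), stats::sd(cors),
           max(cors_tk), mean(cors_tk), stats::sd(cors_tk))
  # --- VFER across the 2.5 kHz split
  sig <- fft_bandpass(s, fs, 0, 2500)
  noi <- fft_bandpass(s, fs, 2500, 4000)
  es <- sum(sig^2); en <- max(sum(noi^2), 1e-15)
  ts_ <- sum(tkeo(sig)^2); tn <- max(sum(tkeo(noi)^2), 1e-30)
  hs <- norm_entropy(sig); hn <- norm_entropy(noi)
  vfer <- c(10 * log10(es / en), en / (es + en),
            10 * log10(ts_ / tn), tn / (ts_ + tn),
            hs, hn, hs / max(hs + hn, 1e-12))
  # --- EMD excitation ratios: top (high-frequency) IMFs as noise. An IMF
  # counts as noise only if its dominant frequency (zero-crossing based)
  # lies above the 2.5 kHz split, so a clean low-frequency signal
  # contributes no "noise" component.
  de <- emd_decompose(s, max_imfs = 3L)
  if (length(de$imfs) < 1L) {
    emdv <- rep(NA_real_, 6L)
  } else {
    dom_freq <- vapply(de$imfs, function(m)
      mean(diff(sign(m)) != 0) * fs / 2, numeric(1))
    is_noise <- dom_freq > 2500
    # the noise set is the leading run of high-frequency IMFs
    if (any(!is_noise)) is_noise[min(which(!is_noise)):length(is_noise)] <- FALSE
    noise <- if (any(is_noise)) Reduce(`+`, de$imfs[is_noise]) else numeric(length(s))
    signal_ <- s - noise
    ee_s <- sum(signal_^2); ee_n <- max(sum(noise^2), 1e-15)
    tk_s <- sum(tkeo(signal_)^2); tk_n <- max(sum(tkeo(noise)^2), 1e-30)
    h_s <- norm_entropy(signal_); h_n <- norm_entropy(noise)
    emdv <- c(10 * log10(ee_s / ee_n), ee_n / (ee_s + ee_n),
              10 * log10(tk_s / tk_n), tk_n / (tk_s + tk_n),
              h_s / max(h_s + h_n, 1e-12), h_n / max(h_s + h_n, 1e-12))
  }
  v <- c(gne, vfer, emdv)
  names(v) <- nm
  if (anyNA(v)) attr(v, "reason") <- "EMD decomposition failure"
  v
}

mel_of_hz <- function(f) 2595 * log10(1 + f / 700)
hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_fft, fs, n_filt = 26L) {
  mel_pts <- seq(0, mel_of_hz(fs / 2), length.out = n_filt + 2L)
  hz_pts <- hz_of_mel(mel_pts)
  bins <- floor((n_fft + 1) * hz_pts / fs)
  fb <- matrix(0, n_filt, n_fft %/% 2L + 1L)
  for (m in seq_len(n_filt)) {
    lo <- bins[m]; c_ <- bins[m + 1L]; hi <- bins[m + 2L]
    if (c_ > lo) for (k in lo:c_) fb[m, k + 1L] <- (k - lo) / (c_ - lo)
    if (hi > c_) for (k in c_:hi) fb[m, k + 1L] <- (hi - k) / (hi - c_)
  }
  fb
}

delta_coeffs <- function(M, w = 2L) {
  # regression deltas over +/- w frames, matrix frames x coeffs
  n <- nrow(M)
  if (n < 2L * w + 1L) return(matrix(0, n, ncol(M)))
  den <- 2 * sum((1:w)^2)
  D <- matrix(0, n, ncol(M))
  for (t in seq_len(n)) {
    for (k in seq_len(w)) {
      tp <- min(t + k, n); tm <- max(t - k, 1L)
      D[t, ] <- D[t, ] + k * (M[tp, ] - M[tm, ])
    }
  }
  D / den
}

#' MFCC family: 42 cepstral measures
#'
#' 13 Mel-frequency cepstral coefficients (c0-c12, 26 Mel filters, 25 ms
#' frames, 10 ms hop) plus the frame log-energy, each with delta and
#' delta-delta regression coefficients, averaged over frames: 14 x 3 = 42
#' values. Cepstral coefficients c1-c12 are invariant to uniform gain; the
#' log-energy shifts by the log of the squared gain.
#'
#' @param x a preprocessed `phonation`.
#' @return named numeric vector of 42 values.
#' @export
mfcc_family <- function(x) {
  fs <- x$sample_rate
  s <- x$samples
  fl <- round(0.025 * fs); hop <- round(0.010 * fs)
  starts <- seq(1L, length(s) - fl + 1L, by = hop)
  n_fft <- 2L^ceiling(log2(fl))
  fb <- mel_filterbank(n_fft, fs)
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(fl) / (fl + 1))
  dct_mat <- t(vapply(0:12, function(k)
    cos(pi * k * (seq_len(26L) - 0.5) / 26L), numeric(26L)))
  feats <- t(vapply(starts, function(s0) {
    seg <- s[s0:(s0 + fl - 1L)]
    logE <- log(sum(seg^2) + 1e-12)
    segw <- c(seg * win, numeric(n_fft - fl))
    P <- Mod(stats::fft(segw))[1:(n_fft %/% 2L + 1L)]^2
    fe <- log(as.numeric(fb %*% P) + 1e-12)
    c(logE, as.numeric(dct_mat %*% fe))
  }, numeric(14L)))
  d1 <- delta_coeffs(feats)
  d2 <- delta_coeffs(d1)
  v <- c(colMeans(feats), colMeans(d1), colMeans(d2))
  names(v) <- .MFCC_NAMES
  v
}

#' F0 summary family: 8 measures
#'
#' Statistical summaries of the per-cycle F0 distribution plus the
#' deviation of the subject's mean F0 from a configurable sex-specific
#' normative value for healthy voices.
#'
#' @param cycles a `cycle_sequence`.
#' @param sex "male" or "female" (selects the normative F0).
#' @param f0_norms named vector of normative F0 values in Hz.
#' @return named numeric vector of 8 values.
#' @export
f0_family <- function(cycles, sex = c("male", "female"),
                      f0_norms = c(male = 120, female = 190)) {
  sex <- match.arg(sex)
  f0 <- cycles$f0_contour
  if (length(f0) < 3L)
    return(missing_family(.F0_NAMES, "unvoiced"))
  norm <- unname(f0_norms[sex])
  m <- mean(f0)
  v <- c(m, stats::median(f0), stats::sd(f0),
         stats::quantile(f0, c(0.05, 0.95), names = FALSE),
         diff(range(f0)), (m - norm) / norm, abs(m - norm))
  names(v) <- .F0_NAMES
  v
}

#' Extract the full 132-measure dysphonia vector
#'
#' Runs [preprocess()], cycle extraction and every measure family, and
#' returns the values in stable registry order. Measures that cannot be
#' computed (e.g. unvoiced input) are NA; their reasons are collected in
#' the `missing_reasons` attribute. Imputation is left to modelling time.
#'
#' @param x a raw `phonation` of duration at least 3 s.
#' @param sex "male" or "female"; defaults to the phonation's `sex` field.
#' @param f0_norms normative F0 values passed to [f0_family()].
#' @return named numeric vector of length 132.
#' @export
extract_all <- function(x, sex = NULL,
                        f0_norms = c(male = 120, female = 190)) {
  stopifnot(inherits(x, "phonation"))
  sex <- sex %||% x$sex
  if (is.null(sex) || is.na(sex)) sex <- "male"
  y <- preprocess(x)
  cyc <- extract_cycles(y)
  reasons <- character(0)
  grab <- function(v) {
    r <- attr(v, "reason")
    if (!is.null(r)) reasons[names(v)[is.na(v)]] <<- r
    v
  }
  voiced <- cyc$flag == "ok"
  jit <- grab(if (voiced) jitter_family(cyc) else
    missing_family(.JITTER_NAMES, "unvoiced"))
  shm <- grab(if (voiced) shimmer_family(cyc) else
    missing_family(.SHIMMER_NAMES, "unvoiced"))
  hg <- grab(hnr_gq_family(y, cyc))
  nl <- grab(nonlinear_family(y, cyc))
  sb <- grab(snr_band_family(y))
  mf <- grab(mfcc_family(y))
  f0 <- grab(if (voiced) f0_family(cyc, sex, f0_norms) else
    missing_family(.F0_NAMES, "unvoiced"))
  out <- c(jit, shm, hg, nl, sb, mf, f0)
  stopifnot(identical(names(out), feature_registry()$name))
  attr(out, "missing_reasons") <- reasons
  out
}

#' Extract features for a whole manifest of phonations
#'
#' @param phonations list of `phonation` objects.
#' @return numeric matrix, one row per phonation, 132 registry columns.
#' @export
extract_features <- function(phonations) {
  rows <- lapply(phonations, function(p) as.numeric(extract_all(p)))
  X <- do.call(rbind, rows)
  colnames(X) <- feature_registry()$name
  X
}
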