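test_that("add_noise hits the commanded SNR exactly and leaves the clean component untouched", {
  ph <- make_vowel(seed = 5)
  out <- add_noise(ph, "awgn", 10, seed = 4)
  noise <- out$samples - ph$samples          # energy contract: pure addition
  snr <- 10 * log10(mean(ph$samples^2) / mean(noise^2))
  expect_lt(abs(snr - 10), 0.1)
  # vanishing-noise limit
  hi <- add_noise(ph, "awgn", 60, seed = 4)
  expect_gt(cor(hi$samples, ph$samples), 0.999)
  # zero-power input rejected
  expect_error(add_noise(phonation(numeric(100) , 8000), "awgn", 10),
               "zero power")
})

test_that("pink noise falls at about 3 dB per octave", {
  x <- pink_noise(2^15, seed = 4)
  P <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * 8000
  i <- f >= 50 & f <= 3000
  slope <- stats::coef(stats::lm(log(P[i]) ~ log(f[i])))[[2]]
  expect_lt(abs(slope - (-1)), 0.2)
  # and the pink-contaminated phonation still hits the target SNR exactly
  ph <- make_vowel(seed = 5)
  out <- add_noise(ph, "pink", 10, seed = 4)
  noise <- out$samples - ph$samples
  expect_lt(abs(10 * log10(mean(ph$samples^2) / mean(noise^2)) - 10), 0.1)
})

test_that("codec frame arithmetic: 3 s at 8 kHz with 20 ms frames gives 150 frames", {
  cfg <- channel_config()
  ph <- phonation(sin(2 * pi * 200 * (0:23999) / 8000), 8000)
  bits <- encode_speech(ph, cfg)
  expect_equal(bits$n_frames, 150)
  expect_equal(length(bits$bits), 150 * cfg$bits_per_frame)
  expect_equal(length(bits$bits) %% bits$frame_length_bits, 0)
  # preconditions
  expect_error(encode_speech(make_vowel(seed = 5), cfg), "resampled")
  cfg_bad <- channel_config(codec_frame_ms = 1, lpc_order = 10)
  expect_error(encode_speech(ph, cfg_bad), "shorter than")
})

test_that("silence encodes to a valid stream that decodes below -40 dBFS", {
  cfg <- channel_config()
  sil <- phonation(numeric(8000 * 3), 8000)
  bits <- encode_speech(sil, cfg)
  expect_equal(length(bits$bits) %% cfg$bits_per_frame, 0)
  dec <- decode_speech(bits, cfg)
  expect_lt(10 * log10(mean(dec$samples^2) + 1e-30), -40)
})

test_that("codec round trip preserves F0 within 2% and F1 within one DFT bin", {
  cfg <- channel_config()
  ph8 <- resample_phonation(make_vowel(seed = 5), 8000)
  dec <- decode_speech(encode_speech(ph8, cfg), cfg)
  f0_in <- mean(extract_cycles(preprocess(ph8))$f0_contour)
  f0_out <- mean(extract_cycles(preprocess(dec))$f0_contour)
  expect_lt(abs(f0_out - f0_in) / f0_in, 0.02)
  # Welch-averaged spectrum: F1 peak bin unchanged
  welch_peak <- function(x, fs, nfft = 2048) {
    starts <- seq(1, length(x) - nfft + 1, by = nfft %/% 2)
    P <- Reduce(`+`, lapply(starts, function(s0)
      Mod(stats::fft(x[s0:(s0 + nfft - 1)] * signal::hanning(nfft)))^2))
    f <- (seq_len(nfft) - 1) / nfft * fs
    keep <- f >= 300 & f <= 1100
    which(keep)[which.max(P[keep])]
  }
  n <- min(length(ph8$samples), length(dec$samples))
  expect_lte(abs(welch_peak(ph8$samples[1:n], 8000) -
                   welch_peak(dec$samples[1:n], 8000)), 1)
})

test_that("transmit maps bits to antipodal symbols through the ISI channel", {
  cfg_id <- channel_config(channel_taps = 1, channel_snr_db = Inf)
  b <- c(1L, 0L, 1L, 1L, 0L)
  r <- transmit(b, cfg_id)
  expect_equal(r, c(1, -1, 1, 1, -1))
  cfg_c <- channel_config(channel_snr_db = Inf)
  expect_equal(length(transmit(b, cfg_c)), length(b) + 4)   # 5 taps
  expect_error(transmit(integer(0), cfg_c), "empty")
})

test_that("BER falls with SNR and the MMSE equalizer beats raw detection", {
  set.seed(1)
  b <- sample(0:1, 1e5, replace = TRUE)
  ber_eq <- ber_raw <- ber_mlse <- numeric(0)
  for (snr in c(0, 5, 10, 20)) {
    cfg <- channel_config(channel_snr_db = snr, equalizer = "mmse_linear",
                          seed = 42)
    r <- transmit(b, cfg)
    ber_eq <- c(ber_eq, bit_error_rate(b, equalize_detect(r, cfg, length(b))))
    cfg_n <- cfg; cfg_n$equalizer <- "none"
    ber_raw <- c(ber_raw, bit_error_rate(b, equalize_detect(r, cfg_n, length(b))))
    cfg_v <- cfg; cfg_v$equalizer <- "mlse"
    ber_mlse <- c(ber_mlse, bit_error_rate(b, equalize_detect(r, cfg_v, length(b))))
  }
  expect_true(all(diff(ber_eq) < 0))            # monotone in SNR
  expect_true(all(diff(ber_mlse) < 0))
  expect_true(all(ber_eq < ber_raw))            # equalizer helps at every SNR
  # the sequence detector dominates the linear equalizer at usable SNRs
  expect_true(all(ber_mlse[3:4] <= ber_eq[3:4]))
  # identity channel, high SNR: exact recovery
  cfg_id <- channel_config(channel_taps = 1, channel_snr_db = 40, seed = 1)
  r <- transmit(b, cfg_id)
  expect_equal(equalize_detect(r, cfg_id, length(b))$bits, b)
})

test_that("degenerate and malformed receiver inputs are handled deterministically", {
  cfg <- channel_config(channel_snr_db = 10)
  z <- equalize_detect(numeric(100 + 4), cfg, 100)
  expect_true(all(z$bits == z$bits[1]))          # all-same-bit convention
  expect_error(equalize_detect(numeric(50), cfg, 100), "length")
})

test_that("the full degradation chain is deterministic, bounded and channel-free in the identity limit", {
  ph <- make_vowel(seed = 5)
  cfg_id <- channel_config(channel_taps = 1, channel_snr_db = Inf,
                           equalizer = "none", seed = 2)
  a <- degrade(ph, cfg_id)
  expect_equal(a$meta$ber, 0)
  expect_equal(a$sample_rate, 8000)
  expect_true(all(abs(a$samples) <= 1))
  # identity channel output equals the pure codec round trip
  ph8 <- resample_phonation(ph, 8000)
  mx <- max(abs(ph8$samples))
  if (mx > 1) ph8$samples <- ph8$samples / mx
  rt <- decode_speech(encode_speech(ph8, cfg_id), cfg_id)
  n <- length(a$samples)
  expect_equal(a$samples, rt$samples[1:n])
  # determinism of the noisy chain
  cfg <- channel_config(channel_snr_db = 10, seed = 77)
  d1 <- degrade(ph, cfg)
  d2 <- degrade(ph, cfg)
  expect_identical(d1$samples, d2$samples)
  expect_true(all(abs(d1$samples) <= 1))
  expect_gt(d1$meta$ber, 0)
})

test_that("F0 survives the hostile channel at 10 dB", {
  ph <- make_vowel(seed = 5)
  f0_cmd <- 120
  cfg <- channel_config(channel_snr_db = 10, seed = 3)
  out <- degrade(ph, cfg)
  cyc <- extract_cycles(preprocess(out))
  expect_equal(cyc$flag, "ok")
  expect_lt(abs(mean(cyc$f0_contour) - f0_cmd) / f0_cmd, 0.05)
})
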