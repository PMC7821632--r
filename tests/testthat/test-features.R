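test_that("the registry holds exactly 132 measures with fixed family sizes", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 132)
  expect_equal(anyDuplicated(reg$name), 0)
  sizes <- table(reg$family)
  expect_equal(as.vector(sizes[c("jitter", "shimmer", "mfcc", "f0")]),
               c(30L, 21L, 42L, 8L))
  # the remaining 31 split across the documented families
  expect_equal(sum(sizes[c("hnr", "gq", "rpde", "dfa", "ppe",
                           "gne", "vfer", "emd")]), 31L)
})

test_that("preprocess keeps exactly the central three seconds and normalizes", {
  fs <- 8000
  x <- phonation(sin(2 * pi * 150 * (0:(5 * fs - 1)) / fs) *
                   seq(0.2, 1, length.out = 5 * fs), fs)
  y <- preprocess(x)
  expect_equal(length(y$samples), 3 * fs)
  # 5 s input: samples from t = 1.0 s to 4.0 s
  expected <- x$samples[(fs + 1):(4 * fs)]
  expect_equal(y$samples, expected / max(abs(expected)))
  expect_equal(max(abs(y$samples)), 1)
  # exactly 3 s input: identity trim, rescale only
  x3 <- phonation(x$samples[1:(3 * fs)], fs)
  y3 <- preprocess(x3)
  expect_equal(y3$samples, x3$samples / max(abs(x3$samples)))
  # too-short input rejected
  expect_error(preprocess(phonation(numeric(2.9 * fs), fs)), "3 s")
})

test_that("a perfect 8 ms pulse train gives exactly 8 ms cycles at 125 Hz", {
  fs <- 24000
  s <- numeric(3.5 * fs)
  s[seq(1, length(s), by = 0.008 * fs)] <- 1
  cyc <- extract_cycles(preprocess(phonation(s, fs)))
  expect_equal(cyc$flag, "ok")
  expect_true(all(abs(cyc$lengths_s - 0.008) < 1e-9))
  expect_equal(mean(cyc$f0_contour), 125)
  # cycle marks cover at least 90% of the segment
  expect_gt(diff(range(cyc$onsets)) / length(preprocess(phonation(s, fs))$samples),
            0.9)
})

test_that("white noise is flagged unvoiced", {
  set.seed(8)
  cyc <- extract_cycles(preprocess(phonation(rnorm(3.2 * 8000) / 4, 8000)))
  expect_equal(cyc$flag, "unvoiced")
  expect_equal(length(cyc$lengths_s), 0)
})

test_that("jitter family matches hand computation and brute force", {
  # worked example: lengths 10,11,10,11 ms
  cyc <- cycle_seq(c(0.010, 0.011, 0.010, 0.011))
  j <- jitter_family(cyc)
  expect_equal(unname(j["jitter_local"]), 0.001 / 0.0105)
  expect_equal(unname(j["jitter_percent"]), 100 * 0.001 / 0.0105)
  expect_equal(length(j), 30)
  # brute-force oracle on random cycle sequences, 1e-12 relative
  set.seed(42)
  for (rep in 1:50) {
    t_ <- runif(sample(10:200, 1), 0.004, 0.012)
    jj <- jitter_family(cycle_seq(t_))
    expect_equal(unname(jj["jitter_local"]), bf_local_jitter(t_),
                 tolerance = 1e-12)
  }
  # constant cycle lengths: every variant is zero
  jz <- jitter_family(cycle_seq(rep(0.008, 60)))
  expect_true(all(jz == 0))
  # amplitude scaling leaves the jitter family untouched
  t_ <- runif(40, 0.006, 0.010)
  a_ <- runif(40, 0.3, 0.9)
  expect_equal(jitter_family(cycle_seq(t_, a_)),
               jitter_family(cycle_seq(t_, 2 * a_)))
  # too few cycles: missing with reason
  short <- jitter_family(cycle_seq(c(0.008, 0.008)[1]))
  expect_true(all(is.na(short)))
  expect_match(attr(short, "reason"), "few cycles")
})

test_that("shimmer family matches hand computation, brute force and its invariances", {
  cyc <- cycle_seq(rep(0.008, 4), c(1.0, 1.1, 1.0, 1.1))
  s <- shimmer_family(cyc)
  expect_equal(unname(s["shim_local"]), 0.1 / 1.05)
  expect_equal(length(s), 21)
  set.seed(43)
  for (rep in 1:50) {
    a_ <- runif(sample(10:200, 1), 0.2, 1)
    ss <- shimmer_family(cycle_seq(rep(0.008, length(a_)), a_))
    expect_equal(unname(ss["shim_local"]), bf_local_shimmer(a_),
                 tolerance = 1e-12)
  }
  # constant amplitudes: all zero
  sz <- shimmer_family(cycle_seq(runif(50, 0.006, 0.01), rep(0.7, 50)))
  expect_true(all(sz == 0))
  # uniform amplitude scaling and time dilation leave shimmer untouched
  t_ <- runif(40, 0.006, 0.010); a_ <- runif(40, 0.3, 0.9)
  expect_equal(shimmer_family(cycle_seq(t_, a_)),
               shimmer_family(cycle_seq(t_, 3 * a_)))
  expect_equal(shimmer_family(cycle_seq(t_, a_)),
               shimmer_family(cycle_seq(t_ * 2, a_)))
})

test_that("HNR is near its ceiling for noiseless vowels and falls with aspiration", {
  cyc0 <- make_cycles(jitter = 0, shimmer = 0, asp = Inf, wander = 0, seed = 2)
  ph0 <- preprocess(make_vowel(jitter = 0, shimmer = 0, asp = Inf,
                               wander = 0, seed = 2))
  h0 <- hnr_gq_family(ph0, cyc0)
  expect_gt(h0["hnr_mean"], 30)
  ph1 <- preprocess(make_vowel(jitter = 0, shimmer = 0, asp = 10,
                               wander = 0, seed = 2))
  h1 <- hnr_gq_family(ph1, extract_cycles(ph1))
  expect_lt(h1["hnr_mean"], h0["hnr_mean"])
  # GQ variability terms vanish on perfectly regular cycles
  expect_equal(unname(h0[c("gq_sd", "gq_local_var", "gq_range")]), c(0, 0, 0))
})

test_that("RPDE separates exact periodicity from noise", {
  ph <- preprocess(make_vowel(jitter = 0, shimmer = 0, asp = Inf,
                              wander = 0, seed = 2))
  r_per <- rpde(ph$samples, 24000)
  expect_lt(r_per, 0.3)     # first returns concentrated near one period
  set.seed(5)
  r_noise <- rpde(rnorm(24000), 8000)
  expect_gt(r_noise, 0.8)
  expect_true(r_per >= 0 && r_per <= 1 && r_noise <= 1)
})

test_that("DFA exponent is near 0.5 for white noise", {
  set.seed(11)
  ex <- replicate(10, dfa_exponent(rnorm(20000)))
  expect_lt(abs(mean(ex) - 0.5), 0.05)
})

test_that("PPE is minimal for a constant F0 contour", {
  const <- cycle_seq(rep(1 / 120, 120))
  expect_equal(ppe(const), 0)
  jittery <- cycle_seq(1 / (120 + cumsum(rnorm(120, 0, 2))))
  expect_gt(ppe(jittery), 0)
})

test_that("VFER sits at its ceiling for band-limited signals and falls with high-band noise", {
  fs <- 8000
  t_ <- (0:(fs * 3.2 - 1)) / fs
  clean <- 0.5 * sin(2 * pi * 300 * t_) + 0.3 * sin(2 * pi * 900 * t_) +
    0.2 * sin(2 * pi * 1500 * t_)
  sb0 <- snr_band_family(preprocess(phonation(clean, fs)))
  expect_gt(sb0["vfer_snr_energy"], 40)
  expect_lt(sb0["vfer_nsr_energy"], 1e-6)
  set.seed(3)
  hp <- fft_noise <- rnorm(length(clean))
  hp <- phonupdrs:::fft_bandpass(fft_noise, fs, 2600, 3900)
  snrs <- vapply(c(0.02, 0.1, 0.4), function(a) {
    snr_band_family(preprocess(phonation(clean + a * hp, fs)))["vfer_snr_energy"]
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
  expect_true(all(snrs < sb0["vfer_snr_energy"]))
})

test_that("EMD classifies no part of a clean low-frequency tone as noise", {
  fs <- 8000
  tone <- sin(2 * pi * 100 * (0:(fs * 3.2 - 1)) / fs)
  sb <- snr_band_family(preprocess(phonation(tone, fs)))
  expect_lt(sb["emd_nsr_energy"], 0.05)
  # and the decomposition itself reconstructs the signal
  de <- emd_decompose(tone[1:8000])
  recon <- Reduce(`+`, de$imfs) + de$residual
  expect_lt(max(abs(recon - tone[1:8000])), 1e-9)
})

test_that("MFCC family has 42 values with the cepstral gain property", {
  ph <- preprocess(make_vowel(seed = 5))
  m1 <- mfcc_family(ph)
  expect_equal(length(m1), 42)
  ph2 <- ph; ph2$samples <- 2 * ph$samples
  m2 <- mfcc_family(ph2)
  # log energy shifts by log(4) in log-power units; c1..c12 unchanged
  expect_equal(unname(m2["mfcc_logE"] - m1["mfcc_logE"]), log(4),
               tolerance = 1e-6)
  expect_lt(max(abs(m2[paste0("mfcc_c", 1:12)] - m1[paste0("mfcc_c", 1:12)])),
            1e-6)
  # a stationary vowel has near-zero delta features
  expect_lt(mean(abs(m1[grep("_d$", names(m1))])), 0.05)
})

test_that("F0 family summarizes the contour and the normative deviation", {
  const <- cycle_seq(rep(1 / 120, 100))
  f <- f0_family(const, "male", f0_norms = c(male = 120, female = 190))
  expect_equal(unname(f["f0_mean"]), 120)
  expect_equal(unname(f["f0_median"]), 120)
  expect_equal(unname(f["f0_sd"]), 0)
  expect_equal(unname(f["f0_rel_dev"]), 0)
  f132 <- f0_family(cycle_seq(rep(1 / 132, 100)), "male",
                    f0_norms = c(male = 120, female = 190))
  expect_equal(unname(f132["f0_rel_dev"]), 0.1)
  expect_equal(length(f), 8)
})

test_that("extract_all returns the 132-vector deterministically with flagged gaps", {
  ph <- make_vowel(seed = 5)
  v1 <- extract_all(ph, "male")
  expect_equal(length(v1), 132)
  expect_identical(names(v1), feature_registry()$name)
  expect_equal(sum(feature_registry()$family == "jitter"), 30)
  v2 <- extract_all(ph, "male")
  expect_identical(v1, v2)
  # unvoiced input carries reasons instead of silent drops
  set.seed(9)
  vn <- extract_all(phonation(rnorm(3.5 * 8000) / 4, 8000), "male")
  expect_equal(length(vn), 132)
  expect_true(sum(is.na(vn)) > 0)
  expect_true(length(attr(vn, "missing_reasons")) > 0)
})

test_that("measured local jitter rises with commanded jitter and HNR/VFER fall with aspiration", {
  jits <- c(0.005, 0.02, 0.05)
  meas <- vapply(jits, function(jf) {
    cyc <- make_cycles(jitter = jf, shimmer = 0, asp = Inf, wander = 0,
                       seed = 7)
    unname(jitter_family(cyc)["jitter_local"])
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
  asps <- c(30, 15, 5)
  hv <- vapply(asps, function(a) {
    ph <- preprocess(make_vowel(jitter = 0.005, shimmer = 0.02, asp = a,
                                wander = 0, seed = 7))
    cyc <- extract_cycles(ph)
    c(unname(hnr_gq_family(ph, cyc)["hnr_mean"]),
      unname(snr_band_family(ph)["vfer_snr_energy"]))
  }, numeric(2))
  expect_true(all(diff(hv[1, ]) < 0))
  expect_true(all(diff(hv[2, ]) < 0))
})
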