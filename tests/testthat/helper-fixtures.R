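# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

make_vowel <- function(f0 = 120, jitter = 0.005, shimmer = 0.02,
                       asp = 25, wander = 0.005, seed = 5, fs = 24000,
                       dur = 3.5, sex = "male") {
  key <- paste("vowel", f0, jitter, shimmer, asp, wander, seed, fs, dur,
               sex, sep = "_")
  cached(key, {
    p <- voice_params(f0_mean = f0, jitter_frac = jitter,
                      shimmer_frac = shimmer, aspiration_snr_db = asp,
                      f0_wander_frac = wander, duration_s = dur)
    synthesize_phonation(p, fs, seed = seed, sex = sex)
  })
}

make_cycles <- function(...) {
  args <- list(...)
  key <- paste("cyc", paste(unlist(args), collapse = "_"), sep = "_")
  cached(key, extract_cycles(preprocess(do.call(make_vowel, args))))
}

# hand-built cycle sequence for direct family-function tests
cycle_seq <- function(lengths_s, amplitudes = rep(1, length(lengths_s))) {
  structure(list(onsets = cumsum(c(1, round(lengths_s * 24000))),
                 lengths_s = lengths_s, amplitudes = amplitudes,
                 f0_contour = 1 / lengths_s, voiced_fraction = 1,
                 flag = "ok"),
            class = "cycle_sequence")
}

# independent brute-force oracles
bf_local_jitter <- function(t_) {
  s <- 0
  for (i in seq_len(length(t_) - 1L)) s <- s + abs(t_[i + 1L] - t_[i])
  (s / (length(t_) - 1L)) / (sum(t_) / length(t_))
}

bf_local_shimmer <- function(a) bf_local_jitter(a)

bf_mae <- function(p, y) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - y[i])
  s / length(p)
}

# synthetic design matrix with known informative features (no audio):
# 5 informative columns linearly tied to the class response, the rest noise
informative_matrix <- function(n = 200, m = 132, n_inf = 5, seed = 1,
                               snr = 1.5) {
  set.seed(seed)
  y <- sample(1:5, n, replace = TRUE)
  X <- matrix(rnorm(n * m), n, m)
  for (j in seq_len(n_inf)) X[, j] <- X[, j] + snr * scale(y)[, 1]
  colnames(X) <- sprintf("feat_%03d", seq_len(m))
  list(X = X, y = y, informative = colnames(X)[seq_len(n_inf)])
}

# direct-feature synthetic cohort for the validation-scheme tests:
# per-subject weekly UPDRS trajectories plus feature rows linked to the
# severity with additive noise, skipping the audio path
feature_cohort <- function(n_subjects = 10, n_weeks = 8, rows_per_week = 2,
                           link = 1, noise = 1, rate_mean = 0.3, seed = 1) {
  set.seed(seed)
  base <- runif(n_subjects, 15, 55)
  rate <- rnorm(n_subjects, rate_mean, 0.2)
  rows <- list()
  for (s in seq_len(n_subjects)) for (w in 0:n_weeks)
    for (r in seq_len(rows_per_week))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", s), week = w,
        y = min(max(base[s] + rate[s] * w, 0), 176))
  man <- do.call(rbind, rows)
  n <- nrow(man)
  X <- cbind(f1 = link * man$y + rnorm(n, 0, noise),
             f2 = -0.5 * link * man$y + rnorm(n, 0, noise),
             f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n))
  list(X = X, manifest = man, y = man$y)
}
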