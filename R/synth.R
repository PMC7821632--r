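#' Default voice synthesis parameters
#'
#' Parameters of the source-filter sustained-/ah:/ synthesizer. The source
#' is a Rosenberg-style glottal pulse train with per-cycle period
#' perturbation (`jitter_frac`), per-cycle amplitude perturbation
#' (`shimmer_frac`), slow F0 wander, and additive aspiration noise at
#' `aspiration_snr_db` relative to the voiced component; the filter is a
#' cascade of three formant resonators with /ah:/ defaults (F2 kept below
#' the ~1.7 kHz upper bound typical of the sustained /ah:/).
#'
#' @param f0_mean mean fundamental frequency in Hz (> 0).
#' @param jitter_frac commanded cycle-to-cycle period perturbation,
#'   dimensionless; calibrated so the classical local jitter measured on the
#'   synthesized cycles equals this value in expectation. Must be < 0.5.
#' @param shimmer_frac commanded cycle-to-cycle amplitude perturbation,
#'   same convention as `jitter_frac`.
#' @param aspiration_snr_db voiced-to-aspiration SNR in dB; `Inf` disables
#'   aspiration noise.
#' @param f0_wander_frac fractional amplitude of slow (vibrato-band) F0
#'   wander.
#' @param formants list of `c(center_hz, bandwidth_hz)` resonators.
#' @param duration_s phonation length in seconds (>= 3; the feature path
#'   analyzes the middle 3 s).
#' @param loudness_gain linear output gain; the loud session slots command
#'   a doubled gain.
#' @return a `voice_params` list.
#' @export
voice_params <- function(f0_mean = 120, jitter_frac = 0.005,
                         shimmer_frac = 0.03, aspiration_snr_db = 25,
                         f0_wander_frac = 0.005,
                         formants = list(c(700, 80), c(1200, 90), c(2600, 120)),
                         duration_s = 3.5, loudness_gain = 1) {
  stopifnot(f0_mean > 0, duration_s >= 3,
            jitter_frac >= 0, jitter_frac < 0.5,
            shimmer_frac >= 0, shimmer_frac < 0.5,
            f0_wander_frac >= 0, f0_wander_frac < 0.5,
            loudness_gain > 0)
  structure(list(f0_mean = f0_mean, jitter_frac = jitter_frac,
                 shimmer_frac = shimmer_frac,
                 aspiration_snr_db = aspiration_snr_db,
                 f0_wander_frac = f0_wander_frac, formants = formants,
                 duration_s = duration_s, loudness_gain = loudness_gain),
            class = "voice_params")
}

# Sex-specific baseline voices: females have higher F0 on average.
base_voice_for_sex <- function(sex) {
  if (sex == "female") voice_params(f0_mean = 190)
  else voice_params(f0_mean = 120)
}

#' Map a UPDRS score to degraded voice parameters
#'
#' Encodes the monotone severity-to-acoustics link the pipeline is designed
#' to recover: higher UPDRS increases jitter, shimmer and F0 wander and
#' decreases the aspiration SNR (more breathiness) and the loudness gain
#' (hypophonia). The link is linear in UPDRS on every parameter with
#' sex-specific slopes, scaled by `link_strength`; `link_strength = 0`
#' returns `base` unchanged. A small seeded between-recording scatter makes
#' repeated phonations at the same severity differ realistically.
#'
#' @param updrs total-UPDRS-scale severity in \[0, 176\].
#' @param sex "male" or "female".
#' @param base baseline `voice_params` for a (near-)healthy voice.
#' @param link_strength nonnegative multiplier on all severity slopes;
#'   1 is the default study condition.
#' @param seed integer seed for the per-recording scatter; `NULL` disables
#'   scatter.
#' @return a `voice_params` object.
#' @export
severity_to_voice_params <- function(updrs, sex = c("male", "female"),
                                     base = NULL, link_strength = 1,
                                     seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(updrs), length(updrs) == 1L, updrs >= 0, updrs <= 176)
  if (link_strength < 0) stop("link_strength must be nonnegative")
  if (is.null(base)) base <- base_voice_for_sex(sex)
  # Sex-specific slopes: F0-linked degradation expresses more strongly in
  # females, energy-linked degradation in both (cf. the gender-dependent
  # feature selection this emulates).
  sx <- if (sex == "female") 1.25 else 1.0
  scatter <- if (is.null(seed)) rep(1, 5) else
    with_seed(child_seed(seed, "scatter"), exp(stats::rnorm(5, 0, 0.05)))
  p <- base
  p$jitter_frac <- min(0.45, (base$jitter_frac +
    link_strength * updrs * 2.5e-4 * sx) * scatter[1])
  p$shimmer_frac <- min(0.45, (base$shimmer_frac +
    link_strength * updrs * 8e-4) * scatter[2])
  p$f0_wander_frac <- min(0.45, (base$f0_wander_frac +
    link_strength * updrs * 1.2e-4 * sx) * scatter[3])
  p$aspiration_snr_db <- (base$aspiration_snr_db -
    link_strength * updrs * 0.22) * scatter[4]
  p$loudness_gain <- max(0.15, base$loudness_gain *
    (1 - link_strength * updrs * 0.006) * scatter[5])
  p
}

# Rosenberg glottal pulse sampled at `n` points over one cycle:
# rising limb over the open phase, sharp closure, closed phase at zero.
rosenberg_pulse <- function(n, open_quotient = 0.6, speed_quotient = 3) {
  n_open <- max(2L, round(n * open_quotient))
  n_rise <- max(1L, round(n_open * speed_quotient / (speed_quotient + 1)))
  n_fall <- max(1L, n_open - n_rise)
  t1 <- seq_len(n_rise) / n_rise
  rise <- 3 * t1^2 - 2 * t1^3
  t2 <- seq_len(n_fall) / n_fall
  fall <- 1 - t2^2
  c(rise, fall, numeric(max(0L, n - n_rise - n_fall)))[seq_len(n)]
}

apply_formants <- function(x, fs, formants) {
  for (fm in formants) {
    r <- exp(-pi * fm[2] / fs)
    th <- 2 * pi * fm[1] / fs
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  x
}

# |x - y| for iid standard normals has mean 2/sqrt(pi); commanded jitter /
# shimmer fractions are divided by it so the classical local measures on
# the generated cycle sequences match the command in expectation.
.PERT_CAL <- 2 / sqrt(pi)

#' Synthesize a sustained /ah:/ phonation
#'
#' Source-filter synthesis: a glottal pulse train with commanded per-cycle
#' period and amplitude perturbations and slow F0 wander is passed through
#' the formant resonator cascade; aspiration noise (white Gaussian shaped
#' by the same formant filter) is added at the commanded SNR. The commanded
#' per-cycle periods and amplitudes are kept in `meta$commanded_cycles` as
#' ground truth for closed-loop tests.
#'
#' @param params a `voice_params` object.
#' @param sample_rate output sampling rate in Hz; must be at least twice
#'   the highest formant center frequency.
#' @param seed integer seed; identical (params, sample_rate, seed) gives
#'   identical waveforms.
#' @param ... provenance fields passed to [phonation()].
#' @return a `phonation`.
#' @export
synthesize_phonation <- function(params, sample_rate = 24000, seed = 1, ...) {
  stopifnot(inherits(params, "voice_params"))
  fmax <- max(vapply(params$formants, `[`, numeric(1), 1L))
  if (sample_rate < 2 * fmax)
    stop("sample_rate must be at least twice the highest formant frequency")
  with_seed(child_seed(seed, "synth"), {
    fs <- sample_rate
    n_total <- round(params$duration_s * fs)
    t0 <- fs / params$f0_mean                 # mean period in samples
    n_cyc <- ceiling(n_total / t0) + 8L
    # slow F0 wander: vibrato-like sinusoid plus smoothed random walk
    vib_f <- stats::runif(1, 4.5, 6)
    vib_ph <- stats::runif(1, 0, 2 * pi)
    wob <- stats::filter(stats::rnorm(n_cyc), rep(1 / 15, 15), sides = 1)
    wob[is.na(wob)] <- 0
    wob <- as.numeric(wob) / max(stats::sd(wob), 1e-9)
    jit <- stats::rnorm(n_cyc) * params$jitter_frac / .PERT_CAL
    shm <- 1 + stats::rnorm(n_cyc) * params$shimmer_frac / .PERT_CAL
    shm <- pmax(shm, 0.05)
    # accumulate cycle onsets
    onsets <- numeric(n_cyc); lens <- numeric(n_cyc)
    pos <- 1
    for (i in seq_len(n_cyc)) {
      cyc_time <- pos / fs
      wander <- 1 + params$f0_wander_frac *
        (sin(2 * pi * vib_f * cyc_time + vib_ph) + 0.5 * wob[i])
      len <- t0 / wander * (1 + jit[i])
      onsets[i] <- pos; lens[i] <- len
      pos <- pos + len
      if (pos > n_total + t0) { n_cyc <- i; break }
    }
    onsets <- onsets[seq_len(n_cyc)]; lens <- lens[seq_len(n_cyc)]
    src <- numeric(n_total + ceiling(2 * t0))
    # fixed pulse shape (duration tied to the mean period, not the jittered
    # cycle): the peak then sits at a constant delay after each onset, so
    # commanded period jitter transfers one-to-one to waveform peak spacing
    li <- max(3L, round(t0))
    base_pulse <- rosenberg_pulse(li)
    for (i in seq_len(n_cyc)) {
      # fractional-delay placement (linear interpolation between grid
      # points) so sub-sample period jitter survives synthesis
      o_int <- floor(onsets[i])
      frac <- onsets[i] - o_int
      idx <- o_int + seq_len(li + 1L) - 1L
      pl <- c(base_pulse, 0) * (1 - frac) + c(0, base_pulse) * frac
      keep <- idx <= length(src) & idx >= 1L
      src[idx[keep]] <- src[idx[keep]] + pl[keep] * shm[i]
    }
    src <- src[seq_len(n_total)]
    voiced <- apply_formants(src, fs, params$formants)
    voiced <- voiced - mean(voiced)
    if (is.finite(params$aspiration_snr_db)) {
      noise <- apply_formants(stats::rnorm(n_total), fs, params$formants)
      pv <- mean(voiced^2)
      pn <- mean(noise^2)
      noise <- noise * sqrt(pv / pn / 10^(params$aspiration_snr_db / 10))
      x <- voiced + noise
    } else x <- voiced
    x <- x / max(abs(x)) * 0.45 * params$loudness_gain
    x <- pmin(pmax(x, -1), 1)
    phonation(x, fs,
              meta = list(params = params,
                          commanded_cycles = list(onsets = onsets,
                                                  lengths_s = lens / fs,
                                                  amplitudes = shm[seq_len(n_cyc)])),
              ...)
  })
}

#' Generate a synthetic PD cohort
#'
#' Emulates the shape of an at-home PD telemonitoring trial: `n_male` +
#' `n_female` subjects, each with clinical UPDRS assessments at weeks 0, 13
#' and 26 and weekly recording sessions of six sustained phonations (slots
#' 1-4 comfortable loudness, slots 5-6 at twice the comfortable loudness).
#' True weekly severity follows a near-linear trajectory (baseline +
#' per-week progression + small Gaussian wobble, clipped to scale range);
#' the weekly modelling response is the piecewise-linear interpolation
#' through the three clinical assessments, exactly as a trial would use.
#'
#' @param n_male,n_female subject counts (at least one subject in total,
#'   each count >= 0, the study default is 28 + 14).
#' @param n_weeks last trial week with a session (default 26; sessions at
#'   weeks 0..n_weeks).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a `pd_cohort` list with `subjects`, `trajectories` (per
#'   subject-week true and interpolated motor/total UPDRS) and `sessions`
#'   (subject, week, slot, loudness) data frames.
#' @export
generate_cohort <- function(n_male = 28, n_female = 14, n_weeks = 26,
                            seed = 1) {
  stopifnot(n_male >= 0, n_female >= 0, n_weeks >= 0)
  if (n_male + n_female < 1) stop("cohort must contain at least one subject")
  with_seed(child_seed(seed, "cohort"), {
    n <- n_male + n_female
    sex <- c(rep("male", n_male), rep("female", n_female))
    id <- sprintf("S%03d", seq_len(n))
    # baseline scores and progression emulate the early-PD trial profile:
    # males motor 20.3 +/- 8.5 progressing ~ +1.7 over 26 weeks, females
    # 17.6 +/- 7.4 progressing ~ +2.5; total ~ motor + 7-9 points
    base_motor <- ifelse(sex == "male",
                         stats::rnorm(n, 20.3, 8.5), stats::rnorm(n, 17.6, 7.4))
    base_motor <- pmin(pmax(base_motor, 3), 60)
    tot_off <- pmax(stats::rnorm(n, 7.5, 3), 1)
    rate_motor <- ifelse(sex == "male",
                         stats::rnorm(n, 0.065, 0.09), stats::rnorm(n, 0.096, 0.09))
    rate_tot <- rate_motor + stats::rnorm(n, 0.04, 0.04)
    age <- round(ifelse(sex == "male", stats::rnorm(n, 64.8, 8.1),
                        stats::rnorm(n, 63.6, 11.6)))
    subjects <- data.frame(subject_id = id, sex = sex, age = age,
                           baseline_motor = base_motor,
                           baseline_total = pmin(base_motor + tot_off, 176),
                           progression_rate = rate_tot,
                           n_weeks = n_weeks, stringsAsFactors = FALSE)
    weeks_all <- 0:26
    traj <- vector("list", n)
    for (i in seq_len(n)) {
      wob_m <- cumsum(stats::rnorm(length(weeks_all), 0, 0.35))
      wob_t <- wob_m + stats::rnorm(length(weeks_all), 0, 0.2)
      motor_true <- pmin(pmax(base_motor[i] + rate_motor[i] * weeks_all +
                                wob_m, 0), 108)
      total_true <- pmin(pmax(subjects$baseline_total[i] +
                                rate_tot[i] * weeks_all + wob_t, 0), 176)
      total_true <- pmax(total_true, motor_true)   # total contains motor
      assess <- data.frame(week = c(0, 13, 26),
                           motor = motor_true[c(1, 14, 27)],
                           total = total_true[c(1, 14, 27)])
      interp <- interpolate_weekly(assess)
      traj[[i]] <- data.frame(subject_id = id[i], week = weeks_all,
                              motor_true = motor_true,
                              total_true = total_true,
                              motor_interp = interp$motor,
                              total_interp = interp$total,
                              stringsAsFactors = FALSE)
    }
    trajectories <- do.call(rbind, traj)
    sessions <- expand.grid(slot = 1:6, week = 0:n_weeks,
                            subject_id = id, stringsAsFactors = FALSE)
    sessions <- sessions[, c("subject_id", "week", "slot")]
    sessions$loudness <- ifelse(sessions$slot <= 4, "comfortable", "loud")
    rownames(sessions) <- NULL
    structure(list(subjects = subjects, trajectories = trajectories,
                   sessions = sessions, seed = seed),
              class = "pd_cohort")
  })
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("<pd_cohort> %d subjects (%d male, %d female), sessions to week %d, %d phonation slots\n",
              nrow(x$subjects), sum(x$subjects$sex == "male"),
              sum(x$subjects$sex == "female"),
              max(x$sessions$week), nrow(x$sessions)))
  invisible(x)
}

#' Synthesize the waveform for one cohort session slot
#'
#' Looks up the subject's true total-UPDRS at the session week, maps it to
#' voice parameters via [severity_to_voice_params()] and synthesizes the
#' phonation; loud slots (5-6) double the loudness gain.
#'
#' @param cohort a `pd_cohort`.
#' @param subject_id,week,slot session coordinates.
#' @param link_strength severity-link multiplier.
#' @param sample_rate synthesis rate in Hz.
#' @param seed integer seed; the per-slot stream is derived from it.
#' @return a `phonation` with provenance filled in.
#' @export
synthesize_slot <- function(cohort, subject_id, week, slot,
                            link_strength = 1, sample_rate = 24000,
                            seed = 1) {
  subj <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  stopifnot(nrow(subj) == 1L, slot %in% 1:6)
  tr <- cohort$trajectories
  row <- tr[tr$subject_id == subject_id & tr$week == week, ]
  stopifnot(nrow(row) == 1L)
  slot_seed <- child_seed(seed, paste(subject_id, week, slot, sep = "_"))
  p <- severity_to_voice_params(row$total_true, subj$sex,
                                link_strength = link_strength,
                                seed = slot_seed)
  if (slot >= 5) p$loudness_gain <- p$loudness_gain * 2
  ph <- synthesize_phonation(p, sample_rate, seed = slot_seed,
                             subject_id = subject_id, sex = subj$sex,
                             week = as.integer(week), slot = as.integer(slot),
                             loudness = if (slot >= 5) "loud" else "comfortable")
  ph
}

#' Write a cohort's phonations as WAV files plus a manifest
#'
#' One 16-bit PCM WAV per session slot, and a tab-delimited manifest with
#' subject, sex, week, slot, loudness, file path and the interpolated
#' motor/total UPDRS response used for modelling.
#'
#' @param cohort a `pd_cohort`.
#' @param out_dir output directory (created if needed).
#' @param link_strength,sample_rate,seed passed to [synthesize_slot()].
#' @param weeks,slots optional subsets of session weeks / slots to render.
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, link_strength = 1,
                         sample_rate = 24000, seed = 1,
                         weeks = NULL, slots = 1:6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ses <- cohort$sessions
  if (!is.null(weeks)) ses <- ses[ses$week %in% weeks, ]
  ses <- ses[ses$slot %in% slots, ]
  tr <- cohort$trajectories
  rows <- vector("list", nrow(ses))
  for (i in seq_len(nrow(ses))) {
    s <- ses[i, ]
    ph <- synthesize_slot(cohort, s$subject_id, s$week, s$slot,
                          link_strength, sample_rate, seed)
    f <- file.path(out_dir, sprintf("%s_w%02d_s%d.wav",
                                    s$subject_id, s$week, s$slot))
    write_wav(ph, f)
    trow <- tr[tr$subject_id == s$subject_id & tr$week == s$week, ]
    rows[[i]] <- data.frame(subject_id = s$subject_id, sex = ph$sex,
                            week = s$week, slot = s$slot,
                            loudness = s$loudness, wav_path = f,
                            motor_updrs = trow$motor_interp,
                            total_updrs = trow$total_interp,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
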