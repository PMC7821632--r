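#' Build the dysphonia design matrix for a synthetic cohort
#'
#' Runs the generation and measurement chain end to end: for every
#' requested session slot, synthesize the phonation at the subject's true
#' severity, optionally push it through the degradation chain, and extract
#' the 132 dysphonia measures. Each phonation gets its own derived seed,
#' so the result is deterministic given `seed`.
#'
#' @param cohort a `pd_cohort` from [generate_cohort()].
#' @param link_strength severity-link multiplier for the voice synthesis.
#' @param channel optional `channel_config`; `NULL` keeps clean audio.
#' @param weeks,slots session subsets to render (defaults: all weeks,
#'   all six slots).
#' @param sample_rate synthesis rate in Hz.
#' @param seed integer seed.
#' @return list with `X` (n x 132 feature matrix) and `manifest`
#'   (subject_id, sex, week, slot, loudness, motor and total interpolated
#'   UPDRS per row).
#' @export
build_design_matrix <- function(cohort, link_strength = 1, channel = NULL,
                                weeks = NULL, slots = 1:6,
                                sample_rate = 24000, seed = 1) {
  ses <- cohort$sessions
  if (!is.null(weeks)) ses <- ses[ses$week %in% weeks, ]
  ses <- ses[ses$slot %in% slots, ]
  if (nrow(ses) == 0L) stop("no sessions selected")
  tr <- cohort$trajectories
  rows <- vector("list", nrow(ses))
  feats <- vector("list", nrow(ses))
  for (i in seq_len(nrow(ses))) {
    s <- ses[i, ]
    ph <- synthesize_slot(cohort, s$subject_id, s$week, s$slot,
                          link_strength, sample_rate, seed)
    if (!is.null(channel)) {
      cfg <- channel
      cfg$seed <- child_seed(seed, paste("chan", s$subject_id, s$week,
                                         s$slot, sep = "_"))
      ph <- degrade(ph, cfg)
    }
    feats[[i]] <- as.numeric(extract_all(ph))
    trow <- tr[tr$subject_id == s$subject_id & tr$week == s$week, ]
    rows[[i]] <- data.frame(subject_id = s$subject_id, sex = ph$sex,
                            week = s$week, slot = s$slot,
                            loudness = s$loudness,
                            motor_updrs = trow$motor_interp,
                            total_updrs = trow$total_interp,
                            stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, feats)
  colnames(X) <- feature_registry()$name
  list(X = X, manifest = do.call(rbind, rows))
}

#' Run the full estimation pipeline on one sex stratum
#'
#' Feature-selection voting on the design matrix followed by repeated
#' 10-fold cross-validation of the random-forest mapping with the chosen
#' subset, plus the dummy-predictor baseline under the same protocol.
#'
#' @param X feature matrix from [build_design_matrix()].
#' @param y response scores for the same rows.
#' @param fs_algorithm selector passed to [vote_select()].
#' @param k subset size (chosen upstream, e.g. with [choose_k_one_se()]).
#' @param n_repeats CV repeats.
#' @param rf_params random-forest overrides.
#' @param seed integer seed.
#' @param scale UPDRS scale.
#' @return list with `fs` (the `fs_result`), `cv` and `dummy`
#'   (`validation_report`s).
#' @export
run_pipeline <- function(X, y, fs_algorithm = "relief", k = 20L,
                         n_repeats = 10L, rf_params = list(ntree = 200L),
                         seed = 1, scale = "total") {
  imp <- impute_medians(X)
  fs <- vote_select(imp$X, discretize(y, scale), algorithm = fs_algorithm,
                    n_perturbations = 10L, top_m = max(30L, k), seed = seed,
                    k = k)
  cv <- cross_validate(X, y, n_repeats = n_repeats,
                       feature_subset = fs$selected, params = rf_params,
                       seed = seed, scale = scale)
  dummy <- cross_validate_dummy(y, n_repeats = n_repeats, seed = seed,
                                scale = scale)
  list(fs = fs, cv = cv, dummy = dummy)
}
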