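test_that("weekly interpolation is exact at assessments and linear between", {
  assess <- data.frame(week = c(0, 13, 26), motor = c(20, 26, 26))
  tr <- interpolate_weekly(assess)
  expect_equal(tr$motor[tr$week == 0], 20)
  expect_equal(tr$motor[tr$week == 13], 26)
  expect_equal(interpolate_weekly(assess, weeks = 6.5)$motor, 23)
  expect_true(all(tr$motor[tr$week >= 13] == 26))     # flat final segment
  flat <- interpolate_weekly(data.frame(week = c(0, 13, 26),
                                        motor = c(18, 18, 18)))
  expect_true(all(flat$motor == 18))
  expect_error(interpolate_weekly(data.frame(week = c(0, 13, 13),
                                             motor = c(1, 2, 3))), "duplicate")
})

test_that("discretization rounds to the nearest integer, half away from zero", {
  expect_equal(discretize(22.4), 22L)
  expect_equal(discretize(22.5), 23L)
  expect_equal(discretize(0.0), 0L)
  expect_equal(discretize(c(1.49, 1.51)), c(1L, 2L))
  expect_error(discretize(-1), "range")
  expect_error(discretize(120, "motor"), "range")
  expect_equal(discretize(120, "total"), 120L)
})

test_that("MAE matches hand arithmetic and a brute-force loop to 1e-12", {
  expect_equal(mae(c(3, 2), c(1, 2)), 1.0)
  expect_equal(mae(1:5, 1:5), 0)
  set.seed(12)
  p <- rnorm(1000, 20, 5); y <- rnorm(1000, 20, 5)
  expect_equal(mae(p, y), bf_mae(p, y), tolerance = 1e-12)
  expect_error(mae(1:3, 1:4), "mismatch")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("the classifier mapping memorizes separable data and refuses leakage columns", {
  set.seed(20)
  n <- 120
  y <- rep(c(10, 20, 30), each = n / 3)
  X <- cbind(f1 = y + rnorm(n, 0, 0.3), f2 = rnorm(n))
  colnames(X) <- c("f1", "f2")
  fit <- updrs_fit(X, y, params = list(ntree = 100), seed = 1)
  expect_s3_class(fit, "updrs_fit")
  pred <- predict(fit, X)
  expect_lt(mae(pred, y), 0.5)
  # single-class training response: constant prediction
  fitc <- updrs_fit(X, rep(15, n), params = list(ntree = 50), seed = 1)
  expect_true(all(predict(fitc, X) == 15L))
  # identifier/timing columns are refused
  Xbad <- cbind(X, week = seq_len(n))
  expect_error(updrs_fit(Xbad, y), "timing")
  # unknown feature subsets are refused
  expect_error(updrs_fit(X, y, feature_subset = "nope"), "not in matrix")
})

test_that("cross-validation reports the 90/10 split arithmetic of the trial sizes", {
  set.seed(21)
  for (spec_n in list(c(4010, 3609, 401), c(1865, 1679, 186))) {
    n <- spec_n[1]
    X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
    colnames(X) <- c("f1", "f2")
    y <- sample(20:24, n, replace = TRUE)
    rep_ <- cross_validate(X, y, n_repeats = 1, params = list(ntree = 4),
                           seed = 1)
    expect_equal(unname(rep_$n_train), spec_n[2])
    expect_equal(unname(rep_$n_test), spec_n[3])
  }
})

test_that("repeated CV beats the dummy baseline on linked features and not on noise", {
  sim <- feature_cohort(n_subjects = 12, n_weeks = 6, rows_per_week = 2,
                        link = 1, noise = 2, seed = 2)
  cv <- cross_validate(sim$X, sim$y, n_repeats = 5,
                       params = list(ntree = 100), seed = 3)
  dum <- cross_validate_dummy(sim$y, n_repeats = 5, seed = 3)
  expect_lt(cv$mae_mean, dum$mae_mean)
  expect_equal(length(cv$per_repeat_mae), 5)
  expect_true(cv$ci95[1] <= cv$mae_mean && cv$mae_mean <= cv$ci95[2])
  expect_true(all(cv$per_repeat_mae >= 0))
  # pure-noise features: no better than dummy (CI overlap)
  noise_X <- sim$X[, c("f3", "f4", "f5")]
  cvn <- cross_validate(noise_X, sim$y, n_repeats = 5,
                        params = list(ntree = 100), seed = 3)
  expect_gt(cvn$ci95[2], dum$ci95[1])
  expect_error(cross_validate(sim$X[1:5, ], sim$y[1:5], n_folds = 10),
               "folds")
})

test_that("tracking validation calibrates on early weeks and never trains on test rows", {
  # constant-trajectory cohort: the calibration feature alone suffices
  sim <- feature_cohort(n_subjects = 6, n_weeks = 8, rows_per_week = 2,
                        link = 0, noise = 1, seed = 4)
  sim$manifest$y <- ave(sim$manifest$y, sim$manifest$subject_id,
                        FUN = function(v) round(mean(v)))
  rep_ <- tracking_validate(sim$X, sim$manifest, sim$manifest$y,
                            calibration_weeks = 4,
                            params = list(ntree = 150), seed = 5)
  expect_lt(rep_$mae_mean, 1.0)
  # partition property: test rows belong to the left-out subject's late
  # weeks and are disjoint from that model's training rows
  for (sid in names(rep_$partitions)) {
    pt <- rep_$partitions[[sid]]
    expect_length(intersect(pt$train, pt$test), 0)
    expect_true(all(sim$manifest$subject_id[pt$test] == sid))
    expect_true(all(sim$manifest$week[pt$test] >= 4))
    own_train <- pt$train[sim$manifest$subject_id[pt$train] == sid]
    expect_true(all(sim$manifest$week[own_train] < 4))
  }
  expect_error(tracking_validate(sim$X[1:4, ], sim$manifest[1:4, ],
                                 sim$manifest$y[1:4]), "2 subjects")
})

test_that("tracking is at least as hard as pooled CV on progressing cohorts", {
  # tracking extrapolates months past the calibration window while pooled
  # CV interpolates within-subject, so with real symptom progression the
  # tracking error should not be smaller
  wins <- 0
  for (seed in 1:6) {
    sim <- feature_cohort(n_subjects = 8, n_weeks = 12, rows_per_week = 2,
                          link = 1, noise = 2, rate_mean = 0.8, seed = seed)
    cv <- cross_validate(sim$X, sim$y, n_repeats = 2,
                         params = list(ntree = 80), seed = seed)
    trk <- tracking_validate(sim$X, sim$manifest, sim$y,
                             calibration_weeks = 4,
                             params = list(ntree = 80), seed = seed)
    if (trk$mae_mean >= cv$mae_mean) wins <- wins + 1
  }
  expect_gte(wins, 4)    # majority of seeds
})

test_that("Spearman report flags constants and recovers exact monotone association", {
  set.seed(30)
  y <- rnorm(120, 25, 6)
  X <- cbind(same = y, anti = -y, flat = rep(1, 120), noise = rnorm(120))
  colnames(X) <- c("same", "anti", "flat", "noise")
  rep_ <- spearman_report(X, y)
  expect_equal(rep_$rho[rep_$feature == "same"], 1)
  expect_equal(rep_$rho[rep_$feature == "anti"], -1)
  expect_equal(rep_$flag[rep_$feature == "flat"], "constant")
  expect_true(is.na(rep_$rho[rep_$feature == "flat"]))
  expect_error(spearman_report(X, rep(3, 120)), "constant")
})

test_that("independent noise features show no spurious Spearman association", {
  set.seed(31)
  hits <- 0
  for (i in 1:100) {
    y <- rnorm(500)
    v <- rnorm(500)
    if (abs(suppressWarnings(cor(v, y, method = "spearman"))) < 0.15)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})
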