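# Mapping module: response preparation (weekly interpolation and integer
# discretization), the random-forest classifier mapping, repeated 10-fold
# cross-validation and the subject-calibrated tracking validation, MAE and
# confidence-interval reporting, and the per-feature Spearman association
# report.

.FORBIDDEN_COLS <- c("subject_id", "subject", "age", "week", "time",
                     "session", "slot")

#' Piecewise-linear weekly UPDRS interpolation
#'
#' Interpolates sparse clinical assessments (typically weeks 0, 13, 26)
#' to weekly values, passing exactly through the measured assessments and
#' linear in between.
#'
#' @param assessments data frame with columns `week` and one or more score
#'   columns (e.g. `motor`, `total`); weeks must be distinct and sorted.
#' @param weeks weeks at which to evaluate (default 0 to the last
#'   assessment week).
#' @return data frame with `week` and the interpolated score columns.
#' @export
interpolate_weekly <- function(assessments, weeks = NULL) {
  stopifnot(is.data.frame(assessments), "week" %in% names(assessments),
            nrow(assessments) >= 2L)
  w <- assessments$week
  if (anyDuplicated(w)) stop("duplicate assessment weeks")
  if (is.unsorted(w)) stop("assessment weeks must be sorted")
  if (is.null(weeks)) weeks <- seq(min(w), max(w))
  out <- data.frame(week = weeks)
  for (col in setdiff(names(assessments), "week"))
    out[[col]] <- stats::approx(w, assessments[[col]], xout = weeks,
                                rule = 2)$y
  out
}

#' Round an interpolated UPDRS score to its integer class
#'
#' Nearest-integer discretization turning the regression target into a
#' multi-class one; exact .5 ties round half away from zero.
#'
#' @param y numeric score(s).
#' @param scale "motor" (range 0-108) or "total" (range 0-176).
#' @return integer class(es).
#' @export
discretize <- function(y, scale = c("total", "motor")) {
  scale <- match.arg(scale)
  hi <- if (scale == "motor") 108 else 176
  if (any(y < 0 | y > hi)) stop("score outside the ", scale, "-UPDRS range")
  as.integer(floor(y + 0.5))
}

#' Mean absolute error
#'
#' @param predicted,actual equal-length nonempty numeric vectors.
#' @return mean of the absolute differences.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) == 0L) stop("empty input")
  mean(abs(predicted - actual))
}

impute_medians <- function(X, medians = NULL) {
  if (is.null(medians))
    medians <- apply(X, 2L, function(v) stats::median(v[is.finite(v)]))
  medians[!is.finite(medians)] <- 0
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- medians[j]
  }
  list(X = X, medians = medians)
}

#' Fit the UPDRS classifier mapping
#'
#' Random-forest multi-class classification of the discretized UPDRS on
#' the dysphonia measures; the predicted score is the predicted class
#' label as an integer. Subject identifiers, age and timing columns are
#' refused as predictors so the mapping cannot lean on them. Missing
#' feature values are imputed by training-set medians.
#'
#' @param X numeric training feature matrix with registry column names.
#' @param y training response (integer UPDRS classes, or scores which are
#'   discretized with [discretize()]).
#' @param feature_subset optional character vector of features to use.
#' @param params list of random-forest overrides (`ntree`, `mtry`).
#' @param seed integer seed; fits are deterministic given it.
#' @param scale UPDRS scale for discretization.
#' @return an object of class `updrs_fit`.
#' @export
updrs_fit <- function(X, y, feature_subset = NULL, params = list(),
                      seed = 1, scale = "total") {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  bad <- intersect(tolower(colnames(X)), .FORBIDDEN_COLS)
  if (length(bad))
    stop("identifier/timing columns must not enter the mapping: ",
         paste(bad, collapse = ", "))
  if (!is.null(feature_subset)) {
    missing_feats <- setdiff(feature_subset, colnames(X))
    if (length(missing_feats))
      stop("features not in matrix: ", paste(missing_feats, collapse = ", "))
    X <- X[, feature_subset, drop = FALSE]
  }
  yc <- if (is.integer(y)) y else discretize(y, scale)
  imp <- impute_medians(X)
  ntree <- params$ntree %||% 500L
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(X))))
  fit <- if (length(unique(yc)) < 2L) NULL else
    with_seed(child_seed(seed, "rf_fit"),
              randomForest::randomForest(imp$X, factor(yc),
                                         ntree = ntree, mtry = mtry))
  structure(list(forest = fit, features = colnames(X),
                 medians = imp$medians, levels = levels(factor(yc)),
                 constant = if (is.null(fit)) yc[1],
                 n_train = nrow(X), scale = scale, seed = seed),
            class = "updrs_fit")
}

#' @export
print.updrs_fit <- function(x, ...) {
  cat(sprintf("<updrs_fit> random forest, %d features, %d training phonations, %d classes (%s-UPDRS)\n",
              length(x$features), x$n_train, length(x$levels), x$scale))
  invisible(x)
}

#' @export
summary.updrs_fit <- function(object, ...) {
  cat(sprintf("UPDRS mapping (%s scale)\n", object$scale))
  print(object)
  oob <- object$forest$err.rate
  if (!is.null(oob))
    cat(sprintf("  OOB classification error: %.3f\n", oob[nrow(oob), 1L]))
  invisible(object)
}

#' Predict UPDRS scores from a fitted mapping
#'
#' @param object an `updrs_fit`.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return integer vector of predicted UPDRS scores.
#' @export
predict.updrs_fit <- function(object, newdata, ...) {
  if (is.null(object$forest))
    return(rep(as.integer(object$constant), nrow(newdata)))
  Xt <- newdata[, object$features, drop = FALSE]
  Xt <- impute_medians(Xt, object$medians)$X
  as.integer(as.character(stats::predict(object$forest, Xt)))
}

#' Fit on a training set and predict a test set
#'
#' Convenience wrapper fitting [updrs_fit()] on the training rows and
#' returning integer UPDRS predictions for the test rows.
#'
#' @param train,test numeric feature matrices (registry columns).
#' @param y training response.
#' @param feature_subset,params,seed,scale as in [updrs_fit()].
#' @return integer predictions for `test`.
#' @export
fit_predict <- function(train, test, y, feature_subset = NULL,
                        params = list(), seed = 1, scale = "total") {
  fit <- updrs_fit(train, y, feature_subset, params, seed, scale)
  predict(fit, test)
}

cv_split_sizes <- function(n, n_folds = 10L) {
  n_test <- n %/% n_folds
  c(train = n - n_test, test = n_test)
}

new_validation_report <- function(scheme, per_repeat, n_train, n_test,
                                  extra = list()) {
  m <- mean(per_repeat); s <- stats::sd(per_repeat)
  ci <- if (length(per_repeat) >= 2L)
    unname(stats::quantile(per_repeat, c(0.025, 0.975)))
  else c(m, m)
  structure(c(list(scheme = scheme, per_repeat_mae = per_repeat,
                   mae_mean = m, mae_sd = s, ci95 = ci,
                   n_train = n_train, n_test = n_test), extra),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> scheme=%s\n", x$scheme))
  cat(sprintf("  MAE %.3f +/- %.3f (95%% CI [%.3f, %.3f]) over %d repeats\n",
              x$mae_mean, x$mae_sd, x$ci95[1], x$ci95[2],
              length(x$per_repeat_mae)))
  cat(sprintf("  split sizes: %d train / %d test\n", x$n_train, x$n_test))
  invisible(x)
}

#' Repeated 10-fold cross-validation of the UPDRS mapping
#'
#' The rows are randomly permuted, cut into `n_folds` contiguous folds,
#' and each fold is predicted from a model trained on the rest; the
#' per-repeat MAE is the mean of the fold test MAEs. The whole process is
#' repeated `n_repeats` times with fresh permutations. Data should come
#' from a single sex stratum (the pipeline studies males and females
#' separately).
#'
#' @param X numeric feature matrix (registry columns only).
#' @param y response scores (discretized internally).
#' @param n_folds folds per repeat (default 10; 90/10 splits).
#' @param n_repeats repeats (the reference protocol uses 100).
#' @param feature_subset,params,scale passed to the fitting routine.
#' @param seed integer seed.
#' @return a `validation_report` with per-repeat MAEs, mean, SD, empirical
#'   95% CI, and the 90/10 split sizes.
#' @export
cross_validate <- function(X, y, n_folds = 10L, n_repeats = 100L,
                           feature_subset = NULL, params = list(),
                           seed = 1, scale = "total") {
  n <- nrow(X)
  if (n_folds > n) stop("more folds than samples")
  yc <- discretize(y, scale)
  sizes <- cv_split_sizes(n, n_folds)
  fold_id_base <- rep(seq_len(n_folds), length.out = n)
  per_repeat <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    perm <- with_seed(child_seed(seed, paste0("cvperm", r)), sample.int(n))
    fold_of <- integer(n)
    fold_of[perm] <- sort(fold_id_base)   # contiguous blocks of the permutation
    fold_mae <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      te <- which(fold_of == f)
      tr <- which(fold_of != f)
      pred <- fit_predict(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                          yc[tr], feature_subset, params,
                          seed = child_seed(seed, paste0("cv", r, "_", f)),
                          scale = scale)
      fold_mae[f] <- mae(pred, yc[te])
    }
    per_repeat[r] <- mean(fold_mae)
  }
  new_validation_report("cv10x100", per_repeat,
                        n_train = sizes["train"], n_test = sizes["test"],
                        extra = list(n_folds = n_folds,
                                     n_repeats = n_repeats,
                                     features = feature_subset))
}

#' MAE of the train-mean dummy predictor under the same CV protocol
#'
#' Baseline for the parameter-recovery checks: each fold predicts the
#' discretized training-set mean for every test row.
#'
#' @param y response scores.
#' @param n_folds,n_repeats,seed,scale as in [cross_validate()].
#' @return a `validation_report`.
#' @export
cross_validate_dummy <- function(y, n_folds = 10L, n_repeats = 10L,
                                 seed = 1, scale = "total") {
  n <- length(y)
  yc <- discretize(y, scale)
  fold_id_base <- rep(seq_len(n_folds), length.out = n)
  per_repeat <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    perm <- with_seed(child_seed(seed, paste0("cvperm", r)), sample.int(n))
    fold_of <- integer(n)
    fold_of[perm] <- sort(fold_id_base)
    fold_mae <- vapply(seq_len(n_folds), function(f) {
      te <- fold_of == f
      mae(rep(round(mean(yc[!te])), sum(te)), yc[te])
    }, numeric(1))
    per_repeat[r] <- mean(fold_mae)
  }
  sizes <- cv_split_sizes(n, n_folds)
  new_validation_report("cv_dummy", per_repeat,
                        n_train = sizes["train"], n_test = sizes["test"])
}

#' Subject-calibrated tracking validation
#'
#' Leave-one-subject-out scheme mirroring deployment for longitudinal
#' tracking: for each subject, the model trains on all other subjects plus
#' that subject's first `calibration_weeks` weeks of data, augmented with
#' a calibration feature (the mean of the subject's own UPDRS over the
#' calibration weeks; other training rows carry the training-set median).
#' Weeks from `calibration_weeks` onward are predicted; within-week
#' phonation predictions are averaged before the absolute error, and the
#' per-subject MAE is the mean over predicted weeks. Subjects with too few
#' weeks are skipped.
#'
#' @param X numeric feature matrix (registry columns only).
#' @param manifest data frame aligned with `X` rows, with `subject_id` and
#'   `week` columns.
#' @param y response scores aligned with `X` rows.
#' @param calibration_weeks number of initial weeks used for calibration
#'   (default 4; weeks 0..3 calibrate, weeks 4+ are predicted).
#' @param params,seed,scale as in [updrs_fit()].
#' @return a `validation_report` whose repeats are the per-subject MAEs;
#'   `skipped` lists subjects without enough weeks.
#' @export
tracking_validate <- function(X, manifest, y, calibration_weeks = 4L,
                              params = list(), seed = 1, scale = "total") {
  stopifnot(nrow(X) == nrow(manifest), nrow(X) == length(y),
            all(c("subject_id", "week") %in% names(manifest)))
  subjects <- unique(manifest$subject_id)
  if (length(subjects) < 2L) stop("tracking needs at least 2 subjects")
  yc <- discretize(y, scale)
  per_subject <- numeric(0)
  skipped <- character(0)
  partitions <- list()
  for (sid in subjects) {
    mine <- manifest$subject_id == sid
    my_weeks <- sort(unique(manifest$week[mine]))
    calib <- mine & manifest$week < calibration_weeks
    test <- mine & manifest$week >= calibration_weeks
    if (length(my_weeks) < calibration_weeks + 1L || !any(test) ||
        !any(calib)) {
      skipped <- c(skipped, sid)
      next
    }
    calib_value <- mean(yc[calib])
    tr <- which(!mine | calib)
    te <- which(test)
    partitions[[sid]] <- list(train = tr, test = te)
    med <- stats::median(yc[tr])
    calib_col <- ifelse(manifest$subject_id == sid, calib_value, med)
    Xa <- cbind(X, updrs_calibration = calib_col)
    pred <- fit_predict(Xa[tr, , drop = FALSE], Xa[te, , drop = FALSE],
                        yc[tr], params = params,
                        seed = child_seed(seed, paste0("track_", sid)),
                        scale = scale)
    wk <- manifest$week[te]
    pred_by_week <- tapply(pred, wk, mean)
    actual_by_week <- tapply(yc[te], wk, mean)
    per_subject <- c(per_subject,
                     mae(as.numeric(pred_by_week), as.numeric(actual_by_week)))
  }
  if (length(per_subject) == 0L) stop("no subject had enough weeks to track")
  new_validation_report("tracking", per_subject,
                        n_train = nrow(X) - sum(manifest$week >= calibration_weeks &
                                                  manifest$subject_id == subjects[1]),
                        n_test = sum(manifest$week >= calibration_weeks &
                                       manifest$subject_id == subjects[1]),
                        extra = list(calibration_weeks = calibration_weeks,
                                     skipped = skipped,
                                     partitions = partitions))
}

#' Per-feature Spearman association with UPDRS
#'
#' @param X numeric feature matrix.
#' @param y nonconstant response.
#' @return data frame with `feature`, `rho`, `p` and a `flag` column
#'   ("ok", or "constant" for undefined correlations).
#' @export
spearman_report <- function(X, y) {
  if (length(unique(y)) < 2L) stop("constant response")
  res <- lapply(colnames(X), function(nm) {
    v <- X[, nm]
    ok <- is.finite(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0)
      return(data.frame(feature = nm, rho = NA_real_, p = NA_real_,
                        flag = "constant"))
    ct <- suppressWarnings(stats::cor.test(v[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(feature = nm, rho = unname(ct$estimate), p = ct$p.value,
               flag = "ok")
  })
  do.call(rbind, res)
}
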