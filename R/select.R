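# Feature-selection module: four rankers (LASSO path order, mRMR, ReliefF,
# random-forest permutation importance), a voting strategy over perturbed
# datasets, and the one-standard-error rule for the subset size.

discretize_bins <- function(v, bins = 10L) {
  # equal-frequency binning; constant columns collapse to one bin
  if (length(unique(v)) <= 1L) return(rep(1L, length(v)))
  q <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                              na.rm = TRUE))
  if (length(q) < 2L) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = q, include.lowest = TRUE, labels = FALSE))
}

mutual_info <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

rank_lasso <- function(X, y) {
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  if (sum(keep) < 2L) {
    r <- abs(apply(X, 2L, function(v)
      if (stats::sd(v) > 0) stats::cor(v, y) else 0))
    return(colnames(X)[order(r, decreasing = TRUE)])
  }
  fit <- glmnet::glmnet(X[, keep, drop = FALSE], y, family = "gaussian",
                        standardize = TRUE, nlambda = 100)
  beta <- as.matrix(fit$beta)
  entry <- apply(beta, 1L, function(b) {
    i <- which(b != 0)
    if (length(i)) i[1] else Inf
  })
  final <- abs(beta[, ncol(beta)])
  ord <- order(entry, -final)
  c(colnames(X)[keep][ord], colnames(X)[!keep])
}

rank_mrmr <- function(X, y, bins = 10L) {
  Xd <- apply(X, 2L, discretize_bins, bins = bins)
  yd <- as.integer(factor(y))
  M <- ncol(X)
  rel <- vapply(seq_len(M), function(j) mutual_info(Xd[, j], yd), numeric(1))
  red <- matrix(NA_real_, M, M)
  selected <- integer(0)
  remaining <- seq_len(M)
  for (step in seq_len(M)) {
    if (length(selected) == 0L) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      crit <- vapply(remaining, function(j) {
        for (s in selected) if (is.na(red[j, s])) {
          red[j, s] <<- red[s, j] <<- mutual_info(Xd[, j], Xd[, s])
        }
        rel[j] - mean(red[j, selected])
      }, numeric(1))
      pick <- remaining[which.max(crit)]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  colnames(X)[selected]
}

rank_relief <- function(X, y, k = 10L) {
  # ReliefF for a discrete response, k nearest hits/misses, all instances
  n <- nrow(X); M <- ncol(X)
  rng <- apply(X, 2L, function(v) max(diff(range(v)), 1e-12))
  Xs <- sweep(X, 2L, rng, "/")
  yf <- as.integer(factor(y))
  classes <- sort(unique(yf))
  priors <- table(factor(yf, levels = classes)) / n
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf
  W <- numeric(M)
  for (i in seq_len(n)) {
    same <- which(yf == yf[i])
    same <- same[same != i]
    if (length(same) == 0L) next
    hits <- same[order(D[i, same])][seq_len(min(k, length(same)))]
    W <- W - colMeans(abs(Xs[hits, , drop = FALSE] -
                            matrix(Xs[i, ], length(hits), M, byrow = TRUE))) / n
    for (cl in classes[classes != yf[i]]) {
      other <- which(yf == cl)
      if (length(other) == 0L) next
      miss <- other[order(D[i, other])][seq_len(min(k, length(other)))]
      w_cl <- priors[[as.character(cl)]] / (1 - priors[[as.character(yf[i])]])
      W <- W + w_cl *
        colMeans(abs(Xs[miss, , drop = FALSE] -
                       matrix(Xs[i, ], length(miss), M, byrow = TRUE))) / n
    }
  }
  colnames(X)[order(W, decreasing = TRUE)]
}

rank_rf <- function(X, y, ntree = 500L) {
  fit <- randomForest::randomForest(X, factor(y), ntree = ntree,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1L)[, 1L]
  colnames(X)[order(imp, decreasing = TRUE)]
}

#' Rank all features by one selection algorithm
#'
#' Produces a total order over the feature columns: "lasso" uses the
#' L1-regularization path entry order on the integer response, "mrmr"
#' greedy mutual-information relevance minus redundancy (10-bin
#' equal-frequency discretization), "relief" ReliefF with k = 10
#' neighbors over all instances, and "rf_importance" out-of-bag
#' permutation importance of a 500-tree random forest. Constant feature
#' columns are ranked last.
#'
#' @param X numeric feature matrix with column names; no missing values.
#' @param y response; discretized to classes for the classifier-based
#'   rankers. Must not be constant.
#' @param algorithm one of "lasso", "mrmr", "relief", "rf_importance".
#' @param params list of per-algorithm overrides (`bins`, `k`, `ntree`).
#' @param seed integer seed (the RF and any stochastic steps use it).
#' @return character vector of feature names, best first.
#' @export
rank_features <- function(X, y,
                          algorithm = c("lasso", "mrmr", "relief",
                                        "rf_importance"),
                          params = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.matrix(X), !is.null(colnames(X)), !anyNA(X))
  if (length(unique(y)) < 2L) stop("constant response cannot be ranked against")
  with_seed(child_seed(seed, paste0("rank_", algorithm)), {
    ranked <- switch(algorithm,
      lasso = rank_lasso(X, y),
      mrmr = rank_mrmr(X, y, bins = params$bins %||% 10L),
      relief = rank_relief(X, y, k = params$k %||% 10L),
      rf_importance = rank_rf(X, y, ntree = params$ntree %||% 500L))
    # constant columns last, whatever the ranker did with them
    const <- colnames(X)[apply(X, 2L, function(v) stats::sd(v) == 0)]
    c(setdiff(ranked, const), const)
  })
}

#' Feature-selection voting over perturbed datasets
#'
#' Runs [rank_features()] on `n_perturbations` subsampled versions of the
#' dataset (90% of rows without replacement by default); each run casts
#' one vote for each of its `top_m` best features. The aggregated ranking
#' sorts by votes, breaking ties by mean rank across perturbations.
#'
#' @param X,y,algorithm,params,seed as in [rank_features()].
#' @param n_perturbations number of perturbed datasets (at least 2).
#' @param subsample_frac fraction of rows in each perturbation.
#' @param top_m number of features voted for per perturbation.
#' @param k optional final subset size; if given, `selected` holds the
#'   first `k` features of the aggregated ranking.
#' @return an `fs_result` with `votes`, `aggregated_ranking`, per-run
#'   `rankings`, and `selected`/`k`.
#' @export
vote_select <- function(X, y, algorithm = "relief", n_perturbations = 10L,
                        subsample_frac = 0.9, top_m = 30L, params = list(),
                        seed = 1, k = NULL) {
  if (n_perturbations < 2L) stop("need at least 2 perturbations")
  n <- nrow(X)
  n_sub <- round(subsample_frac * n)
  if (n_sub < 10L) stop("subsample too small for ranking")
  nm <- colnames(X)
  rankings <- vector("list", n_perturbations)
  votes <- stats::setNames(numeric(length(nm)), nm)
  rank_sum <- stats::setNames(numeric(length(nm)), nm)
  for (b in seq_len(n_perturbations)) {
    idx <- with_seed(child_seed(seed, paste0("perturb", b)),
                     sample.int(n, n_sub))
    yb <- y[idx]
    if (length(unique(yb)) < 2L) next
    rk <- rank_features(X[idx, , drop = FALSE], yb, algorithm, params,
                        seed = child_seed(seed, paste0("rankseed", b)))
    rankings[[b]] <- rk
    votes[rk[seq_len(min(top_m, length(rk)))]] <-
      votes[rk[seq_len(min(top_m, length(rk)))]] + 1
    rank_sum[rk] <- rank_sum[rk] + seq_along(rk)
  }
  mean_rank <- rank_sum / n_perturbations
  agg <- nm[order(-votes, mean_rank)]
  structure(list(algorithm = algorithm, rankings = rankings,
                 votes = votes, mean_rank = mean_rank,
                 aggregated_ranking = agg,
                 k = k, selected = if (!is.null(k)) agg[seq_len(k)]),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("<fs_result> algorithm=%s, %d perturbations\n",
              x$algorithm, length(x$rankings)))
  top <- utils::head(x$aggregated_ranking, 10L)
  cat("  top features:", paste(top, collapse = ", "), "\n")
  if (!is.null(x$k)) cat("  selected K =", x$k, "\n")
  invisible(x)
}

#' One-standard-error rule for the subset size
#'
#' Given mean and standard deviation of the validation MAE for a sequence
#' of subset sizes K, returns the smallest K whose mean MAE is within one
#' standard deviation (taken at the global minimum) of the lowest mean
#' MAE. Never exceeds the argmin K.
#'
#' @param mae_by_k data frame with columns `k`, `mean`, `sd`.
#' @return the chosen K.
#' @export
choose_k_one_se <- function(mae_by_k) {
  stopifnot(is.data.frame(mae_by_k), nrow(mae_by_k) >= 1L,
            all(c("k", "mean", "sd") %in% names(mae_by_k)))
  mae_by_k <- mae_by_k[order(mae_by_k$k), , drop = FALSE]
  i_min <- which.min(mae_by_k$mean)
  thresh <- mae_by_k$mean[i_min] + mae_by_k$sd[i_min]
  ok <- which(mae_by_k$mean <= thresh)
  mae_by_k$k[min(ok)]
}
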