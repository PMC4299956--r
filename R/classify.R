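#' SVM hyperparameters
#'
#' Defaults for the radial-basis-function support vector classifier:
#' regularization cost 1 and kernel width `gamma = 1/d` on per-fold
#' standardized features (equivalent to `1/(d * pooled variance)` on the
#' raw scale). An optional inner 5-fold grid search over cost and gamma,
#' run within each training fold, is available but off by default.
#'
#' @param cost Regularization parameter C.
#' @param gamma RBF kernel width; `NULL` means `1/n_features` after
#'   standardization.
#' @param tune If `TRUE`, grid-search cost and gamma by inner 5-fold CV
#'   inside every training fold.
#' @param tune_grid List with `cost` and `gamma` candidate vectors.
#' @return List of class `svm_hyperparams`.
#' @export
svm_hyperparams <- function(cost = 1, gamma = NULL, tune = FALSE,
                            tune_grid = list(cost = c(0.1, 1, 10),
                                             gamma_scale = c(0.25, 1, 4))) {
  structure(list(cost = cost, gamma = gamma, tune = tune,
                 tune_grid = tune_grid), class = "svm_hyperparams")
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu, "-"), 2, st$sd, "/")
}

# Fit one RBF-SVM on standardized features and return a scoring closure
# oriented so that positive decision values indicate the patient class.
# Inverse-frequency class weights remove the systematic bias from
# imbalanced training folds (leave-one-out always under-represents the
# held-out subject's class by one).
fit_rbf_svm <- function(x, y, hp) {
  d <- ncol(x)
  gamma <- hp$gamma %||% (1 / d)
  cost <- hp$cost
  cw <- 1 / table(droplevels(y))
  cw <- cw / mean(cw)
  if (isTRUE(hp$tune)) {
    best <- c(Inf, cost, gamma)
    folds <- rep_len(seq_len(5L), nrow(x))[order(seq_len(nrow(x)))]
    for (co in hp$tune_grid$cost) for (gs in hp$tune_grid$gamma_scale) {
      err <- 0
      ok <- TRUE
      for (f in 1:5) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L || !any(!tr)) { ok <- FALSE; break }
        m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = co, gamma = gs / d, scale = FALSE,
                        class.weights = cw)
        err <- err + sum(stats::predict(m, x[!tr, , drop = FALSE]) != y[!tr])
      }
      if (ok && err < best[1]) best <- c(err, co, gs / d)
    }
    cost <- best[2]; gamma <- best[3]
  }
  m <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                  scale = FALSE, class.weights = cw)
  # e1071's decision-value sign follows the order labels were seen in
  # training; orient it from the training data itself.
  dv_train <- attr(stats::predict(m, x, decision.values = TRUE),
                   "decision.values")[, 1]
  flip <- mean(dv_train[y == "patient"]) < mean(dv_train[y == "control"])
  list(model = m, flip = flip, cost = cost, gamma = gamma)
}

svm_decision <- function(fit, newx) {
  dv <- attr(stats::predict(fit$model, newx, decision.values = TRUE),
             "decision.values")[, 1]
  if (fit$flip) -dv else dv
}

#' Leave-one-out SVM decision scores
#'
#' For each subject, fits the RBF-kernel support vector classifier on all
#' remaining subjects (features standardized with training-fold statistics
#' only) and records the continuous decision value of the held-out subject.
#' Positive scores indicate the patient side; the class label at the
#' conventional threshold 0 is the sign of the score.
#'
#' @param dataset A `feature_dataset`.
#' @param hyperparams An [svm_hyperparams()].
#' @param keep_models Keep the per-fold fitted models (needed by
#'   [rank_features()]); default `FALSE`.
#' @return A `loo_result`: data frame (subject_id, true_label,
#'   decision_score, fold) with attributes `hyperparams` and, optionally,
#'   `models`.
#' @export
loo_scores <- function(dataset, hyperparams = svm_hyperparams(),
                       keep_models = FALSE) {
  stopifnot(inherits(dataset, "feature_dataset"))
  x <- dataset$x
  if (any(!is.finite(x))) stopf("non-finite feature values")
  y <- dataset$group
  if (min(table(y)) < 2L)
    stopf("need at least 2 subjects per class for leave-one-out")
  n <- nrow(x)
  scores <- numeric(n)
  models <- if (keep_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L) stopf("single-class training fold at subject %d", i)
    st <- standardize_fit(x[tr, , drop = FALSE])
    fit <- fit_rbf_svm(standardize_apply(x[tr, , drop = FALSE], st),
                       y[tr], hyperparams)
    scores[i] <- svm_decision(fit, standardize_apply(x[i, , drop = FALSE], st))
    if (keep_models) models[[i]] <- list(fit = fit, st = st)
  }
  res <- data.frame(subject_id = dataset$subject_id,
                    true_label = as.character(y),
                    decision_score = scores, fold = seq_len(n),
                    stringsAsFactors = FALSE)
  attr(res, "hyperparams") <- hyperparams
  if (keep_models) attr(res, "models") <- models
  class(res) <- c("loo_result", "data.frame")
  res
}

loo_accuracy <- function(res) {
  mean((res$decision_score > 0) == (res$true_label == "patient"))
}

#' Rank features by leave-one-out permutation importance
#'
#' Importance of a feature is the mean drop in leave-one-out accuracy when
#' that feature's column is permuted across subjects and every held-out
#' subject is re-scored with its already-fitted fold model (the models are
#' fitted once, on intact data). The drop is averaged over `n_perm`
#' permutations. Ties are broken by original feature order.
#'
#' @param dataset A `feature_dataset`.
#' @param hyperparams An [svm_hyperparams()].
#' @param n_perm Number of permutations per feature (default 20).
#' @param seed Integer seed for the permutations.
#' @return A `feature_ranking` data frame (feature, importance), ordered
#'   from most to least important, with attribute `baseline_accuracy`.
#' @export
rank_features <- function(dataset, hyperparams = svm_hyperparams(),
                          n_perm = 20L, seed = 1L) {
  res <- loo_scores(dataset, hyperparams, keep_models = TRUE)
  models <- attr(res, "models")
  x <- dataset$x
  n <- nrow(x)
  d <- ncol(x)
  is_pat <- res$true_label == "patient"
  base_acc <- loo_accuracy(res)
  perms <- with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  correct <- matrix(0, nrow = d, ncol = n_perm,
                    dimnames = list(colnames(x), NULL))
  for (i in seq_len(n)) {
    mi <- models[[i]]
    # one prediction batch per fold: d features x n_perm permuted rows
    newx <- x[rep(i, d * n_perm), , drop = FALSE]
    row <- 0L
    for (j in seq_len(d)) for (r in seq_len(n_perm)) {
      row <- row + 1L
      newx[row, j] <- x[perms[[r]][i], j]
    }
    dv <- svm_decision(mi$fit, standardize_apply(newx, mi$st))
    hit <- (dv > 0) == is_pat[i]
    correct <- correct + matrix(hit, nrow = d, ncol = n_perm, byrow = TRUE)
  }
  drop <- base_acc - rowMeans(correct) / n
  ord <- order(-drop, seq_len(d))
  out <- data.frame(feature = colnames(x)[ord], importance = drop[ord],
                    stringsAsFactors = FALSE)
  attr(out, "baseline_accuracy") <- base_acc
  class(out) <- c("feature_ranking", "data.frame")
  out
}

loo_criterion <- function(dataset, criterion, hyperparams) {
  res <- loo_scores(dataset, hyperparams)
  val <- switch(criterion,
    loo_accuracy = loo_accuracy(res),
    loo_auc = roc_auc(res$decision_score, res$true_label == "patient")$auc)
  list(value = val, scores = res)
}

#' Stepwise backward feature elimination
#'
#' Starting from the full feature set, repeatedly removes the least
#' important feature (by [rank_features()] permutation importance) and
#' re-evaluates the leave-one-out criterion. Returns the feature set that
#' maximizes the criterion along the trace; ties go to the smaller set.
#'
#' The criterion is evaluated on the full sample's leave-one-out scores,
#' mirroring selection-then-validation as commonly reported; for a fully
#' nested protocol run the selection inside each outer fold via
#' [loo_with_selection()].
#'
#' @param dataset A `feature_dataset`.
#' @param criterion `"loo_auc"` (default) or `"loo_accuracy"`.
#' @param min_size Smallest feature-set size to explore.
#' @param hyperparams An [svm_hyperparams()].
#' @param n_perm Permutations per feature for the importance ranking.
#' @param seed Integer seed.
#' @return A `backward_selection`: list with `selected` (feature names),
#'   `criterion`, `best_value`, and `trace` (data frame: step, n_features,
#'   removed_feature, criterion).
#' @export
backward_select <- function(dataset, criterion = c("loo_auc", "loo_accuracy"),
                            min_size = 1L,
                            hyperparams = svm_hyperparams(),
                            n_perm = 20L, seed = 1L) {
  criterion <- match.arg(criterion)
  feats <- colnames(dataset$x)
  if (length(feats) < 1L) stopf("dataset has no features")
  if (min_size > length(feats))
    stopf("min_size (%d) exceeds feature count (%d)", min_size, length(feats))
  sets <- list(feats)
  crit <- loo_criterion(select_features(dataset, feats), criterion,
                        hyperparams)$value
  removed <- NA_character_
  step <- 0L
  cur <- feats
  while (length(cur) > min_size) {
    rk <- rank_features(select_features(dataset, cur), hyperparams,
                        n_perm = n_perm,
                        seed = subject_seed(seed, step + 1L))
    worst <- rk$feature[nrow(rk)]
    cur <- setdiff(cur, worst)
    step <- step + 1L
    sets[[step + 1L]] <- cur
    removed <- c(removed, worst)
    crit <- c(crit, loo_criterion(select_features(dataset, cur), criterion,
                                  hyperparams)$value)
  }
  trace <- data.frame(step = seq_along(crit) - 1L,
                      n_features = lengths(sets),
                      removed_feature = removed, criterion = crit,
                      stringsAsFactors = FALSE)
  # max criterion; ties resolved toward the smaller (later) set
  best <- which(crit == max(crit))
  best <- best[length(best)]
  structure(list(selected = sets[[best]], criterion = criterion,
                 best_value = crit[best], trace = trace),
            class = "backward_selection")
}

#' Leave-one-out scoring with per-fold (nested) backward selection
#'
#' The fully nested protocol: for each held-out subject, backward selection
#' is re-run on the remaining subjects only, and the held-out subject is
#' scored with the features selected in that fold. Slower but free of
#' selection optimism.
#'
#' @inheritParams backward_select
#' @return A `loo_result` with an extra list-column attribute
#'   `selected_per_fold`.
#' @export
loo_with_selection <- function(dataset, criterion = c("loo_auc", "loo_accuracy"),
                               min_size = 1L,
                               hyperparams = svm_hyperparams(),
                               n_perm = 10L, seed = 1L) {
  criterion <- match.arg(criterion)
  n <- nrow(dataset$x)
  scores <- numeric(n)
  sel_list <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    inner <- dataset
    inner$x <- dataset$x[keep, , drop = FALSE]
    inner$group <- dataset$group[keep]
    inner$gender <- dataset$gender[keep]
    inner$age <- dataset$age[keep]
    inner$subject_id <- dataset$subject_id[keep]
    bs <- backward_select(inner, criterion, min_size, hyperparams,
                          n_perm = n_perm, seed = subject_seed(seed, i))
    sel_list[[i]] <- bs$selected
    st <- standardize_fit(inner$x[, bs$selected, drop = FALSE])
    fit <- fit_rbf_svm(standardize_apply(inner$x[, bs$selected, drop = FALSE], st),
                       inner$group, hyperparams)
    scores[i] <- svm_decision(
      fit, standardize_apply(dataset$x[i, bs$selected, drop = FALSE], st))
  }
  res <- data.frame(subject_id = dataset$subject_id,
                    true_label = as.character(dataset$group),
                    decision_score = scores, fold = seq_len(n),
                    stringsAsFactors = FALSE)
  attr(res, "selected_per_fold") <- sel_list
  class(res) <- c("loo_result", "data.frame")
  res
}
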