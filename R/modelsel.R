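# Hybrid feature selection and nested leave-one-subject-out evaluation.
#
# Selection is a two-stage hybrid: a univariate ANOVA F filter keeps the
# 40 highest-scoring features, then recursive feature elimination with
# cross-validation (forest importance, step 1, macro-F1 scoring) picks
# the best cardinality. Classification is nested: the outer loop holds
# out one subject; the inner loop is leave-one-subject-out over the
# remaining subjects and scores every grid point by mean macro F1; the
# winning grid point is refit on all non-held-out data (scaler fit on
# training rows only) and evaluated on the held-out subject.

feature_matrix <- function(ft) {
  as.matrix(ft[, setdiff(names(ft), feature_meta_columns()), drop = FALSE])
}

#' Univariate ANOVA F filter
#'
#' One-way F statistic of each feature against the load class; the top
#' `k` features are kept. A constant feature has an undefined F and is
#' ranked last with a warning.
#'
#' @param ft a `feature_table` containing both classes.
#' @param k number of features to keep (default 40).
#' @return List with `anova_scores` (named F statistics), `kept` (the
#'   `k` retained feature names, by decreasing F).
#' @export
anova_filter <- function(ft, k = 40) {
  X <- feature_matrix(ft)
  y <- ft$load_class
  if (length(unique(y)) < 2)
    cogload_error("cogload_parameter_error", "need both classes for the F filter")
  scores <- apply(X, 2, function(x) f_statistic(x, y))
  if (any(!is.finite(scores))) {
    warning("constant feature(s) ranked last: ",
            paste(names(scores)[!is.finite(scores)], collapse = ", "))
    scores[!is.finite(scores)] <- -Inf
  }
  kept <- names(sort(scores, decreasing = TRUE))[seq_len(min(k, length(scores)))]
  list(anova_scores = scores, kept = kept)
}

f_statistic <- function(x, y) {
  groups <- split(x, y)
  k <- length(groups)
  n <- length(x)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0) return(if (ssb > 0) Inf else NaN)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from the filtered feature set, the least-important feature
#' (forest mean-decrease-in-impurity) is removed one at a time. Each
#' cardinality is scored by cross-validated macro F1; folds are grouped
#' by subject when at least `folds` subjects exist, otherwise
#' stratified at the window level. The returned selection is the
#' elimination path on the full data cut at the best-scoring
#' cardinality (largest score; ties favour fewer features).
#'
#' @param ft a `feature_table` restricted to the filtered features.
#' @param folds number of cross-validation folds (default 12).
#' @param seed integer seed (fold assignment and forest bootstrap).
#' @param rf_params forest hyperparameters used as the elimination
#'   estimator.
#' @return List with `curve` (data.frame n_features, mean_f1),
#'   `selected` (feature names), `path` (elimination order, first
#'   removed first) and `seed`.
#' @export
rfecv_select <- function(ft, folds = 12, seed = 1L,
                         rf_params = list(n_estimators = 60, max_depth = 30)) {
  X <- feature_matrix(ft)
  y <- ft$load_class
  p <- ncol(X)
  fold_id <- make_folds(ft, folds, seed)
  nf <- length(unique(fold_id))
  score_mat <- matrix(NA_real_, nrow = p, ncol = nf)
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    te <- !tr
    if (length(unique(y[te])) < 2) {
      warning("fold ", f, " has a single class; skipped")
      next
    }
    sc <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(sc, X[tr, , drop = FALSE])
    Xte <- apply_scaler(sc, X[te, , drop = FALSE])
    feats <- colnames(X)
    while (length(feats) >= 1) {
      m <- fit_model(Xtr[, feats, drop = FALSE], y[tr], "rf",
                     rf_params, seed = seed + f)
      pred <- predict_model(m, Xte[, feats, drop = FALSE])
      score_mat[length(feats), f] <-
        compute_metrics_from_labels(y[te], pred)$f1 / 100
      if (length(feats) == 1) break
      imp <- model_importance(m)
      feats <- feats[-which.min(imp)]
    }
  }
  curve <- data.frame(n_features = seq_len(p),
                      mean_f1 = rowMeans(score_mat, na.rm = TRUE))
  best_k <- which.max(curve$mean_f1)
  # elimination path on the full data for the reported feature set
  scf <- fit_scaler(X)
  Xs <- apply_scaler(scf, X)
  feats <- colnames(X)
  order_removed <- character(0)
  while (length(feats) > 1) {
    m <- fit_model(Xs[, feats, drop = FALSE], y, "rf", rf_params, seed = seed)
    imp <- model_importance(m)
    worst <- feats[which.min(imp)]
    order_removed <- c(order_removed, worst)
    feats <- setdiff(feats, worst)
  }
  rank_order <- c(feats, rev(order_removed))   # most important first
  selected <- head(rank_order, best_k)
  list(curve = curve, selected = selected, path = order_removed, seed = seed)
}

make_folds <- function(ft, folds, seed) {
  subj <- ft$subject_id
  us <- unique(subj)
  set.seed(seed)
  if (length(us) >= folds) {
    sf <- setNames(rep(seq_len(folds), length.out = length(us)),
                   sample(us))
    unname(sf[subj])
  } else {
    y <- ft$load_class
    id <- integer(length(y))
    for (cl in unique(y)) {
      w <- which(y == cl)
      id[w] <- sample(rep(seq_len(folds), length.out = length(w)))
    }
    id
  }
}

#' Run the hybrid selection (filter + wrapper) on a feature table
#'
#' @param ft a `feature_table`.
#' @param k filter cardinality (default 40).
#' @param folds,seed,rf_params passed to [rfecv_select()].
#' @return A `selection_result`: `anova_scores`, `kept40`,
#'   `rfecv_curve`, `selected`, `selector_seed`.
#' @export
select_features <- function(ft, k = 40, folds = 12, seed = 1L,
                            rf_params = list(n_estimators = 60, max_depth = 30)) {
  flt <- anova_filter(ft, k)
  sub <- ft[, c(feature_meta_columns(), flt$kept)]
  class(sub) <- class(ft)
  rf <- rfecv_select(sub, folds = folds, seed = seed, rf_params = rf_params)
  structure(list(anova_scores = flt$anova_scores, kept40 = flt$kept,
                 rfecv_curve = rf$curve, selected = rf$selected,
                 selector_seed = seed),
            class = "selection_result")
}

fit_scaler <- function(X, method = "zscore") {
  if (method == "zscore") {
    mu <- colMeans(X)
    s <- apply(X, 2, sd)
    s[s < 1e-12] <- 1
    list(method = method, center = mu, scale = s)
  } else {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    rg <- hi - lo; rg[rg < 1e-12] <- 1
    list(method = "minmax", center = lo, scale = rg)
  }
}

apply_scaler <- function(sc, X) {
  sweep(sweep(as.matrix(X), 2, sc$center), 2, sc$scale, "/")
}

#' Confusion counts and macro metrics for one evaluation
#'
#' High load is the positive class. Precision, recall and F1 are
#' computed per class and macro-averaged (unweighted mean over the two
#' classes); a per-class ratio that is 0/0 contributes 0 with a warning.
#' All metrics are percentages.
#'
#' @param tp,fn,fp,tn confusion counts (HL positive).
#' @return List: `precision`, `recall`, `f1`, `accuracy` (percent).
#' @export
#' @examples
#' compute_metrics(61, 8, 0, 48)   # precision 92.86, accuracy 93.16
compute_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, " (0/0) set to 0")
      return(0)
    }
    num / den
  }
  prec_hl <- ratio(tp, tp + fp, "HL precision")
  rec_hl <- ratio(tp, tp + fn, "HL recall")
  prec_ll <- ratio(tn, tn + fn, "LL precision")
  rec_ll <- ratio(tn, tn + fp, "LL recall")
  f1c <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = 50 * (prec_hl + prec_ll),
       recall = 50 * (rec_hl + rec_ll),
       f1 = 50 * (f1c(prec_hl, rec_hl) + f1c(prec_ll, rec_ll)),
       accuracy = 100 * (tp + tn) / (tp + fn + fp + tn))
}

compute_metrics_from_labels <- function(truth, pred) {
  tp <- sum(truth == "HL" & pred == "HL")
  fn <- sum(truth == "HL" & pred == "LL")
  fp <- sum(truth == "LL" & pred == "HL")
  tn <- sum(truth == "LL" & pred == "LL")
  suppressWarnings(c(compute_metrics(tp, fn, fp, tn),
                     list(tp = tp, fn = fn, fp = fp, tn = tn)))
}

#' Nested leave-one-subject-out evaluation with grid search
#'
#' For each held-out subject, every grid point is scored by
#' leave-one-subject-out over the remaining subjects (mean macro F1);
#' the best point (first listed wins ties) is refit on all non-held-out
#' rows and evaluated on the held-out subject. In `"reproduction"` mode
#' the caller passes a fixed feature set chosen once on all data
#' (mirroring a selection-before-split analysis order); in
#' `"leakage_safe"` mode (default) selection is re-run inside each
#' outer fold via `select_fn`.
#'
#' @param ft a `feature_table` with at least 3 subjects.
#' @param grid data.frame of hyperparameters (see [hyper_grid()]).
#' @param model "svm", "rf" or "gnb".
#' @param mode "leakage_safe" or "reproduction".
#' @param features fixed feature names (required in reproduction mode).
#' @param select_fn function(ft) -> character of feature names, used in
#'   leakage-safe mode; defaults to the hybrid selection with a reduced
#'   forest.
#' @param scaler "zscore" (default) or "minmax".
#' @param seed integer seed.
#' @return List of `subject_evaluation` objects: per subject the
#'   confusion counts, macro metrics (percent), winning grid row and
#'   numbers of training/test windows.
#' @export
nested_loso <- function(ft, grid = hyper_grid("svm"), model = "svm",
                        mode = c("leakage_safe", "reproduction"),
                        features = NULL, select_fn = NULL,
                        scaler = "zscore", seed = 1L) {
  mode <- match.arg(mode)
  subjects <- unique(ft$subject_id)
  if (length(subjects) < 3)
    cogload_error("cogload_parameter_error", "need at least 3 subjects")
  if (mode == "reproduction" && is.null(features))
    cogload_error("cogload_parameter_error",
                  "reproduction mode requires a fixed feature set")
  if (is.null(select_fn))
    select_fn <- function(sub_ft)
      select_features(sub_ft, folds = min(12, length(unique(sub_ft$subject_id))),
                      seed = seed)$selected
  ft$.row_id <- seq_len(nrow(ft))
  evals <- list()
  for (s in subjects) {
    test <- ft[ft$subject_id == s, , drop = FALSE]
    train <- ft[ft$subject_id != s, , drop = FALSE]
    stopifnot(!any(test$.row_id %in% train$.row_id))   # provenance guard
    feats <- if (mode == "reproduction") features else {
      tr_ft <- train[, setdiff(names(train), ".row_id")]
      class(tr_ft) <- class(ft)
      select_fn(tr_ft)
    }
    Xtr_all <- as.matrix(train[, feats, drop = FALSE])
    ytr_all <- train$load_class
    inner_subjects <- unique(train$subject_id)
    # inner LOSO score per grid row
    grid_scores <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      prm <- as.list(grid[gi, , drop = FALSE])
      f1s <- c()
      for (v in inner_subjects) {
        itr <- train$subject_id != v
        if (length(unique(ytr_all[itr])) < 2) next
        sc <- fit_scaler(Xtr_all[itr, , drop = FALSE], scaler)
        m <- fit_model(apply_scaler(sc, Xtr_all[itr, , drop = FALSE]),
                       ytr_all[itr], model, prm, seed = seed)
        pred <- predict_model(m, apply_scaler(sc, Xtr_all[!itr, , drop = FALSE]))
        f1s <- c(f1s, compute_metrics_from_labels(ytr_all[!itr], pred)$f1)
      }
      grid_scores[gi] <- mean(f1s)
    }
    best <- which(grid_scores == max(grid_scores))[1]   # first listed wins
    prm <- as.list(grid[best, , drop = FALSE])
    sc <- fit_scaler(Xtr_all, scaler)
    m <- fit_model(apply_scaler(sc, Xtr_all), ytr_all, model, prm, seed = seed)
    if (length(unique(test$load_class)) < 2)
      warning("subject ", s, " has windows of a single class")
    pred <- predict_model(m, apply_scaler(sc, as.matrix(test[, feats, drop = FALSE])))
    met <- compute_metrics_from_labels(test$load_class, pred)
    evals[[s]] <- structure(
      list(subject_id = s, tp = met$tp, fn = met$fn, fp = met$fp, tn = met$tn,
           precision = met$precision, recall = met$recall, f1 = met$f1,
           accuracy = met$accuracy, best_params = prm,
           inner_score = grid_scores[best], features = feats,
           n_train = nrow(train), n_test = nrow(test)),
      class = "subject_evaluation")
  }
  evals
}

#' Mean metrics across subject evaluations
#' @param evals list of `subject_evaluation` (from [nested_loso()]).
#' @return List with unweighted mean `precision`, `recall`, `f1`,
#'   `accuracy` (percent) and `n_subjects`.
#' @export
summarise_evaluations <- function(evals) {
  stopifnot(length(evals) >= 1)
  g <- function(f) mean(vapply(evals, `[[`, numeric(1), f))
  list(precision = g("precision"), recall = g("recall"),
       f1 = g("f1"), accuracy = g("accuracy"), n_subjects = length(evals))
}

#' Per-subject metric table (one row per held-out subject)
#' @param evals list of `subject_evaluation`.
#' @return data.frame with confusion counts and percent metrics.
#' @export
evaluation_table <- function(evals) {
  do.call(rbind, lapply(evals, function(e)
    data.frame(subject_id = e$subject_id, tp = e$tp, fn = e$fn, fp = e$fp,
               tn = e$tn, precision = e$precision, f1 = e$f1,
               recall = e$recall, accuracy = e$accuracy)))
}
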