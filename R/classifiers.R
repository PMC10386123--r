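# Classifier backends: linear support vector machine (dual coordinate
# descent), Gaussian naive Bayes, and the compiled random forest. A thin
# common interface (fit_model / predict_model) keeps the nested
# cross-validation generic over model families.

#' Fit a classifier
#'
#' @param X numeric matrix (rows = windows, columns = features), already
#'   scaled by the caller.
#' @param y factor or character vector with levels HL/LL (HL positive).
#' @param model "svm", "rf" or "gnb".
#' @param params named list of hyperparameters; see [hyper_grid()] for
#'   the tuned names per family.
#' @param seed integer; seeds the forest's bootstrap. SVM and naive
#'   Bayes are deterministic.
#' @return Opaque model object with class `cogload_model`.
#' @export
fit_model <- function(X, y, model = c("svm", "rf", "gnb"),
                      params = list(), seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  yb <- as.integer(y == "HL")           # 1 = HL (positive class)
  fit <- switch(model,
    svm = {
      C <- params$C %||% 1
      Xb <- cbind(X, 1)
      w <- .svm_dcd(Xb, ifelse(yb == 1, 1, -1), C, 1000L, 1e-4)
      list(w = w)
    },
    gnb = {
      vs <- params$var_smoothing %||% 1e-9
      mu <- rbind(colMeans(X[yb == 1, , drop = FALSE]),
                  colMeans(X[yb == 0, , drop = FALSE]))
      vr <- rbind(apply(X[yb == 1, , drop = FALSE], 2, var0),
                  apply(X[yb == 0, , drop = FALSE], 2, var0))
      vr <- vr + vs * max(apply(X, 2, var0))
      prior <- c(mean(yb == 1), mean(yb == 0))
      list(mu = mu, vr = vr, prior = prior)
    },
    rf = {
      p <- ncol(X)
      mtry <- switch(params$max_features %||% "sqrt",
                     sqrt = , auto = max(1L, floor(sqrt(p))),
                     p)
      .rf_fit(X, yb,
              as.integer(params$n_estimators %||% 100),
              as.integer(mtry),
              as.integer(params$max_depth %||% 30),
              as.integer(params$min_samples_split %||% 2),
              as.integer(params$min_samples_leaf %||% 1),
              isTRUE(params$bootstrap %||% TRUE),
              as.double(seed))
    })
  structure(list(model = model, fit = fit, params = params),
            class = "cogload_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

var0 <- function(x) if (length(x) < 2) 0 else var(x)

#' Predict class labels
#' @param object a `cogload_model`.
#' @param X matrix scaled like the training data.
#' @return Character vector of "HL"/"LL".
#' @export
predict_model <- function(object, X) {
  X <- as.matrix(X)
  score <- switch(object$model,
    svm = as.numeric(cbind(X, 1) %*% object$fit$w),
    gnb = {
      f <- object$fit
      ll <- function(k) {
        v <- pmax(f$vr[k, ], 1e-12)
        as.numeric(-(sweep(X, 2, f$mu[k, ])^2) %*% (1 / (2 * v))) -
          0.5 * sum(log(2 * pi * v)) + log(max(f$prior[k], 1e-300))
      }
      ll(1) - ll(2)
    },
    rf = .rf_predict(object$fit, X) - 0.5)
  ifelse(score > 0, "HL", "LL")
}

#' Feature importance of a fitted model
#'
#' Mean decrease in Gini impurity for the forest; absolute weight for
#' the linear SVM; absolute standardised mean difference for naive
#' Bayes.
#' @param object a `cogload_model`.
#' @return Numeric vector, one value per feature column.
#' @export
model_importance <- function(object) {
  switch(object$model,
    rf = as.numeric(object$fit$importance),
    svm = abs(head(object$fit$w, -1)),
    gnb = {
      f <- object$fit
      abs(f$mu[1, ] - f$mu[2, ]) / sqrt(pmax(f$vr[1, ] + f$vr[2, ], 1e-12))
    })
}

#' Hyperparameter grids for tuning
#'
#' The exact tuned value lists per model family. The SVM grid retains a
#' gamma axis for fidelity with common tuning setups even though gamma
#' is inert for a linear kernel (documented; it multiplies the grid but
#' not the search space of distinct models). The naive Bayes grid is a
#' logarithmic sweep of the variance-smoothing floor from 1 to 1e-9 with
#' exponent step 0.099. The forest grid is the full factorial of the six
#' tuned parameters and is large (18,480 points); `reduced = TRUE` gives
#' a small diagonal useful for tests.
#'
#' @param model "svm", "rf" or "gnb".
#' @param reduced logical; return a small grid for fast runs.
#' @return data.frame, one row per grid point, in documented order
#'   (ties in tuning are broken by the first row).
#' @export
hyper_grid <- function(model = c("svm", "rf", "gnb"), reduced = FALSE) {
  model <- match.arg(model)
  g <- switch(model,
    svm = expand.grid(C = c(0.1, 1, 10, 100),
                      gamma = c(1, 0.1, 0.01, 0.001),
                      kernel = "linear", stringsAsFactors = FALSE),
    gnb = data.frame(var_smoothing = 10^(seq(0, -9, by = -0.099))),
    rf = if (reduced) {
      expand.grid(bootstrap = c(TRUE, FALSE),
                  max_depth = c(5, 26, 110),
                  max_features = "sqrt",
                  min_samples_split = c(2, 10),
                  min_samples_leaf = c(1, 4),
                  n_estimators = c(26, 70), stringsAsFactors = FALSE)
    } else {
      expand.grid(bootstrap = c(TRUE, FALSE),
                  max_depth = c(5, 15, 26, 36, 47, 57, 68, 78, 89, 99, 110),
                  max_features = c("auto", "sqrt"),
                  min_samples_split = c(2, 5, 10, 15, 20, 25),
                  min_samples_leaf = c(1, 2, 4, 6, 8, 10, 12),
                  n_estimators = c(5, 12, 19, 26, 33, 41, 48, 55, 62, 70),
                  stringsAsFactors = FALSE)
    })
  if (model == "svm" && reduced) g <- g[g$gamma == 1, , drop = FALSE]
  if (model == "gnb" && reduced) g <- g[seq(1, nrow(g), by = 10), , drop = FALSE]
  rownames(g) <- NULL
  g
}
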