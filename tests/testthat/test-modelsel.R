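# Feature selection, metric arithmetic, nested leave-one-subject-out.

test_that("the F filter matches a brute-force analysis-of-variance oracle", {
  ft <- toy_feature_table(4, 10, sep = 1.5, seed = 3)
  res <- anova_filter(ft, k = 5)
  for (f in c("inf1", "noise1", "noise4")) {
    oracle <- anova(lm(ft[[f]] ~ ft$load_class))$`F value`[1]
    expect_equal(unname(res$anova_scores[f]), oracle, tolerance = 1e-9)
  }
  # a near-label feature ranks first
  ft$leak <- as.numeric(ft$load_class == "HL") + rnorm(nrow(ft), 0, 1e-3)
  expect_equal(anova_filter(ft, k = 3)$kept[1], "leak")
})

test_that("constant features are ranked last with a warning; k = all keeps all", {
  ft <- toy_feature_table(4, 10, seed = 4)
  ft$const <- 1
  expect_warning(res <- anova_filter(ft, k = ncol(ft) - 5), regexp = "const")
  expect_equal(tail(res$kept, 1), "const")
  expect_setequal(res$kept, setdiff(names(ft), feature_meta_columns()))
})

test_that("recursive elimination recovers the informative pair and is seed-stable", {
  ft <- toy_feature_table(8, 20, sep = 3, p_noise = 18, seed = 5)
  sel1 <- select_features(ft, k = 20, folds = 8, seed = 9)
  sel2 <- select_features(ft, k = 20, folds = 8, seed = 9)
  expect_identical(sel1$selected, sel2$selected)
  expect_true(all(c("inf1", "inf2") %in% sel1$selected))
  expect_lte(length(sel1$selected), 4)   # at most two extras
  expect_equal(sel1$rfecv_curve$n_features, 1:20)
})

test_that("all-noise features give a flat near-chance elimination curve", {
  ft <- toy_feature_table(6, 16, sep = 0, p_noise = 10, seed = 6)
  sel <- rfecv_select(ft, folds = 6, seed = 2,
                      rf_params = list(n_estimators = 30, max_depth = 10))
  expect_lt(mean(sel$curve$mean_f1), 0.62)
})

test_that("metric arithmetic reproduces the reference per-subject rows", {
  m <- compute_metrics(61, 8, 0, 48)
  expect_equal(round(m$precision, 2), 92.86)
  expect_equal(round(m$f1, 2), 93.08)
  expect_equal(round(m$recall, 2), 94.20)
  expect_equal(round(m$accuracy, 2), 93.16)
  m2 <- compute_metrics(31, 3, 0, 47)
  expect_equal(round(m2$precision, 2), 97.00)
  expect_equal(round(m2$accuracy, 2), 96.30)
  m3 <- compute_metrics(40, 0, 0, 25)
  expect_equal(unlist(m3[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 100, recall = 100, f1 = 100, accuracy = 100))
  expect_warning(compute_metrics(0, 0, 5, 5), regexp = "0/0")
})

test_that("metrics equal an independent confusion-matrix evaluation", {
  set.seed(11)
  truth <- sample(c("HL", "LL"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.3, sample(c("HL", "LL"), 200, TRUE), truth)
  m <- cogload:::compute_metrics_from_labels(truth, pred)
  tab <- table(truth, pred)
  acc <- 100 * sum(diag(tab)) / sum(tab)
  expect_equal(m$accuracy, acc)
  prec_by_class <- diag(tab) / colSums(tab)[rownames(tab)]
  expect_equal(m$precision, 100 * mean(prec_by_class), tolerance = 1e-9)
})

test_that("nested evaluation: separable data reach 100 %, metrics compose", {
  ft <- toy_feature_table(6, 16, sep = 6, seed = 7)
  ev <- nested_loso(ft, hyper_grid("svm"), "svm", mode = "reproduction",
                    features = c("inf1", "inf2"), seed = 1)
  s <- summarise_evaluations(ev)
  expect_equal(s$accuracy, 100)
  for (e in ev) {
    m <- compute_metrics(e$tp, e$fn, e$fp, e$tn)
    expect_equal(m$f1, e$f1)
    expect_equal(m$accuracy, e$accuracy)
  }
  # single-subject summary is that subject
  s1 <- summarise_evaluations(ev[1])
  expect_equal(s1$accuracy, ev[[1]]$accuracy)
})

test_that("grid determinism: a fixed seed fixes the winning grid point", {
  ft <- toy_feature_table(5, 12, sep = 1, seed = 8)
  e1 <- nested_loso(ft, hyper_grid("rf", reduced = TRUE)[1:6, ], "rf",
                    mode = "reproduction", features = c("inf1", "inf2", "noise1"),
                    seed = 5)
  e2 <- nested_loso(ft, hyper_grid("rf", reduced = TRUE)[1:6, ], "rf",
                    mode = "reproduction", features = c("inf1", "inf2", "noise1"),
                    seed = 5)
  expect_identical(lapply(e1, `[[`, "best_params"),
                   lapply(e2, `[[`, "best_params"))
})

test_that("the tuned grids carry the documented value lists", {
  g <- hyper_grid("svm")
  expect_setequal(unique(g$C), c(0.1, 1, 10, 100))
  expect_setequal(unique(g$gamma), c(1, 0.1, 0.01, 0.001))
  expect_true(all(g$kernel == "linear"))
  rf <- hyper_grid("rf")
  expect_equal(nrow(rf), 2 * 11 * 2 * 6 * 7 * 10)
  gnb <- hyper_grid("gnb")
  expect_equal(max(gnb$var_smoothing), 1)
  expect_lt(min(gnb$var_smoothing), 1.3e-9)
})

test_that("there are never fewer than 3 subjects and leakage is guarded", {
  ft <- toy_feature_table(2, 10, seed = 9)
  expect_error(nested_loso(ft, hyper_grid("svm"), "svm",
                           mode = "reproduction", features = "inf1"),
               class = "cogload_parameter_error")
})
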