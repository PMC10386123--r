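# Questionnaire scoring and the routed statistics.

test_that("affect scoring: sums, bounds, and errors on missing items", {
  items <- as.data.frame(as.list(setNames(rep(1, 20), paste0("item_", 1:20))))
  neg_idx <- setdiff(1:20, panas_positive_items())
  items[paste0("item_", neg_idx)] <- 2
  s <- score_panas(items)
  expect_equal(s$negative, 20)
  expect_equal(s$positive, 10)
  expect_error(score_panas(items[-1]), class = "cogload_scoring_error")
  items$item_3 <- NA
  expect_error(score_panas(items), class = "cogload_scoring_error")
  items$item_3 <- 9
  expect_error(score_panas(items), class = "cogload_scoring_error")
})

test_that("workload scoring: unweighted mean and weighted variant", {
  expect_equal(score_nasatlx(rep(50, 6)), 50)
  expect_equal(score_nasatlx(c(0, 0, 0, 0, 0, 100)), 16.67, tolerance = 1e-2)
  expect_equal(score_nasatlx(c(80, 0, 0, 0, 0, 0), c(15, 0, 0, 0, 0, 0)), 80)
  expect_equal(score_nasatlx(rep(50, 6), rep(2.5, 6)), 50)
  expect_error(score_nasatlx(rep(50, 6), rep(1, 6)),
               class = "cogload_scoring_error")
  expect_error(score_nasatlx(rep(150, 6)), class = "cogload_scoring_error")
})

test_that("the signed-rank test is exact where enumeration is possible", {
  # n = 6, all positive distinct differences: two-sided p = 2/2^6
  x <- c(5, 6, 7, 8, 9, 10); y <- c(1, 1.5, 2, 2.2, 3, 3.9)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$p_value, 0.03125)
  expect_equal(w$method, "exact")
  # one nonzero difference: exact two-sided p = 1
  w1 <- wilcoxon_signed_rank(c(1, 1, 2), c(1, 1, 1))
  expect_equal(w1$p_value, 1)
  # enumeration with ties agrees with the scipy convention on the
  # bundled after-load vs after-eating comparison
  ref <- reference_table("negative_affect")
  w2 <- wilcoxon_signed_rank(ref$after_load, ref$after_eating)
  expect_equal(w2$p_value, 0.0009765625, tolerance = 1e-9)
  expect_equal(w2$method, "exact_ties")
})

test_that("routing: identical pairs give t = 0, p = 1; shifts route as expected", {
  set.seed(13)
  a <- rnorm(10, 10, 2)
  r <- route_test(cbind(a, a), "paired_2", "self")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # a clean normal shift routes to the paired t-test
  b <- a + 1 + rnorm(10, 0, 0.5)
  r2 <- route_test(cbind(a, b), "paired_2")
  expect_equal(r2$test, "paired_t")
  expect_lt(r2$p_value, 0.05)
  expect_error(route_test(cbind(a[1:2], b[1:2]), "paired_2"),
               class = "cogload_parameter_error")
})

test_that("the three-timepoint route reproduces the reference Friedman analysis", {
  ref <- reference_table("negative_affect")
  m <- as.matrix(ref[, c("before_load", "after_load", "after_eating")])
  r <- route_test(m, "repeated_3", "negative affect, high-load session")
  expect_equal(r$test, "friedman")
  expect_equal(unname(r$group_means), c(13.3, 15.3, 11.5), tolerance = 0.05)
  expect_equal(r$p_value, 0.0005, tolerance = 0.05)   # prints as 0.0005
  # brute-force tie-corrected rank statistic agrees within 1e-6
  R <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  A <- sum(R^2); C <- n * k * (k + 1)^2 / 4
  stat_bf <- (k - 1) * sum((colSums(R) - n * (k + 1) / 2)^2) / (A - C)
  expect_equal(unname(r$statistic), stat_bf, tolerance = 1e-6)
})

test_that("post-hoc pairs behave per contract in both methods", {
  ref <- reference_table("negative_affect")
  m <- as.matrix(ref[, c("before_load", "after_load", "after_eating")])
  ph <- posthoc_pairwise(m)
  pv <- vapply(ph, `[[`, numeric(1), "p_value")
  expect_lt(pv[3], 0.005)            # after load vs after eating: significant
  expect_gt(pv[1], 0.05)             # before vs after load: not significant
  nem <- posthoc_pairwise(m, method = "nemenyi")
  pvn <- vapply(nem, `[[`, numeric(1), "p_value")
  expect_stat_close(pvn[3], 0.002, 0.0006)   # rounds to the printed 0.002
  # a condition against itself
  dup <- m; dup[, 2] <- dup[, 1]
  expect_warning(ph2 <- posthoc_pairwise(dup), regexp = "identical")
  expect_equal(ph2[[1]]$p_value, 1)
})

test_that("the affect flag reproduces the reference subjects", {
  ref <- reference_table("negative_affect")
  long <- data.frame(
    subject_id = rep(ref$subject_id, 3),
    timepoint = rep(c("before_load", "after_load", "after_eating"), each = 12),
    negative = c(ref$before_load, ref$after_load, ref$after_eating))
  flags <- flag_higher_negative_affect(long)
  expect_equal(sum(flags), 8)
  expect_false(flags[["5"]])   # (10, 10, 10)
  expect_false(flags[["3"]])   # (17, 13, 11)
  expect_true(flags[["1"]])
  # missing timepoint excludes the subject
  flags2 <- flag_higher_negative_affect(long[-1, ])
  expect_false("1" %in% names(flags2))
})

test_that("direction of change is the rounded session-mean ratio and is symmetric", {
  ref <- reference_table("food_means")
  expect_equal(direction_of_change(ref$mean_hl, ref$mean_ll), ref$direction)
  expect_equal(direction_of_change(158.9, 120.1), 1.3)
  expect_equal(direction_of_change(38.00, 25.10), 1.5)
  expect_equal(direction_of_change(10, 10), 1.0)
  r <- 158.9 / 120.1
  expect_equal(1 / r, 120.1 / 158.9)   # label swap maps r to 1/r
})

test_that("food summaries route tests per item and exclude unmatched items", {
  tab <- generate_food_table(10, c(chips = 1.6), seed = 14)
  fs <- food_summary(tab)
  expect_true(all(c("chips", "sugar_g", "total_kcal") %in% fs$item))
  chips <- fs[fs$item == "chips", ]
  expect_gt(chips$direction, 1)
  expect_true(chips$test %in% c("paired_t", "wilcoxon"))
  # drop one session of one item
  tab2 <- tab[!(tab$item == "nuts" & tab$session_type == "HL"), ]
  expect_warning(fs2 <- food_summary(tab2), regexp = "nuts")
  expect_false("nuts" %in% fs2$item)
})

test_that("scoring bounds hold on generated questionnaires", {
  spec <- compact_spec("s03", "HL", seed = 15)
  q <- generate_questionnaires(spec, affect_effect = 2, workload_effect = 30,
                               seed = 16)
  s <- score_panas(q$panas)
  expect_true(all(s$positive >= 10 & s$positive <= 50))
  expect_true(all(s$negative >= 10 & s$negative <= 50))
  wl <- score_nasatlx(q$nasatlx[, c("mental", "physical", "temporal",
                                    "performance", "effort", "frustration")])
  expect_true(all(wl >= 0 & wl <= 100))
})
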