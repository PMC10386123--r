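# Questionnaire scoring and the normality-routed statistical decision
# tree for affect, workload and food-consumption comparisons.

#' Score the 20-item affect schedule
#'
#' Positive and negative affect are each the sum of ten 1-5 items, so
#' both subscales range 10-50.
#'
#' @param items data.frame with columns `item_1` .. `item_20` (plus any
#'   metadata columns, which are carried through).
#' @return The metadata columns plus `positive` and `negative` sums.
#' @export
score_panas <- function(items) {
  cols <- paste0("item_", 1:20)
  missing <- setdiff(cols, names(items))
  if (length(missing))
    cogload_error("cogload_scoring_error",
                  paste("missing item column(s):", paste(missing, collapse = ", ")))
  vals <- as.matrix(items[cols])
  if (any(!is.finite(vals)))
    cogload_error("cogload_scoring_error", "missing item response (no imputation)")
  if (any(vals < 1 | vals > 5))
    cogload_error("cogload_scoring_error", "item responses must be in 1..5")
  pos <- panas_positive_items()
  out <- items[setdiff(names(items), cols)]
  out$positive <- rowSums(vals[, pos, drop = FALSE])
  out$negative <- rowSums(vals[, -pos, drop = FALSE])
  out
}

#' Score the six-subscale workload index
#'
#' Unweighted (raw) variant: the mean of the six subscales. Weighted
#' variant: `sum(w_i * s_i) / 15` with pairwise-comparison weights
#' summing to 15.
#'
#' @param subscales numeric vector (or matrix/data.frame rows) of six
#'   values in 0-100.
#' @param weights optional numeric vector of six weights summing to 15.
#' @return Workload score(s), 0-100.
#' @export
score_nasatlx <- function(subscales, weights = NULL) {
  m <- if (is.null(dim(subscales))) matrix(as.numeric(subscales), nrow = 1)
       else as.matrix(subscales)
  if (ncol(m) != 6)
    cogload_error("cogload_scoring_error", "need exactly six subscales")
  if (any(m < 0 | m > 100))
    cogload_error("cogload_scoring_error", "subscales must be in 0..100")
  if (is.null(weights)) {
    out <- rowMeans(m)
  } else {
    if (length(weights) != 6 || abs(sum(weights) - 15) > 1e-9)
      cogload_error("cogload_scoring_error", "weights must be six values summing to 15")
    out <- as.numeric(m %*% weights) / 15
  }
  if (length(out) == 1) out[[1]] else out
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Zero differences are dropped (Wilcoxon's original rule). The p-value
#' is exact (via the signed-rank distribution without ties, or complete
#' sign-flip enumeration with ties) for n <= `exact_max` effective
#' pairs, otherwise a tie-corrected normal approximation without
#' continuity correction.
#'
#' @param x,y paired samples.
#' @param exact_max largest n for exact enumeration with ties
#'   (default 14; 2^n sign patterns are enumerated).
#' @return List: `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 14) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties && n <= 25) {
    p <- min(1, 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n)))
    method <- "exact"
  } else if (n <= exact_max) {
    # enumerate all sign assignments of the observed (tied) ranks
    tot <- 2^n
    stats <- colSums(r * (t(as.matrix(expand.grid(rep(list(c(0, 1)), n))))))
    lo <- sum(stats <= V) / tot
    hi <- sum(stats >= V) / tot
    p <- min(1, 2 * min(lo, hi))
    method <- "exact_ties"
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(statistic = V, p_value = p, n_effective = n, method = method)
}

#' Normality-routed paired / repeated-measures test
#'
#' Implements the analysis decision tree: Shapiro-Wilk on each condition
#' decides the route. For two paired conditions, normal data take a
#' paired t-test, non-normal data a Wilcoxon signed-rank test. Three
#' repeated conditions take the Friedman test (the nonparametric route
#' is also used when all conditions pass normality, and the routing is
#' recorded so the choice is auditable).
#'
#' @param samples matrix/data.frame, one column per condition, complete
#'   cases only (n >= 3 rows).
#' @param design "paired_2" or "repeated_3".
#' @param label comparison label carried into the result.
#' @return A `stat_result`: `comparison`, `test`, `statistic`,
#'   `p_value`, `group_means`, `group_sds`, `shapiro_p`, `routing`.
#' @export
route_test <- function(samples, design = c("paired_2", "repeated_3"),
                       label = "") {
  design <- match.arg(design)
  m <- as.matrix(samples)
  if (any(!is.finite(m)))
    cogload_error("cogload_parameter_error", "complete cases only")
  if (nrow(m) < 3)
    cogload_error("cogload_parameter_error", "need at least 3 paired observations")
  ncond <- if (design == "paired_2") 2 else 3
  if (ncol(m) != ncond)
    cogload_error("cogload_parameter_error",
                  sprintf("%s needs %d columns", design, ncond))
  sw <- apply(m, 2, function(col) {
    if (sd(col) < 1e-12) return(0)   # constant: not normal
    shapiro.test(col)$p.value
  })
  normal <- all(sw > 0.05)
  if (design == "paired_2") {
    dif <- m[, 1] - m[, 2]
    if (normal) {
      res <- if (sd(dif) < 1e-12) {
        # degenerate paired data: identical samples give t = 0, p = 1
        if (all(dif == 0)) list(test = "paired_t", statistic = 0, p_value = 1)
        else list(test = "paired_t", statistic = sign(mean(dif)) * Inf,
                  p_value = 0)
      } else {
        tt <- t.test(m[, 1], m[, 2], paired = TRUE)
        list(test = "paired_t", statistic = unname(tt$statistic),
             p_value = tt$p.value)
      }
    } else {
      w <- wilcoxon_signed_rank(m[, 1], m[, 2])
      res <- list(test = "wilcoxon", statistic = w$statistic,
                  p_value = w$p_value)
    }
  } else {
    fr <- friedman.test(m)
    res <- list(test = "friedman", statistic = unname(fr$statistic),
                p_value = fr$p.value)
  }
  structure(list(comparison = label, test = res$test,
                 statistic = res$statistic, p_value = res$p_value,
                 group_means = colMeans(m), group_sds = apply(m, 2, sd),
                 shapiro_p = sw,
                 routing = if (normal) "normal" else "non_normal"),
            class = "stat_result")
}

special_case_identical <- function(m) all(m[, 1] == m[, 2])

#' Post-hoc pairwise comparisons after a significant Friedman test
#'
#' The default interpretation is uncorrected pairwise Wilcoxon
#' signed-rank tests over the three condition pairs (zeros dropped).
#' The alternative `"nemenyi"` method uses the studentized-range
#' post-hoc on mean ranks. A condition compared with itself yields
#' p = 1.
#'
#' @param samples matrix/data.frame with three condition columns.
#' @param method "wilcoxon" (default) or "nemenyi".
#' @return List of `stat_result`, one per pair (1-2, 1-3, 2-3).
#' @export
posthoc_pairwise <- function(samples, method = c("wilcoxon", "nemenyi")) {
  method <- match.arg(method)
  m <- as.matrix(samples)
  stopifnot(ncol(m) == 3)
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("cond", 1:3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  if (method == "nemenyi") {
    n <- nrow(m); k <- 3
    R <- t(apply(m, 1, rank))
    rm_ <- colMeans(R)
    se <- sqrt(k * (k + 1) / (6 * n))
    out <- lapply(pairs, function(pr) {
      q <- abs(rm_[pr[1]] - rm_[pr[2]]) / se * sqrt(2)
      p <- 1 - ptukey(q, nmeans = k, df = Inf)
      structure(list(comparison = paste(cn[pr], collapse = " vs "),
                     test = "nemenyi", statistic = q, p_value = p,
                     group_means = colMeans(m[, pr]),
                     group_sds = apply(m[, pr], 2, sd),
                     routing = "rank"),
                class = "stat_result")
    })
    return(out)
  }
  lapply(pairs, function(pr) {
    sub <- m[, pr]
    if (special_case_identical(sub)) {
      w <- list(statistic = 0, p_value = 1)
      warning("identical conditions; p = 1")
    } else {
      w <- wilcoxon_signed_rank(sub[, 1], sub[, 2])
    }
    structure(list(comparison = paste(cn[pr], collapse = " vs "),
                   test = "posthoc_wilcoxon", statistic = w$statistic,
                   p_value = w$p_value, group_means = colMeans(sub),
                   group_sds = apply(sub, 2, sd), routing = "non_normal"),
              class = "stat_result")
  })
}

#' Flag subjects whose negative affect peaked right after load
#'
#' TRUE iff negative affect after load strictly exceeds both the
#' before-load and the after-eating scores (high-load session).
#'
#' @param panas_scores data.frame with columns `subject_id`,
#'   `timepoint` (before_load / after_load / after_eating) and
#'   `negative`; one row per subject x timepoint.
#' @return Named logical vector, one entry per subject with all three
#'   timepoints (others are excluded).
#' @export
flag_higher_negative_affect <- function(panas_scores) {
  out <- logical(0)
  for (s in as.character(unique(panas_scores$subject_id))) {
    sub <- panas_scores[as.character(panas_scores$subject_id) == s, ]
    g <- function(tp) sub$negative[sub$timepoint == tp]
    if (!all(vapply(c("before_load", "after_load", "after_eating"),
                    function(tp) length(g(tp)) == 1, logical(1)))) next
    out[[s]] <- g("after_load") > g("before_load") &&
      g("after_load") > g("after_eating")
  }
  out
}

#' Energy and sugar densities of the offered snacks
#'
#' Reads the static density table shipped with the package (synthetic
#' stand-in values typical of packaged-food labels; user-overridable).
#' @param path optional CSV overriding the shipped table.
#' @return data.frame: item, kcal_per_100, sugar_per_100.
#' @export
food_density_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "food_density_synthetic.csv",
                        package = "cogload")
  read.csv(path)
}

#' Per-item food-consumption comparison between sessions
#'
#' For each item (and for total energy and sugar), computes high- and
#' low-load means and standard deviations over the analysis subgroup,
#' runs the normality-routed paired test, and reports the direction of
#' change, the ratio of the high-load mean to the low-load mean rounded
#' to one decimal (above 1 means more was consumed under high load).
#'
#' @param records long data.frame: `subject_id`, `session_type`,
#'   `item`, `consumed_g` (as produced by [generate_food_table()]).
#' @param subgroup optional subject ids restricting the analysis (e.g.
#'   the higher-negative-affect subjects); default all.
#' @param density density table, see [food_density_table()].
#' @return data.frame, one row per item plus `sugar_g` and
#'   `total_kcal`: means, sds, `p_value`, `test`, `direction`.
#' @export
food_summary <- function(records, subgroup = NULL,
                         density = food_density_table()) {
  if (!is.null(subgroup))
    records <- records[records$subject_id %in% subgroup, ]
  subjects <- sort(unique(records$subject_id))
  items <- unique(records$item)
  wide <- function(item_rows, value) {
    hl <- setNames(item_rows[[value]][item_rows$session_type == "HL"],
                   item_rows$subject_id[item_rows$session_type == "HL"])
    ll <- setNames(item_rows[[value]][item_rows$session_type == "LL"],
                   item_rows$subject_id[item_rows$session_type == "LL"])
    common <- intersect(names(hl), names(ll))
    cbind(HL = hl[common], LL = ll[common])
  }
  rows <- list()
  add_row <- function(name, m) {
    if (nrow(m) < 3) {
      warning("item ", name, " lacks paired data; excluded")
      return()
    }
    rt <- route_test(m, "paired_2", label = name)
    dir <- if (mean(m[, "LL"]) > 0)
      round(mean(m[, "HL"]) / mean(m[, "LL"]), 1) else NA_real_
    rows[[length(rows) + 1]] <<- data.frame(
      item = name, mean_hl = mean(m[, "HL"]), sd_hl = sd(m[, "HL"]),
      mean_ll = mean(m[, "LL"]), sd_ll = sd(m[, "LL"]),
      p_value = rt$p_value, test = rt$test, direction = dir)
  }
  per_subject_kcal <- aggregate_energy(records, density)
  for (it in items) {
    sub <- records[records$item == it, ]
    if (!all(c("HL", "LL") %in% sub$session_type)) {
      warning("item ", it, " absent in one session; excluded")
      next
    }
    add_row(it, wide(sub, "consumed_g"))
  }
  add_row("sugar_g", wide(per_subject_kcal, "sugar_g"))
  add_row("total_kcal", wide(per_subject_kcal, "kcal"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

aggregate_energy <- function(records, density = food_density_table()) {
  dd <- setNames(density$kcal_per_100, density$item)
  ss <- setNames(density$sugar_per_100, density$item)
  miss <- setdiff(unique(records$item), names(dd))
  if (length(miss))
    cogload_error("cogload_parameter_error",
                  paste("no density for item(s):", paste(miss, collapse = ", ")))
  records$kcal <- records$consumed_g * dd[records$item] / 100
  records$sugar_g <- records$consumed_g * ss[records$item] / 100
  stats::aggregate(cbind(kcal, sugar_g) ~ subject_id + session_type,
                   data = records, FUN = sum)
}

#' Direction of change between session means
#' @param mean_hl,mean_ll group means.
#' @return `round(mean_hl / mean_ll, 1)`.
#' @export
direction_of_change <- function(mean_hl, mean_ll) round(mean_hl / mean_ll, 1)
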