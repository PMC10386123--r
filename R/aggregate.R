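# Per-subject aggregation of classification accuracy, affect flags and
# normalized food consumption, plus hierarchical clustering of items.

#' Min-max normalize food consumption per item-session column
#'
#' Each item-session column is scaled to 0-1 across all subjects and
#' both sessions jointly, `(x - min) / (max - min)`, so grams and
#' millilitres become comparable. A constant column maps to all zeros
#' with a warning. Calories are deliberately excluded (water has zero
#' calories and would distort the scale).
#'
#' @param records long food table (`subject_id`, `session_type`,
#'   `item`, `consumed_g`).
#' @return data.frame: `subject_id`, then one `item_session` column per
#'   item and session, values in 0-1.
#' @export
normalize_food <- function(records) {
  if (any(records$consumed_g < 0))
    cogload_error("cogload_parameter_error", "amounts must be non-negative")
  subjects <- sort(unique(records$subject_id))
  out <- data.frame(subject_id = subjects)
  for (it in sort(unique(records$item))) {
    sub <- records[records$item == it, ]
    lo <- min(sub$consumed_g); hi <- max(sub$consumed_g)
    for (sess in intersect(c("HL", "LL"), unique(records$session_type))) {
      col <- paste0(it, "_", sess)
      v <- sub$consumed_g[match(paste(subjects, sess),
                                paste(sub$subject_id, sub$session_type))]
      if (hi - lo < 1e-12) {
        warning("constant column ", col, "; normalized to 0")
        out[[col]] <- rep(0, length(subjects))
      } else {
        out[[col]] <- (v - lo) / (hi - lo)
      }
    }
  }
  out
}

#' Binary labels from evaluations and affect flags
#'
#' `accuracy_label` is 1 iff the subject's classification accuracy is
#' strictly above 80 %; `neg_affect_label` is 1 iff the subject's
#' negative affect peaked just after load.
#'
#' @param evals list of `subject_evaluation` (see [nested_loso()]).
#' @param affect_flags named logical vector from
#'   [flag_higher_negative_affect()].
#' @param cut accuracy threshold in percent (default 80).
#' @return data.frame: `subject_id`, `accuracy`, `accuracy_label`,
#'   `neg_affect_label`.
#' @export
binarize_labels <- function(evals, affect_flags, cut = 80) {
  acc <- vapply(evals, `[[`, numeric(1), "accuracy")
  ids <- vapply(evals, `[[`, character(1), "subject_id")
  stopifnot(all(ids %in% names(affect_flags)))
  data.frame(subject_id = ids, accuracy = acc,
             accuracy_label = as.integer(acc > cut),
             neg_affect_label = as.integer(affect_flags[ids]))
}

#' Agglomerative clustering of food items
#'
#' Items are the objects; the subjects-by-sessions normalized
#' consumption profiles are the dimensions. Ward linkage on Euclidean
#' distance by default (configurable), cut into `k` clusters.
#'
#' @param normalized output of [normalize_food()].
#' @param k number of clusters (default 3).
#' @param linkage `hclust` method (default "ward.D2").
#' @param metric `dist` method (default "euclidean").
#' @return A `cluster_result`: `assignment` (named by item), `tree`
#'   (hclust), `order` (leaf order), `newick` (tree in Newick text).
#' @export
cluster_items <- function(normalized, k = 3, linkage = "ward.D2",
                          metric = "euclidean") {
  cols <- setdiff(names(normalized), "subject_id")
  items <- unique(sub("_(HL|LL)$", "", cols))
  if (k > length(items))
    cogload_error("cogload_parameter_error",
                  sprintf("k = %d exceeds the %d items", k, length(items)))
  # profile per item: its HL and LL columns stacked over subjects
  prof <- t(vapply(items, function(it)
    c(normalized[[paste0(it, "_HL")]], normalized[[paste0(it, "_LL")]]),
    numeric(2 * nrow(normalized))))
  rownames(prof) <- items
  d <- dist(prof, method = metric)
  tree <- hclust(d, method = linkage)
  assignment <- cutree(tree, k = k)
  phy <- ape::as.phylo(tree)
  structure(list(assignment = assignment, tree = tree, order = tree$order,
                 items = items,
                 newick = ape::write.tree(phy)),
            class = "cluster_result")
}

#' Cross-tabulate accuracy labels within affect groups
#'
#' Counts and fractions of high-accuracy subjects within each
#' negative-affect group, plus per-cluster mean normalized consumption
#' by session when a clustering is supplied.
#'
#' @param labels output of [binarize_labels()].
#' @param normalized output of [normalize_food()] (optional).
#' @param clusters a `cluster_result` (optional).
#' @return List: `table` (data.frame per affect group: n, n high
#'   accuracy, fraction) and optionally `cluster_means`.
#' @export
cross_tabulate <- function(labels, normalized = NULL, clusters = NULL) {
  groups <- split(labels, labels$neg_affect_label)
  tab <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- groups[[g]]
    data.frame(neg_affect_label = as.integer(g), n = nrow(sub),
               n_high_accuracy = sum(sub$accuracy_label),
               fraction_high_accuracy =
                 if (nrow(sub)) sum(sub$accuracy_label) / nrow(sub) else NA_real_)
  }))
  out <- list(table = tab)
  if (!is.null(normalized) && !is.null(clusters)) {
    cm <- lapply(split(names(clusters$assignment), clusters$assignment),
                 function(its) {
      vapply(c("HL", "LL"), function(sess)
        mean(unlist(normalized[paste0(its, "_", sess)])), numeric(1))
    })
    out$cluster_means <- cm
  }
  out
}

#' Assemble the per-subject aggregate table
#'
#' @param labels output of [binarize_labels()].
#' @param normalized output of [normalize_food()].
#' @return data.frame keyed by subject: normalized item-session
#'   amounts, `accuracy_label`, `neg_affect_label`.
#' @export
aggregate_table <- function(labels, normalized) {
  merge(normalized, labels[c("subject_id", "accuracy_label", "neg_affect_label")],
        by = "subject_id")
}
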