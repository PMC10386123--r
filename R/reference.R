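# Published reference tables bundled as plain-text inputs.
#
# These are per-subject summary tables from a 12-subject wearable
# cognitive-load study (support-vector-machine confusion counts per
# held-out subject, negative-affect questionnaire scores at three
# timepoints of the high-load session, and per-item food-consumption
# session means). They serve as regression inputs: the package's metric
# arithmetic, questionnaire statistics and direction-of-change
# computations must reproduce the printed columns from the printed raw
# counts and scores.

#' Bundled reference tables
#'
#' @param which one of "confusion" (per-subject confusion counts and
#'   printed percent metrics), "negative_affect" (per-subject negative
#'   affect at before-load / after-load / after-eating) or
#'   "food_means" (per-item session means, sds, p-values and printed
#'   direction-of-change ratios).
#' @return data.frame.
#' @export
#' @examples
#' head(reference_table("confusion"))
reference_table <- function(which = c("confusion", "negative_affect",
                                      "food_means")) {
  which <- match.arg(which)
  f <- c(confusion = "reference_confusion.csv",
         negative_affect = "reference_negative_affect.csv",
         food_means = "reference_food_means.csv")[[which]]
  read.csv(system.file("extdata", f, package = "cogload"))
}
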