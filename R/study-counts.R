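#' Reference direction counts from the proof-of-concept study
#'
#' The package ships the published contingency counts of the
#' proof-of-concept behavioural study on preterm infants (2--5 months)
#' and toddlers (2--4 years): for each of the four feature sets and each
#' data split (toddler training, toddler validation, infant validation),
#' the number of trials predicted left/centre/right, separated by the
#' speaker side the sound actually came from. These counts are the input
#' for the validation statistics -- correct-decision rates
#' ("specificity"), exact one-sided binomial tests and cross-feature-set
#' averages -- since the underlying video recordings are not publicly
#' available.
#'
#' @param path Optional override for the TSV location (used in tests).
#' @return `study_direction_counts()`: long-format `data.frame`
#'   (`feature_set`, `class`, `split`, `left`, `right`).
#'   `study_direction_tables()`: nested list
#'   `tables[[feature_set]][[split]]` of [direction_table()] objects.
#' @examples
#' tabs <- study_direction_tables()
#' correct_decision_rate(tabs$head_rot$validation_infant) # 44/76
#' @export
study_direction_counts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "study_direction_counts.tsv",
                                package = "latreact", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname study_direction_counts
#' @export
study_direction_tables <- function(path = NULL) {
  df <- study_direction_counts(path)
  out <- list()
  for (fs in unique(df$feature_set)) {
    out[[fs]] <- list()
    for (sp in unique(df$split)) {
      sub <- df[df$feature_set == fs & df$split == sp, ]
      counts <- matrix(0L, 3L, 2L,
                       dimnames = list(class = direction_levels(),
                                       side = c("left", "right")))
      counts[sub$class, ] <- as.matrix(sub[, c("left", "right")])
      out[[fs]][[sp]] <- structure(
        counts, split = sp, feature_set = fs,
        class = c("direction_table", class(counts))
      )
    }
  }
  out
}
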