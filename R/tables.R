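## Composition shares from a printed baseline-characteristics table.

#' Recompute within-group composition percentages from a counts table
#'
#' Takes a long-format counts table (columns `group`, `characteristic`,
#' `level`, `count`) in which each group carries a `total` row, and
#' recomputes each level's share of its group as a percentage rounded to one
#' decimal — the convention such cohort tables print. A packaged example
#' (`system.file("extdata", "cohort_table_counts.tsv", package = "gxlife")`)
#' holds the genetic-risk and lifestyle composition counts of a large
#' incident-obesity cohort.
#'
#' @param counts A data frame as above, or a path to a tab-delimited file.
#' @param digits Decimals to round the percentage to (default 1).
#' @return The table with an appended `pct` column (NA on `total` rows).
#' @export
composition_shares <- function(counts, digits = 1) {
  if (is.character(counts)) counts <- utils::read.delim(counts)
  need <- c("group", "characteristic", "level", "count")
  if (!all(need %in% names(counts)))
    stop_gx("counts table must have columns: %s", paste(need, collapse = ", "))
  totals <- counts[counts$characteristic == "total", c("group", "count")]
  if (!nrow(totals)) stop_gx("counts table lacks 'total' rows")
  denom <- stats::setNames(totals$count, totals$group)
  counts$pct <- ifelse(counts$characteristic == "total", NA_real_,
                       pct(counts$count, denom[counts$group], digits))
  counts
}
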