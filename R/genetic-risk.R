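## Polygenic score standardization and quintile-based risk categories.

#' Standardize polygenic scores to mean 0, SD 1
#'
#' Affine-invariant and idempotent: standardizing `a*x + b` (a > 0) or an
#' already standardized vector returns the same values.
#'
#' @param raw_scores Numeric vector with at least two distinct finite values.
#' @return Numeric vector with sample mean 0 and sample SD 1.
#' @export
standardize_pgs <- function(raw_scores) {
  x <- raw_scores[is.finite(raw_scores)]
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop_gx("need at least two distinct finite scores (zero variance input)")
  (raw_scores - mean(x)) / stats::sd(x)
}

#' Empirical percentile ranks (average-rank convention)
#'
#' @param x Numeric vector.
#' @return Percentiles in (0, 100]; a tied block shares its average rank.
#' @export
pgs_percentile <- function(x) {
  if (!length(x)) stop_gx("empty score vector")
  100 * rank(x, ties.method = "average", na.last = "keep") / sum(!is.na(x))
}

#' Quintile-based genetic risk categories
#'
#' Low = lowest quintile (percentile <= 20), high = highest quintile
#' (percentile > 80), intermediate = quintiles 2-4. With n divisible by 5 and
#' no ties this yields exactly n/5 low and n/5 high. A tied block straddling a
#' boundary falls entirely on the side containing its average rank, so
#' categories are deterministic and permutation-invariant.
#'
#' @param pgs_z Numeric vector of (raw or standardized) scores; categories are
#'   rank-based, hence identical for both.
#' @return Data frame with columns `percentile` and `category` (factor
#'   `low` / `intermediate` / `high`).
#' @export
assign_categories <- function(pgs_z) {
  pr <- pgs_percentile(pgs_z)
  category <- ifelse(pr <= 20, "low", ifelse(pr > 80, "high", "intermediate"))
  data.frame(percentile = pr,
             category = factor(category, levels = c("low", "intermediate", "high")))
}

#' Flag the top fraction of an empirical distribution
#'
#' Used for the top-20% polygenic-score group and for the top-20% cutoffs of
#' alternative adiposity indices (body fat %, waist circumference,
#' waist-to-hip ratio). Ties at the threshold are resolved by the average-rank
#' convention, so a tied block is flagged as a whole or not at all.
#'
#' @param values Numeric vector.
#' @param fraction Fraction in (0, 1) to flag at the top.
#' @return Integer 0/1 flags.
#' @export
top_fraction_flag <- function(values, fraction = 0.2) {
  if (!length(values)) stop_gx("empty value vector")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_gx("fraction must lie strictly in (0, 1)")
  as.integer(pgs_percentile(values) > 100 * (1 - fraction))
}

#' Read a two-column polygenic score file
#'
#' @param path Tab-delimited file with columns `participant_id` and `raw_pgs`
#'   (header required).
#' @return Data frame with those two columns.
#' @export
read_pgs <- function(path) {
  if (!file.exists(path)) stop_gx("PGS file not found: %s", path)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("participant_id", "raw_pgs")
  if (!all(need %in% names(d)))
    stop_gx("PGS file must have columns: %s", paste(need, collapse = ", "))
  d[need]
}

#' Append standardized PGS, percentile and risk category to a cohort
#'
#' Adds `pgs_z`, `pgs_percentile`, `genetic_category` and the top-20% flag
#' `pgs_top20`.
#'
#' @param cohort Cohort data frame with a `pgs_raw` column, or lacking one if
#'   `scores` is supplied.
#' @param scores Optional data frame from [read_pgs()], merged by
#'   `participant_id`.
#' @return The augmented cohort.
#' @export
add_genetic_risk <- function(cohort, scores = NULL) {
  if (!is.null(scores)) {
    cohort <- merge(cohort, scores, by = "participant_id", all.x = TRUE,
                    sort = FALSE)
    cohort$pgs_raw <- cohort$raw_pgs
    cohort$raw_pgs <- NULL
  }
  if (is.null(cohort$pgs_raw)) stop_gx("cohort lacks pgs_raw")
  cohort$pgs_z <- standardize_pgs(cohort$pgs_raw)
  cat_df <- assign_categories(cohort$pgs_z)
  cohort$pgs_percentile <- cat_df$percentile
  cohort$genetic_category <- cat_df$category
  cohort$pgs_top20 <- top_fraction_flag(cohort$pgs_z, 0.2)
  cohort
}
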