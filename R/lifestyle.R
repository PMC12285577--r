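## Lifestyle factor classification and composite / weighted scoring.
##
## Five binary favorable-behavior indicators, classified from raw measures at
## fixed cutoffs; the composite score is the count of favorable behaviors
## (0-5) and the weighted score rescales fitted per-factor weights back onto
## the same 0-5 scale so both share one three-band categorization.

factor_names <- c("activity", "diet", "sedentary", "alcohol", "sleep")

#' Classify the five lifestyle factors from raw measures
#'
#' Cutoffs (favorable direction):
#' * physical activity: MET minutes/week strictly exceeding 3000;
#' * diet: at least 4 of the 8 healthy-diet criteria met;
#' * sedentary behavior: screen time at most 2 h/day;
#' * alcohol: at most 14 g/day for women, 28 g/day for men;
#' * sleep: duration within the closed interval 6 to 8 h/day.
#'
#' A missing raw measure yields a missing indicator; an unknown sex yields a
#' missing alcohol indicator; negative measures are rejected.
#'
#' @param profile A data frame (or one-row list) with columns
#'   `diet_criteria_met` (0-8), `met_min_week`, `screen_hours_day`,
#'   `alcohol_g_day`, `sleep_hours_day`, `sex` (`"female"`/`"male"`).
#' @return A data frame of five integer 0/1 columns: `activity`, `diet`,
#'   `sedentary`, `alcohol`, `sleep`.
#' @export
#' @examples
#' classify_factors(data.frame(diet_criteria_met = 4, met_min_week = 3200,
#'   screen_hours_day = 1.5, alcohol_g_day = 10, sleep_hours_day = 7,
#'   sex = "female"))
classify_factors <- function(profile) {
  profile <- as.data.frame(profile)
  need <- c("diet_criteria_met", "met_min_week", "screen_hours_day",
            "alcohol_g_day", "sleep_hours_day", "sex")
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop_gx("profile lacks column(s): %s", paste(miss, collapse = ", "))
  num <- profile[, setdiff(need, "sex")]
  if (any(unlist(num) < 0, na.rm = TRUE))
    stop_gx("raw lifestyle measures must be nonnegative")
  if (any(profile$diet_criteria_met > 8, na.rm = TRUE))
    stop_gx("diet_criteria_met must be at most 8")
  thr <- ifelse(profile$sex == "female", 14,
                ifelse(profile$sex == "male", 28, NA_real_))
  data.frame(
    activity  = as.integer(profile$met_min_week > 3000),
    diet      = as.integer(profile$diet_criteria_met >= 4),
    sedentary = as.integer(profile$screen_hours_day <= 2),
    alcohol   = as.integer(profile$alcohol_g_day <= thr),
    sleep     = as.integer(profile$sleep_hours_day >= 6 &
                             profile$sleep_hours_day <= 8))
}

#' Composite lifestyle score: count of favorable behaviors
#'
#' One point per favorable behavior; a missing indicator makes the score
#' missing (the record is excluded from score-based analyses downstream).
#'
#' @param indicators Data frame or matrix of the five 0/1 indicators.
#' @return Integer vector in 0-5 (NA where any indicator is missing).
#' @export
composite_score <- function(indicators) {
  indicators <- as.matrix(indicators)
  if (ncol(indicators) != 5L) stop_gx("expected five indicator columns")
  s <- rowSums(indicators)
  as.integer(ifelse(is.na(s), NA, s))
}

#' Three-band lifestyle categorization
#'
#' Bands on the 0-5 scale, applied identically to the integer and weighted
#' scores: poor `[0, 2)`, intermediate `[2, 4)`, healthy `[4, 5]`.
#'
#' @param score Numeric vector in \[0, 5\].
#' @return Factor with levels `healthy`, `intermediate`, `poor`.
#' @export
categorize_lifestyle <- function(score) {
  if (any(score < 0 | score > 5, na.rm = TRUE))
    stop_gx("lifestyle score must lie in [0, 5]")
  out <- ifelse(score < 2, "poor", ifelse(score < 4, "intermediate", "healthy"))
  factor(out, levels = c("healthy", "intermediate", "poor"))
}

#' Estimate per-factor lifestyle weights from a prevalent-obesity fit
#'
#' Fits a logistic regression of prevalent obesity on the five favorable
#' indicators (mutually adjusted by default, or one at a time) plus the
#' standard covariate set, and takes the absolute values of the five indicator
#' coefficients as weights. Favorable indicators carry negative log-odds on
#' the obesity scale, so the magnitude quantifies how strongly each factor
#' relates to obesity.
#'
#' @param cohort Cohort with the five indicator columns `ls_activity`, ...,
#'   `ls_sleep` (see [add_lifestyle()]), the outcome flag and covariates.
#' @param outcome Name of the 0/1 prevalent-obesity column.
#' @param adjust `"mutual"` (one joint fit, default) or `"single"`
#'   (one fit per factor).
#' @param min_n Minimum number of complete rows (refuses below it).
#' @return An object of class `lifestyle_weights`: `b` (named positive
#'   weights), `coef` (signed coefficients), `source_fit` ([gxe_fit]) and
#'   `adjust`.
#' @export
estimate_weights <- function(cohort, outcome = "obese_prev",
                             adjust = c("mutual", "single"), min_n = 500) {
  adjust <- match.arg(adjust)
  ind_cols <- paste0("ls_", factor_names)
  miss <- setdiff(c(ind_cols, outcome), names(cohort))
  if (length(miss))
    stop_gx("cohort lacks column(s): %s (run add_lifestyle() first)",
            paste(miss, collapse = ", "))
  covs <- active_covariates(cohort, "main", with_pgs = FALSE)
  keep <- stats::complete.cases(cohort[, c(ind_cols, outcome, covs)])
  dat <- cohort[keep, ]
  if (nrow(dat) < min_n)
    stop_gx("only %d complete rows; at least %d required to estimate weights",
            nrow(dat), min_n)
  get_coef <- function(terms) {
    f <- stats::reformulate(c(terms, covs), response = outcome)
    fit <- stats::glm(f, family = stats::binomial(), data = dat)
    list(fit = fit, coef = stats::coef(fit))
  }
  if (adjust == "mutual") {
    res <- get_coef(ind_cols)
    b_signed <- res$coef[ind_cols]
    source_fit <- as_gxe_fit(res$fit, family = "logistic")
    bad <- ind_cols[!is.finite(b_signed) |
                      sqrt(diag(stats::vcov(res$fit))[ind_cols]) > 5]
    if (!res$fit$converged || length(bad))
      stop_gx("weight regression unstable for factor(s): %s",
              paste(sub("^ls_", "", if (length(bad)) bad else ind_cols),
                    collapse = ", "))
  } else {
    fits <- lapply(ind_cols, get_coef)
    b_signed <- vapply(seq_along(ind_cols),
                       function(i) fits[[i]]$coef[[ind_cols[i]]], numeric(1))
    names(b_signed) <- ind_cols
    source_fit <- as_gxe_fit(fits[[1]]$fit, family = "logistic")
    if (any(!is.finite(b_signed)))
      stop_gx("weight regression unstable for factor(s): %s",
              paste(sub("^ls_", "", ind_cols[!is.finite(b_signed)]), collapse = ", "))
  }
  b <- abs(b_signed)
  names(b) <- sub("^ls_", "", names(b))
  structure(list(b = b, coef = b_signed, adjust = adjust,
                 source_fit = source_fit,
                 source_hash = config_hash(unname(b_signed))),
            class = "lifestyle_weights")
}

#' @export
print.lifestyle_weights <- function(x, ...) {
  cat(sprintf("Lifestyle weights (%s adjustment):\n", x$adjust))
  print(round(x$b, 4))
  invisible(x)
}

#' Serialize lifestyle weights to JSON (with the source-fit hash)
#' @param weights A `lifestyle_weights` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  jsonlite::write_json(list(b = as.list(weights$b), adjust = weights$adjust,
                            source_hash = weights$source_hash),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Weighted lifestyle score
#'
#' `(b1*x1 + ... + b5*x5) * 5 / sum(b)`: per-factor weights applied to the
#' favorable indicators and rescaled to the 0-5 range, so equal weights
#' reproduce the raw count exactly, all-favorable gives 5 and none gives 0.
#'
#' @param indicators Data frame/matrix of the five 0/1 indicators (columns in
#'   the order `activity`, `diet`, `sedentary`, `alcohol`, `sleep`, or named).
#' @param weights A `lifestyle_weights` object or a named/plain numeric of 5
#'   nonnegative weights with positive sum.
#' @return Numeric vector in \[0, 5\].
#' @export
weighted_score <- function(indicators, weights) {
  b <- if (inherits(weights, "lifestyle_weights")) weights$b else weights
  b <- unlist(b)
  if (length(b) != 5L || any(!is.finite(b)) || any(b < 0))
    stop_gx("weights must be five finite nonnegative values")
  if (sum(b) == 0) stop_gx("weights sum to zero; weighted score undefined")
  x <- as.matrix(as.data.frame(indicators))
  if (!is.null(names(b)) && all(names(b) %in% colnames(x))) {
    x <- x[, names(b), drop = FALSE]
  } else if (!is.null(names(b)) && all(paste0("ls_", names(b)) %in% colnames(x))) {
    x <- x[, paste0("ls_", names(b)), drop = FALSE]
  }
  if (ncol(x) != 5L) stop_gx("expected five indicator columns")
  as.numeric(x %*% b) * 5 / sum(b)
}

#' Append lifestyle indicators, scores and categories to a cohort
#'
#' Adds the indicator columns `ls_activity` ... `ls_sleep`, the composite
#' `lifestyle_score`, its `lifestyle_category`, and — when `weights` are
#' supplied — `lifestyle_score_weighted` and `lifestyle_category_weighted`
#' (same banding).
#'
#' @param cohort Cohort with the raw lifestyle measure columns.
#' @param weights Optional `lifestyle_weights`.
#' @return The augmented cohort.
#' @export
add_lifestyle <- function(cohort, weights = NULL) {
  ind <- classify_factors(cohort)
  names(ind) <- paste0("ls_", names(ind))
  cohort[names(ind)] <- ind
  cohort$lifestyle_score <- composite_score(ind)
  cohort$lifestyle_category <- categorize_lifestyle(cohort$lifestyle_score)
  if (!is.null(weights)) {
    cohort$lifestyle_score_weighted <- weighted_score(ind, weights)
    cohort$lifestyle_category_weighted <-
      categorize_lifestyle(cohort$lifestyle_score_weighted)
  }
  cohort
}
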