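## Obesity-related morbidity (ORM) scan: high-PGS association, lifestyle
## subgroups among high-PGS carriers, and BMI-mediation by adjustment.

#' Names of the morbidity endpoints present in a cohort
#' @param cohort Cohort data frame.
#' @return Character vector like `c("orm_01", ..., "orm_20")`.
#' @export
orm_endpoints <- function(cohort) {
  sort(unique(sub("_event$", "",
                  grep("^orm_\\d+_event$", names(cohort), value = TRUE))))
}

#' Bonferroni significance flags
#'
#' Strict inequality: a p-value exactly at `alpha/m` is not flagged.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Number of comparisons (default `length(p)`).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical flags.
#' @export
bonferroni_flags <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) stop_gx("m must be at least 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_gx("p-values must lie in [0, 1]")
  p < alpha / m
}

orm_fit_one <- function(cohort, ep, terms) {
  ev <- paste0(ep, "_event"); tm <- paste0(ep, "_time")
  dat <- cohort[!is.na(cohort[[ev]]), ]
  if (!any(dat[[ev]] == 1))
    return(NULL)
  tryCatch(fit_cox(dat, tm, ev, terms), error = function(e) NULL)
}

orm_row <- function(ep, contrast, tab_row, n_events, m) {
  if (is.null(tab_row)) {
    data.frame(endpoint = ep, contrast = contrast, hr = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               n_events = n_events, estimable = FALSE,
               replicated = NA, bonferroni = NA)
  } else {
    data.frame(endpoint = ep, contrast = contrast, hr = tab_row$ratio,
               ci_low = tab_row$ci_low, ci_high = tab_row$ci_high,
               p = tab_row$p, n_events = n_events, estimable = TRUE,
               replicated = tab_row$p < 0.05,
               bonferroni = bonferroni_flags(tab_row$p, m))
  }
}

#' Association scan of high genetic risk with the morbidity endpoints
#'
#' One adjusted Cox fit per endpoint, contrasting top-20% PGS carriers with
#' the remaining 80% (reference). Rows are flagged at the nominal (p < 0.05,
#' "replicated") and Bonferroni (p < 0.05/m) thresholds; endpoints with zero
#' events are returned non-estimable.
#'
#' @param cohort Scored cohort with `pgs_top20` and ORM endpoint columns.
#' @param endpoints Endpoint names (default: all present).
#' @param adjust_bmi Add baseline BMI to the design (mediation-by-adjustment).
#' @return An `orm_result` data frame, one row per endpoint.
#' @export
orm_association_scan <- function(cohort, endpoints = NULL, adjust_bmi = FALSE) {
  endpoints <- endpoints %||% orm_endpoints(cohort)
  if (!length(endpoints)) stop_gx("no morbidity endpoints in cohort")
  covs <- active_covariates(cohort)
  terms <- c("pgs_top20", covs, if (adjust_bmi) "bmi")
  m <- length(endpoints)
  rows <- lapply(endpoints, function(ep) {
    fit <- orm_fit_one(cohort, ep, terms)
    tab <- if (is.null(fit)) NULL else {
      s <- summary(fit); s[s$term == "pgs_top20", ]
    }
    orm_row(ep, "top20", tab,
            sum(cohort[[paste0(ep, "_event")]], na.rm = TRUE), m)
  })
  out <- do.call(rbind, rows)
  structure(out, adjust_bmi = adjust_bmi, class = c("orm_result", "data.frame"))
}

#' Lifestyle subgroups among high-PGS carriers
#'
#' Splits the top-20% PGS carriers into a healthy-lifestyle subgroup and an
#' unfavorable subgroup (poor and intermediate combined) and contrasts each
#' with the same reference, the remaining 80% of the cohort, from one fit
#' with two indicator terms per endpoint.
#'
#' @param cohort Scored cohort.
#' @param endpoints Endpoint names (default: all present).
#' @param adjust_bmi Add baseline BMI to the design.
#' @return An `orm_result` with two rows (contrasts `top20_healthy`,
#'   `top20_unfavorable`) per endpoint.
#' @export
orm_lifestyle_subgroups <- function(cohort, endpoints = NULL, adjust_bmi = FALSE) {
  endpoints <- endpoints %||% orm_endpoints(cohort)
  cohort$sub_healthy <- as.integer(cohort$pgs_top20 == 1 &
                                     cohort$lifestyle_category == "healthy")
  cohort$sub_unfav <- as.integer(cohort$pgs_top20 == 1 &
                                   cohort$lifestyle_category != "healthy")
  covs <- active_covariates(cohort)
  terms <- c("sub_healthy", "sub_unfav", covs, if (adjust_bmi) "bmi")
  m <- length(endpoints)
  rows <- lapply(endpoints, function(ep) {
    n_ev <- sum(cohort[[paste0(ep, "_event")]], na.rm = TRUE)
    if (sum(cohort$sub_healthy) == 0 || sum(cohort$sub_unfav) == 0) {
      return(rbind(orm_row(ep, "top20_healthy", NULL, n_ev, m),
                   orm_row(ep, "top20_unfavorable", NULL, n_ev, m)))
    }
    fit <- orm_fit_one(cohort, ep, terms)
    if (is.null(fit)) {
      return(rbind(orm_row(ep, "top20_healthy", NULL, n_ev, m),
                   orm_row(ep, "top20_unfavorable", NULL, n_ev, m)))
    }
    s <- summary(fit)
    rbind(orm_row(ep, "top20_healthy", s[s$term == "sub_healthy", ], n_ev, m),
          orm_row(ep, "top20_unfavorable", s[s$term == "sub_unfav", ], n_ev, m))
  })
  out <- do.call(rbind, rows)
  structure(out, adjust_bmi = adjust_bmi, class = c("orm_result", "data.frame"))
}

#' BMI-mediation assessment by adjustment
#'
#' Re-runs the top-20% association scan with baseline BMI in the design and
#' reports, per endpoint, the attenuation ratio `adjusted log-HR /
#' unadjusted log-HR`. Under a fully BMI-mediated genetic effect the adjusted
#' hazard ratios collapse toward 1.
#'
#' @param cohort Scored cohort.
#' @param endpoints Endpoint names (default: all present).
#' @return An `orm_result` with paired unadjusted/adjusted columns
#'   (`hr`, `hr_adj`, ...) and `attenuation`.
#' @export
orm_bmi_adjusted_scan <- function(cohort, endpoints = NULL) {
  endpoints <- endpoints %||% orm_endpoints(cohort)
  un <- orm_association_scan(cohort, endpoints, adjust_bmi = FALSE)
  ad <- orm_association_scan(cohort, endpoints, adjust_bmi = TRUE)
  out <- data.frame(endpoint = un$endpoint, contrast = un$contrast,
                    hr = un$hr, ci_low = un$ci_low, ci_high = un$ci_high,
                    p = un$p,
                    hr_adj = ad$hr, ci_low_adj = ad$ci_low,
                    ci_high_adj = ad$ci_high, p_adj = ad$p,
                    attenuation = log(ad$hr) / log(un$hr),
                    estimable = un$estimable & ad$estimable)
  structure(out, class = c("orm_result", "data.frame"))
}

#' @export
print.orm_result <- function(x, digits = 3, ...) {
  cat(sprintf("Morbidity scan (%d rows%s)\n", nrow(x),
              if (isTRUE(attr(x, "adjust_bmi"))) ", BMI-adjusted" else ""))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Median follow-up time across the morbidity endpoints
#' @param cohort Cohort with ORM time columns.
#' @return Median, in years, of all endpoint follow-up times.
#' @export
orm_median_followup <- function(cohort) {
  tcols <- grep("^orm_\\d+_time$", names(cohort), value = TRUE)
  stats::median(unlist(cohort[tcols]), na.rm = TRUE)
}
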