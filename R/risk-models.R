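## Joint 3x3 genetic-by-lifestyle grid, isolated effects, and absolute
## risk-by-age prediction from the Breslow baseline.

endpoint_kind <- function(endpoint) {
  match.arg(endpoint, c("incident", "prevalent"))
}

## Analysis rows for a given endpoint: incident analyses drop participants
## already obese at baseline so prevalent and incident case sets never overlap.
analysis_rows <- function(cohort, endpoint, outcome = "obese_prev") {
  if (endpoint == "incident" && outcome %in% names(cohort)) {
    !is.na(cohort[[outcome]]) & cohort[[outcome]] == 0
  } else rep(TRUE, nrow(cohort))
}

#' Joint genetic-by-lifestyle 3x3 category grid
#'
#' Cross-classifies genetic risk (low / intermediate / high) and lifestyle
#' (healthy / intermediate / poor) into nine categories and estimates the
#' eight contrasts against the low-genetic / healthy-lifestyle reference from
#' a single adjusted model with eight indicator terms: a Cox model for the
#' incident endpoint (prevalent cases excluded), a logistic model for the
#' prevalent endpoint.
#'
#' @param cohort Cohort with `genetic_category`, `lifestyle_category` (or the
#'   weighted variant), covariates and endpoint columns.
#' @param endpoint `"incident"` or `"prevalent"`.
#' @param outcome Prevalent-obesity flag column (default `"obese_prev"`).
#' @param weighted Use the weighted-score lifestyle categories.
#' @return A `gxe_grid`: data frame of 9 rows (genetic, lifestyle, n,
#'   n_events, ratio, ci_low, ci_high, p, estimable) with the fitted model in
#'   attribute `fit`. The reference row carries ratio 1 and no CI.
#' @export
joint_category_grid <- function(cohort, endpoint = c("incident", "prevalent"),
                                outcome = "obese_prev", weighted = FALSE) {
  endpoint <- endpoint_kind(endpoint)
  lcol <- if (weighted) "lifestyle_category_weighted" else "lifestyle_category"
  for (cl in c("genetic_category", lcol))
    if (is.null(cohort[[cl]])) stop_gx("cohort lacks %s", cl)
  rows <- analysis_rows(cohort, endpoint, outcome)
  dat <- cohort[rows, ]
  glev <- c("low", "intermediate", "high")
  llev <- c("healthy", "intermediate", "poor")
  dat$joint <- factor(paste(dat$genetic_category, dat[[lcol]], sep = "/"),
                      levels = as.vector(outer(glev, llev,
                                               function(g, l) paste(g, l, sep = "/"))))
  dat$joint <- stats::relevel(dat$joint, ref = "low/healthy")
  covs <- active_covariates(dat)
  dat$joint <- droplevels(dat$joint)  # empty cells reported non-estimable below
  fit <- if (endpoint == "incident") {
    fit_cox(dat, "obesity_time", "obesity_event", c("joint", covs))
  } else {
    fit_logistic(dat, outcome, c("joint", covs))
  }
  tab <- summary(fit)
  grid <- expand.grid(lifestyle = llev, genetic = glev,
                      stringsAsFactors = FALSE)[, c("genetic", "lifestyle")]
  evcol <- if (endpoint == "incident") "obesity_event" else outcome
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cell <- paste(grid$genetic[i], grid$lifestyle[i], sep = "/")
    in_cell <- dat$joint == cell
    term <- paste0("joint", cell)
    row <- tab[tab$term == term, ]
    if (cell == "low/healthy") {
      data.frame(genetic = grid$genetic[i], lifestyle = grid$lifestyle[i],
                 n = sum(in_cell), n_events = sum(dat[[evcol]][in_cell], na.rm = TRUE),
                 ratio = 1, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                 estimable = TRUE)
    } else if (nrow(row) == 0 || sum(in_cell) == 0) {
      data.frame(genetic = grid$genetic[i], lifestyle = grid$lifestyle[i],
                 n = sum(in_cell), n_events = sum(dat[[evcol]][in_cell], na.rm = TRUE),
                 ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, estimable = FALSE)
    } else {
      data.frame(genetic = grid$genetic[i], lifestyle = grid$lifestyle[i],
                 n = sum(in_cell), n_events = sum(dat[[evcol]][in_cell], na.rm = TRUE),
                 ratio = row$ratio, ci_low = row$ci_low, ci_high = row$ci_high,
                 p = row$p, estimable = TRUE)
    }
  }))
  structure(out, fit = fit, endpoint = endpoint,
            class = c("gxe_grid", "data.frame"))
}

#' @export
print.gxe_grid <- function(x, digits = 3, ...) {
  cat(sprintf("Joint genetic x lifestyle grid (%s endpoint, %s):\n",
              attr(x, "endpoint"),
              if (attr(x, "endpoint") == "incident") "HR" else "OR"))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Isolated effect of one domain, adjusted for the other
#'
#' Estimates the genetic (or lifestyle) category effects with the other
#' domain's categories and the standard covariates in the model, plus a trend
#' p-value obtained by replacing the domain's categories with its continuous
#' score.
#'
#' @param cohort Cohort with both category columns, `pgs_z`,
#'   `lifestyle_score` and endpoint columns.
#' @param endpoint `"incident"` or `"prevalent"`.
#' @param domain `"genetic"` or `"lifestyle"`.
#' @param outcome Prevalent-obesity flag column.
#' @param weighted Use weighted-score lifestyle categories/score.
#' @return A `gxe_isolated`: effect table rows for the domain's categories,
#'   with attributes `fit` and `trend_p`.
#' @export
isolated_effect <- function(cohort, endpoint = c("incident", "prevalent"),
                            domain = c("genetic", "lifestyle"),
                            outcome = "obese_prev", weighted = FALSE) {
  endpoint <- endpoint_kind(endpoint)
  domain <- match.arg(domain)
  lcat <- if (weighted) "lifestyle_category_weighted" else "lifestyle_category"
  lscore <- if (weighted) "lifestyle_score_weighted" else "lifestyle_score"
  rows <- analysis_rows(cohort, endpoint, outcome)
  dat <- cohort[rows, ]
  covs <- active_covariates(dat)
  dom_cat <- if (domain == "genetic") "genetic_category" else lcat
  oth_cat <- if (domain == "genetic") lcat else "genetic_category"
  dom_cont <- if (domain == "genetic") "pgs_z" else lscore
  do_fit <- function(terms) {
    if (endpoint == "incident") {
      fit_cox(dat, "obesity_time", "obesity_event", terms)
    } else fit_logistic(dat, outcome, terms)
  }
  fit <- do_fit(c(dom_cat, oth_cat, covs))
  trend <- do_fit(c(dom_cont, oth_cat, covs))
  tab <- summary(fit)
  tab <- tab[startsWith(tab$term, dom_cat), ]
  trend_p <- summary(trend)[summary(trend)$term == dom_cont, "p"]
  structure(tab, fit = fit, trend_p = trend_p, domain = domain,
            endpoint = endpoint, class = c("gxe_isolated", "data.frame"))
}

#' @export
print.gxe_isolated <- function(x, digits = 3, ...) {
  cat(sprintf("Isolated %s effect (%s endpoint), adjusted for the other domain:\n",
              attr(x, "domain"), attr(x, "endpoint")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("  trend p (continuous score): %.3g\n", attr(x, "trend_p")))
  invisible(x)
}

#' Fit the absolute-risk model for incident obesity
#'
#' Cox model of incident obesity on the lifestyle category, the continuous
#' standardized PGS and the reduced covariate set (enrollment age, sex, first
#' 4 PCs), with prevalent cases excluded. Stores the design-column means and
#' the Breslow baseline so absolute risks can be evaluated at any lifestyle
#' group and PGS percentile with covariates held at their means.
#'
#' @param cohort Scored cohort.
#' @param outcome Prevalent-obesity flag used to exclude baseline cases.
#' @param weighted Use weighted-score lifestyle categories.
#' @param timescale `"followup"` (default): time since enrollment is the
#'   hazard timescale and enrollment age is a covariate; the age-75 horizon
#'   is `75 - mean enrollment age` on that scale. `"age"`: attained age is
#'   the timescale with delayed entry at enrollment (left truncation), age
#'   leaves the covariate set, and the predicted risk conditions on being
#'   event-free at the mean enrollment age.
#' @return A `gxe_risk_model`.
#' @export
fit_risk_model <- function(cohort, outcome = "obese_prev", weighted = FALSE,
                           timescale = c("followup", "age")) {
  timescale <- match.arg(timescale)
  lcol <- if (weighted) "lifestyle_category_weighted" else "lifestyle_category"
  rows <- analysis_rows(cohort, "incident", outcome)
  dat <- cohort[rows, ]
  covs <- covariate_terms("risk-curve")
  if (timescale == "age") {
    covs <- setdiff(covs, "age_enroll")
    dat$age_exit <- dat$age_enroll + dat$obesity_time
  }
  terms <- c(lcol, "pgs_z", covs)
  fit <- if (timescale == "age") {
    fit_cox(dat, "age_exit", "obesity_event", terms, start = "age_enroll")
  } else {
    fit_cox(dat, "obesity_time", "obesity_event", terms)
  }
  mm <- stats::model.matrix(stats::reformulate(terms), data = dat)[, -1, drop = FALSE]
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  structure(list(fit = fit, lifestyle_col = lcol, timescale = timescale,
                 design_means = colMeans(mm),
                 mean_age = mean(dat$age_enroll, na.rm = TRUE),
                 basehaz = bh), class = "gxe_risk_model")
}

#' @export
print.gxe_risk_model <- function(x, ...) {
  cat(sprintf("Absolute-risk model (incident obesity), mean enrollment age %.1f y\n",
              x$mean_age))
  print(x$fit)
  invisible(x)
}

breslow_cumhaz <- function(bh, t) {
  # step-function lookup; flat extrapolation beyond the last event time
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    idx <- bh$time <= ti
    if (!any(idx)) 0 else max(bh$hazard[idx])
  }, numeric(1))
}

#' Predicted probability of obesity by a target age
#'
#' Evaluates `1 - S0(t*)^exp(eta)` with `S0` the Breslow baseline survival,
#' `t* = target_age - mean enrollment age`, and `eta` the linear predictor at
#' the requested lifestyle group, the PGS value of the requested percentile
#' (normal quantile of the standardized score), and all other covariates at
#' their sample means. Beyond the last observed event time the baseline is
#' extrapolated flat.
#'
#' @param model A [fit_risk_model()] result.
#' @param group Lifestyle category: `"healthy"`, `"intermediate"` or `"poor"`.
#' @param pgs_percentile Percentile in (0, 100).
#' @param target_age Target age in years (default 75).
#' @return Probability in percent.
#' @export
absolute_risk_by_age <- function(model, group, pgs_percentile, target_age = 75) {
  stopifnot(inherits(model, "gxe_risk_model"))
  group <- match.arg(group, c("healthy", "intermediate", "poor"))
  if (any(pgs_percentile <= 0 | pgs_percentile >= 100))
    stop_gx("pgs_percentile must lie strictly in (0, 100)")
  t_star <- target_age - model$mean_age
  if (t_star <= 0) stop_gx("target age (%.1f) not beyond mean enrollment age (%.1f)",
                           target_age, model$mean_age)
  cf <- coef(model$fit)
  xm <- model$design_means
  H0 <- if (identical(model$timescale, "age")) {
    # age timescale: baseline hazard accumulated from the mean enrollment
    # age to the target age, conditioning on being event-free at entry
    breslow_cumhaz(model$basehaz, target_age) -
      breslow_cumhaz(model$basehaz, model$mean_age)
  } else {
    breslow_cumhaz(model$basehaz, t_star)
  }
  vapply(pgs_percentile, function(pp) {
    x <- xm
    for (lv in c("intermediate", "poor")) {
      cl <- paste0(model$lifestyle_col, lv)
      if (cl %in% names(x)) x[cl] <- as.numeric(group == lv)
    }
    x["pgs_z"] <- stats::qnorm(pp / 100)
    eta <- sum(cf[names(x)] * x)
    100 * (1 - exp(-H0 * exp(eta)))
  }, numeric(1))
}

#' Risk gradient across PGS percentiles
#'
#' Evaluates the predicted probability by the target age for the healthy and
#' poor lifestyle groups over a percentile grid, and their pointwise
#' difference (poor minus healthy) in percentage units.
#'
#' @param model A [fit_risk_model()] result.
#' @param percentiles Numeric grid in (0, 100).
#' @param target_age Target age (default 75).
#' @return A `risk_curve` data frame with columns `percentile`, `healthy`,
#'   `poor`, `difference`.
#' @export
risk_gradient_curve <- function(model, percentiles = 1:99, target_age = 75) {
  healthy <- absolute_risk_by_age(model, "healthy", percentiles, target_age)
  poor <- absolute_risk_by_age(model, "poor", percentiles, target_age)
  structure(data.frame(percentile = percentiles, healthy = healthy, poor = poor,
                       difference = poor - healthy),
            target_age = target_age, class = c("risk_curve", "data.frame"))
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("Predicted obesity probability (%%) by age %s across PGS percentiles\n",
              attr(x, "target_age")))
  cat(sprintf("  median healthy %.2f%%, median poor %.2f%%; difference %.2f at p5, %.2f at p95\n",
              stats::median(x$healthy), stats::median(x$poor),
              x$difference[which.min(abs(x$percentile - 5))],
              x$difference[which.min(abs(x$percentile - 95))]))
  invisible(x)
}

#' @export
plot.risk_curve <- function(x, ...) {
  graphics::plot(x$percentile, x$poor, type = "l", col = "grey40", lwd = 2,
                 xlab = "PGS percentile",
                 ylab = sprintf("Probability of obesity by age %s (%%)",
                                attr(x, "target_age")),
                 ylim = range(c(x$healthy, x$poor)), ...)
  graphics::lines(x$percentile, x$healthy, col = "steelblue", lwd = 2)
  graphics::legend("topleft", legend = c("poor lifestyle", "healthy lifestyle"),
                   col = c("grey40", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}
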