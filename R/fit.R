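## Regression contracts: proportional hazards for incident endpoints,
## logistic for prevalent endpoints, wrapped in one S3 result class.

#' Covariate adjustment presets
#'
#' `"main"` is the full adjustment set (enrollment age, sex, education,
#' deprivation tertile, smoking status, diabetes, the four weight-affecting
#' conditions, weight-gain medication; plus genotyping array and the first 10
#' principal components when the model contains the polygenic score).
#' `"risk-curve"` is the reduced set used for absolute-risk prediction
#' (enrollment age, sex, first 4 principal components).
#'
#' @param preset `"main"` or `"risk-curve"`.
#' @param with_pgs Logical; add array flag + 10 PCs to the main set.
#' @return Character vector of covariate column names.
#' @export
covariate_terms <- function(preset = c("main", "risk-curve"), with_pgs = TRUE) {
  preset <- match.arg(preset)
  if (preset == "risk-curve")
    return(c("age_enroll", "sex", paste0("pc", 1:4)))
  base <- c("age_enroll", "sex", "education", "deprivation", "smoking",
            "diabetes", "cond_depression", "cond_cushing", "cond_hypothyroid",
            "cond_pcos", "weight_gain_med")
  if (with_pgs) base <- c(base, "array_flag", paste0("pc", 1:10))
  base
}

## Covariates usable in a given analysis subset: present, non-constant, and
## for binary flags carrying enough minority observations to adjust for (a
## condition with a couple of carriers would only destabilize the fit).
active_covariates <- function(dat, preset = "main", with_pgs = TRUE,
                              min_minority = 10L) {
  covs <- intersect(covariate_terms(preset, with_pgs), names(dat))
  keep <- vapply(covs, function(v) {
    x <- stats::na.omit(dat[[v]])
    u <- unique(x)
    if (length(u) < 2L) return(FALSE)
    if (length(u) == 2L) min(table(x)) >= min_minority else TRUE
  }, logical(1))
  covs[keep]
}

as_gxe_fit <- function(fit, family, formula = NULL) {
  cf <- stats::coef(fit)
  structure(list(
    coef = cf,
    vcov = stats::vcov(fit),
    loglik = as.numeric(stats::logLik(fit)),
    n = if (family == "cox") fit$n else stats::nobs(fit),
    n_events = if (family == "cox") fit$nevent else sum(fit$y),
    family = family,
    formula = formula %||% deparse(stats::formula(fit)),
    xlevels = fit$xlevels,
    fit = fit), class = "gxe_fit")
}

#' Fit a Cox proportional-hazards model
#'
#' Thin contract over [survival::coxph()] with Breslow tie handling (the
#' baseline survival used for absolute-risk prediction is the Breslow
#' estimator, so ties default to Breslow for internal consistency; Efron is
#' available).
#'
#' @param data Data frame.
#' @param time,event Names of the follow-up time (years) and 0/1 event
#'   columns.
#' @param terms Character vector of model terms (column names or interaction
#'   expressions).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param start Optional column of entry times for left-truncated (counting
#'   process) data, e.g. enrollment age when age is the timescale.
#' @return A `gxe_fit`: coefficients, covariance, partial log-likelihood,
#'   n, event count and the underlying fit.
#' @export
fit_cox <- function(data, time, event, terms, ties = c("breslow", "efron"),
                    start = NULL) {
  ties <- match.arg(ties)
  if (!any(data[[event]] == 1, na.rm = TRUE))
    stop_gx("no events in '%s'; cannot fit a hazards model", event)
  # a constant covariate carries no information: it gets coefficient 0 (HR 1)
  # rather than poisoning the design with a singular column
  is_const <- vapply(terms, function(tm) {
    tm %in% names(data) &&
      length(unique(stats::na.omit(data[[tm]]))) < 2L
  }, logical(1))
  const_terms <- terms[is_const]
  terms <- terms[!is_const]
  surv_lhs <- if (is.null(start)) {
    paste0("survival::Surv(", time, ", ", event, ")")
  } else {
    paste0("survival::Surv(", start, ", ", time, ", ", event, ")")
  }
  if (!length(terms)) {
    f0 <- stats::as.formula(paste0(surv_lhs, " ~ 1"))
    fit0 <- survival::coxph(f0, data = data)
    k <- length(const_terms)
    out <- structure(list(
      coef = stats::setNames(rep(0, k), const_terms),
      vcov = matrix(0, k, k, dimnames = list(const_terms, const_terms)),
      loglik = fit0$loglik[1], n = fit0$n, n_events = fit0$nevent,
      family = "cox", formula = deparse(f0), xlevels = NULL, fit = fit0),
      class = "gxe_fit")
    return(out)
  }
  f <- stats::as.formula(paste0(surv_lhs, " ~ ",
                                paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties, x = FALSE, model = FALSE),
    warning = function(w) {
      # rare-covariate monotone likelihood: harmless for the contrasts of
      # interest, so keep it out of the condition stream
      if (grepl("converged before variable|may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit))))
    stop_gx("non-estimable coefficients (collinear design): %s",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  if (is.list(fit$info) && isTRUE(fit$info$convergence > 0))
    stop_gx("Cox fit did not converge")
  out <- as_gxe_fit(fit, "cox", deparse(f))
  if (length(const_terms)) {
    k <- length(out$coef)
    all_names <- c(names(out$coef), const_terms)
    coef2 <- stats::setNames(c(out$coef, rep(0, length(const_terms))), all_names)
    vcov2 <- matrix(0, length(all_names), length(all_names),
                    dimnames = list(all_names, all_names))
    vcov2[seq_len(k), seq_len(k)] <- out$vcov
    out$coef <- coef2
    out$vcov <- vcov2
  }
  out
}

#' Fit a logistic regression
#'
#' Maximum-likelihood logistic fit with observed-information covariance;
#' errors on a one-class outcome or (quasi-)complete separation.
#'
#' @param data Data frame.
#' @param outcome Name of the 0/1 outcome column.
#' @param terms Character vector of model terms.
#' @return A `gxe_fit`.
#' @export
fit_logistic <- function(data, outcome, terms) {
  y <- data[[outcome]]
  if (length(unique(stats::na.omit(y))) < 2L)
    stop_gx("outcome '%s' has a single class; logistic fit undefined", outcome)
  f <- stats::reformulate(terms, response = outcome)
  fit <- stats::glm(f, family = stats::binomial(), data = data)
  if (!fit$converged) stop_gx("logistic fit did not converge")
  if (any(is.na(stats::coef(fit))))
    stop_gx("non-estimable coefficients (collinear design): %s",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(se)) || any(se > 100))
    stop_gx("unstable logistic fit (probable separation) in term(s): %s",
            paste(names(se)[!is.finite(se) | se > 100], collapse = ", "))
  as_gxe_fit(fit, "logistic", deparse(f))
}

#' @export
coef.gxe_fit <- function(object, ...) object$coef

#' @export
vcov.gxe_fit <- function(object, ...) object$vcov

#' @export
logLik.gxe_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' @export
confint.gxe_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coef
  if (missing(parm)) parm <- names(cf)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov))[parm]
  cbind(lower = cf[parm] - z * se, upper = cf[parm] + z * se)
}

#' Effect table for a fitted model
#'
#' @param object A `gxe_fit`.
#' @param level Confidence level (Wald).
#' @param ... Unused.
#' @return Data frame with columns `term`, `estimate`, `se`, `ratio`
#'   (HR for Cox fits, OR for logistic), `ci_low`, `ci_high`, `p`.
#' @export
summary.gxe_fit <- function(object, level = 0.95, ...) {
  cf <- object$coef
  keep <- names(cf) != "(Intercept)"
  cf <- cf[keep]
  se <- sqrt(diag(object$vcov))[names(cf)]
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
             ratio = exp(unname(cf)),
             ci_low = exp(unname(cf - z * se)),
             ci_high = exp(unname(cf + z * se)),
             p = 2 * stats::pnorm(-abs(unname(cf) / unname(se))),
             row.names = NULL)
}

#' @export
print.gxe_fit <- function(x, digits = 4, ...) {
  lab <- if (x$family == "cox") "Cox proportional-hazards" else "Logistic"
  cat(sprintf("%s fit: %s\n  n = %d, events/cases = %d\n",
              lab, x$formula, x$n, x$n_events))
  print(summary(x), digits = digits)
  invisible(x)
}

#' Serialize an effect table as TSV
#' @param fit A `gxe_fit` (or a data frame already shaped like its summary).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  tab <- if (inherits(fit, "gxe_fit")) summary(fit) else fit
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
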