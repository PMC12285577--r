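## Multiplicative and additive gene-lifestyle interaction: product-term
## tests, RERI from a continuous logistic fit, attributable-proportion
## decomposition of the joint effect, and bootstrap / delta-method CIs.

#' Multiplicative interaction test
#'
#' Adds the product of the continuous PGS and lifestyle score to the adjusted
#' logistic model and reports the Wald test of the product term.
#'
#' @param cohort Scored cohort.
#' @param outcome 0/1 prevalent-obesity column (interaction analyses default
#'   to the prevalent endpoint, which captures genetic influence accumulated
#'   from before enrollment).
#' @param g_term,l_term Continuous exposure columns.
#' @param covariates Covariate column names (default: the main preset,
#'   intersected with available columns).
#' @return List with class `gxe_mult_test`: `coefficient`, `se`, `p`,
#'   `estimable`, `term`, `fit`.
#' @export
multiplicative_test <- function(cohort, outcome = "obese_prev",
                                g_term = "pgs_z", l_term = "lifestyle_score",
                                covariates = NULL) {
  covs <- covariates %||% active_covariates(cohort)
  term <- paste0(g_term, ":", l_term)
  f <- stats::reformulate(c(g_term, l_term, term, covs), response = outcome)
  fit <- stats::glm(f, family = stats::binomial(), data = cohort)
  cf <- stats::coef(fit)
  pterm <- grep(":", names(cf), value = TRUE)
  est <- unname(cf[pterm])
  if (length(pterm) != 1L || is.na(est)) {
    return(structure(list(coefficient = NA_real_, se = NA_real_, p = NA_real_,
                          estimable = FALSE, term = term, fit = fit),
                     class = "gxe_mult_test"))
  }
  se <- sqrt(stats::vcov(fit)[pterm, pterm])
  structure(list(coefficient = est, se = se,
                 p = 2 * stats::pnorm(-abs(est / se)),
                 estimable = TRUE, term = term,
                 fit = as_gxe_fit(fit, "logistic")),
            class = "gxe_mult_test")
}

#' @export
print.gxe_mult_test <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("Multiplicative interaction term %s: non-estimable\n", x$term))
  } else {
    cat(sprintf("Multiplicative interaction %s: coef %.4f (SE %.4f), p = %.3g\n",
                x$term, x$coefficient, x$se, x$p))
  }
  invisible(x)
}

#' Relative excess risk due to interaction from three relative risks
#'
#' `RERI = RR11 - RR10 - RR01 + 1`; positive values indicate supra-additive
#' joint effects of the two exposures.
#'
#' @param rr11 Relative risk under double exposure.
#' @param rr10,rr01 Relative risks under each single exposure.
#' @return The RERI.
#' @export
reri_binary <- function(rr11, rr10, rr01) {
  if (any(c(rr11, rr10, rr01) <= 0))
    stop_gx("relative risks must be strictly positive")
  rr11 - rr10 - rr01 + 1
}

#' Default exposure contrast for the continuous interaction model
#'
#' Genetic contrast: means of the bottom and top quintiles of the
#' standardized PGS. Lifestyle contrast: 4.5 to 0.5 points on the 0-5 healthy
#' score (unfavorable direction), matching the healthy / poor categorical
#' framing.
#'
#' @param cohort Scored cohort (needs `pgs_z`).
#' @return List with numeric `g = c(g0, g1)` and `l = c(l0, l1)`.
#' @export
default_contrast <- function(cohort) {
  q <- stats::quantile(cohort$pgs_z, c(0.2, 0.8), na.rm = TRUE)
  list(g = c(mean(cohort$pgs_z[cohort$pgs_z <= q[1]], na.rm = TRUE),
             mean(cohort$pgs_z[cohort$pgs_z > q[2]], na.rm = TRUE)),
       l = c(4.5, 0.5))
}

## Relative risks (OR approximation) at the four contrast corners of a
## logistic fit with main and product terms.
corner_rrs <- function(coefs, g_term, l_term, contrast) {
  pn <- intersect(c(paste0(g_term, ":", l_term), paste0(l_term, ":", g_term)),
                  names(coefs))
  if (!length(pn)) stop_gx("fit lacks the %s x %s product term", g_term, l_term)
  bg <- coefs[[g_term]]; bl <- coefs[[l_term]]; bgl <- coefs[[pn[1]]]
  g0 <- contrast$g[1]; g1 <- contrast$g[2]
  l0 <- contrast$l[1]; l1 <- contrast$l[2]
  rr <- function(g, l) exp(bg * (g - g0) + bl * (l - l0) + bgl * (g * l - g0 * l0))
  c(RR11 = rr(g1, l1), RR10 = rr(g1, l0), RR01 = rr(g0, l1))
}

#' RERI and joint-effect decomposition from a continuous logistic fit
#'
#' Evaluates odds ratios (as relative-risk approximations) at the four
#' corners of the exposure contrast — (g0,l0) reference, (g1,l0), (g0,l1),
#' (g1,l1) — from the fitted main-effect and product coefficients, and forms
#' `RERI = RR11 - RR10 - RR01 + 1` together with the attributable
#' proportions of the joint effect:
#' `AP_G = (RR10 - 1)/(RR11 - 1)`, `AP_L = (RR01 - 1)/(RR11 - 1)`,
#' `AP_I = RERI/(RR11 - 1)`, which sum to 1 identically.
#'
#' @param fit A `gxe_fit` (logistic) containing both main terms and their
#'   product.
#' @param contrast List with `g = c(g0, g1)`, `l = c(l0, l1)`; see
#'   [default_contrast()].
#' @param g_term,l_term Names of the exposure terms in the fit.
#' @return A `gxe_decomposition` with the RRs, RERI and (if `RR11 > 1`) the
#'   attributable proportions.
#' @export
reri_continuous <- function(fit, contrast, g_term = "pgs_z",
                            l_term = "lifestyle_score") {
  coefs <- if (inherits(fit, "gxe_fit")) fit$coef else stats::coef(fit)
  rrs <- corner_rrs(coefs, g_term, l_term, contrast)
  dec <- list(RR11 = rrs[["RR11"]], RR10 = rrs[["RR10"]], RR01 = rrs[["RR01"]],
              RERI = reri_binary(rrs[["RR11"]], rrs[["RR10"]], rrs[["RR01"]]),
              contrast = contrast, g_term = g_term, l_term = l_term,
              note = "odds ratios used as relative-risk approximations")
  class(dec) <- "gxe_decomposition"
  if (dec$RR11 > 1) {
    ap <- decompose(dec$RR11, dec$RR10, dec$RR01)
    dec[names(ap)] <- ap
  }
  dec
}

#' Attributable-proportion decomposition of the joint effect
#'
#' Splits the excess risk under double exposure into the shares attributable
#' to each exposure alone and to their additive interaction. The three
#' proportions sum to 1 by construction.
#'
#' @param rr11,rr10,rr01 Relative risks (double, genetic-only,
#'   lifestyle-only exposure) versus the doubly unexposed.
#' @return Named list `AP_G`, `AP_L`, `AP_I`.
#' @export
decompose <- function(rr11, rr10, rr01) {
  if (any(c(rr11, rr10, rr01) <= 0))
    stop_gx("relative risks must be strictly positive")
  if (rr11 <= 1)
    stop_gx("RR11 = %.3f <= 1: no excess joint risk, decomposition undefined", rr11)
  reri <- reri_binary(rr11, rr10, rr01)
  list(AP_G = (rr10 - 1) / (rr11 - 1),
       AP_L = (rr01 - 1) / (rr11 - 1),
       AP_I = reri / (rr11 - 1))
}

#' @export
print.gxe_decomposition <- function(x, digits = 3, ...) {
  cat("Additive gene-lifestyle interaction (OR as RR approximation)\n")
  cat(sprintf("  RR11 %.3f, RR10 %.3f, RR01 %.3f -> RERI %.3f\n",
              x$RR11, x$RR10, x$RR01, x$RERI))
  if (!is.null(x$AP_G))
    cat(sprintf("  attributable proportions: genetic %.1f%%, lifestyle %.1f%%, interaction %.1f%%\n",
                100 * x$AP_G, 100 * x$AP_L, 100 * x$AP_I))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CIs (%s):\n", x$ci_method))
    print(round(x$ci, digits))
  }
  invisible(x)
}

#' Nonparametric bootstrap percentile confidence intervals
#'
#' Resamples participants with replacement, re-applies the estimator and
#' takes percentile intervals component-wise. Deterministic given `seed`.
#' Estimator failures on a resample are caught and counted; more than 5%
#' failures is an error.
#'
#' @param data Data frame of participants.
#' @param estimator Function `data -> named numeric vector`.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List: `ci` (matrix with columns `estimate`, `lower`, `upper`),
#'   `B`, `seed`, `n_failed`.
#' @export
bootstrap_ci <- function(data, estimator, B = 1000, seed = 1, level = 0.95) {
  if (B < 100) stop_gx("B must be at least 100")
  est <- estimator(data)
  n <- nrow(data)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = B, ncol = length(est))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(estimator(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val) || length(val) != length(est) || any(!is.finite(val))) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- val
    }
  }
  if (n_failed > 0.05 * B)
    stop_gx("%d of %d bootstrap resamples failed (> 5%%)", n_failed, B)
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  out <- cbind(estimate = est, lower = ci[, 1], upper = ci[, 2])
  rownames(out) <- names(est)
  list(ci = out, B = B, seed = as.integer(seed), n_failed = n_failed)
}

## Delta-method CI for smooth functions of the coefficient vector.
delta_ci <- function(coefs, vc, fun, level = 0.95, h = 1e-6) {
  est <- fun(coefs)
  grad <- matrix(0, nrow = length(coefs), ncol = length(est))
  for (j in seq_along(coefs)) {
    up <- coefs; up[j] <- up[j] + h
    dn <- coefs; dn[j] <- dn[j] - h
    grad[j, ] <- (fun(up) - fun(dn)) / (2 * h)
  }
  se <- sqrt(pmax(diag(t(grad) %*% vc %*% grad), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(estimate = est, lower = est - z * se, upper = est + z * se)
}

#' Full gene-lifestyle additive interaction analysis
#'
#' Fits the adjusted logistic model with continuous PGS, continuous lifestyle
#' score and their product, evaluates the RERI decomposition at the contrast,
#' and attaches confidence intervals (nonparametric bootstrap by default, or
#' the delta method).
#'
#' @param cohort Scored cohort.
#' @param outcome 0/1 prevalent-obesity column.
#' @param contrast See [default_contrast()]; computed from the cohort if NULL.
#' @param ci `"bootstrap"`, `"delta"` or `"none"`.
#' @param B,seed Bootstrap settings.
#' @param covariates Covariate columns (default main preset).
#' @return A `gxe_decomposition` with `ci` (matrix for RERI and the APs),
#'   `ci_method`, `B`, `seed` and the underlying `fit`.
#' @export
gxe_interaction <- function(cohort, outcome = "obese_prev", contrast = NULL,
                            ci = c("bootstrap", "delta", "none"),
                            B = 1000, seed = 1, covariates = NULL) {
  ci <- match.arg(ci)
  contrast <- contrast %||% default_contrast(cohort)
  covs <- covariates %||% active_covariates(cohort)
  g_term <- "pgs_z"; l_term <- "lifestyle_score"
  terms <- c(g_term, l_term, paste0(g_term, ":", l_term), covs)
  fit <- fit_logistic(cohort, outcome, terms)
  dec <- reri_continuous(fit, contrast, g_term, l_term)
  dec$fit <- fit
  quantities <- function(coefs) {
    rrs <- corner_rrs(coefs, g_term, l_term, contrast)
    reri <- reri_binary(rrs[["RR11"]], rrs[["RR10"]], rrs[["RR01"]])
    out <- c(RERI = reri)
    if (rrs[["RR11"]] > 1)
      out <- c(out, unlist(decompose(rrs[["RR11"]], rrs[["RR10"]], rrs[["RR01"]])))
    out
  }
  if (ci == "delta") {
    dec$ci <- delta_ci(fit$coef, fit$vcov, quantities)
    dec$ci_method <- "delta"
  } else if (ci == "bootstrap") {
    estimator <- function(d) {
      f <- fit_logistic(d, outcome, terms)
      quantities(f$coef)
    }
    bs <- bootstrap_ci(cohort, estimator, B = B, seed = seed)
    dec$ci <- bs$ci
    dec$ci_method <- "bootstrap"
    dec$B <- bs$B
    dec$seed <- bs$seed
    dec$n_failed <- bs$n_failed
  }
  dec
}

#' Serialize an interaction decomposition (JSON + one-row TSV)
#'
#' @param dec A `gxe_decomposition`.
#' @param path_json,path_tsv Output paths (either may be NULL to skip).
#' @return Invisibly, the list written as JSON.
#' @export
write_decomposition <- function(dec, path_json = NULL, path_tsv = NULL) {
  payload <- list(RR11 = dec$RR11, RR10 = dec$RR10, RR01 = dec$RR01,
                  RERI = dec$RERI, AP_G = dec$AP_G, AP_L = dec$AP_L,
                  AP_I = dec$AP_I, contrast = dec$contrast,
                  ci_method = dec$ci_method, B = dec$B, seed = dec$seed,
                  note = dec$note)
  if (!is.null(dec$ci))
    payload$ci <- as.data.frame(cbind(quantity = rownames(dec$ci),
                                      as.data.frame(dec$ci)))
  if (!is.null(path_json))
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  if (!is.null(path_tsv)) {
    row <- data.frame(RR11 = dec$RR11, RR10 = dec$RR10, RR01 = dec$RR01,
                      RERI = dec$RERI,
                      AP_G = dec$AP_G %||% NA, AP_L = dec$AP_L %||% NA,
                      AP_I = dec$AP_I %||% NA)
    utils::write.table(row, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(payload)
}
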