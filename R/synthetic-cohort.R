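## Synthetic cohort generator.
##
## Raw lifestyle measures are drawn from one-parameter-calibrated families so
## that the downstream classification rules reproduce the configured favorable
## prevalences in expectation; the raw distributions themselves are a modelling
## convenience, only the classified indicators carry meaning downstream.

# Closed-form / root-solved calibrations. p is always the favorable fraction.
calibrate_met_meanlog    <- function(p, sdlog = 1.1) log(3000) - sdlog * stats::qnorm(1 - p)
calibrate_screen_rate    <- function(p, shape = 2) stats::qgamma(p, shape = shape, rate = 1) / 2
calibrate_alcohol_meanlog <- function(p, threshold, sdlog = 1.3)
  log(threshold) - sdlog * stats::qnorm(p)
calibrate_sleep_sd       <- function(p) 1 / stats::qnorm((1 + p) / 2)
calibrate_diet_prob <- function(p) {
  stats::uniroot(function(q) 1 - stats::pbinom(3, 8, q) - p,
                 c(1e-6, 1 - 1e-6), tol = 1e-10)$root
}

cohort_schema <- function(n_orm) {
  cols <- c("participant_id", "age_enroll", "sex", "pgs_raw", "bmi",
            "body_fat_pct", "waist_circumference_cm", "waist_hip_ratio",
            "diet_criteria_met", "met_min_week", "screen_hours_day",
            "alcohol_g_day", "sleep_hours_day",
            "education", "deprivation", "smoking", "diabetes",
            "cond_depression", "cond_cushing", "cond_hypothyroid", "cond_pcos",
            "weight_gain_med", "array_flag", paste0("pc", 1:10),
            "obese_prev", "obesity_event", "obesity_time")
  if (n_orm > 0)
    cols <- c(cols, as.vector(rbind(sprintf("orm_%02d_event", seq_len(n_orm)),
                                    sprintf("orm_%02d_time", seq_len(n_orm)))))
  cols
}

#' Generate a synthetic cohort
#'
#' Draws one cohort under the generative model described in [sim_config()]:
#' standard-normal raw PGS; raw lifestyle measures calibrated so the
#' classification rules of [classify_factors()] hit the configured favorable
#' prevalences in expectation; BMI as a linear function of PGS and the
#' unfavorable-factor count plus Gaussian noise; prevalent obesity from the
#' logistic liability (including the gene-by-lifestyle product term); and
#' incident obesity from an exponential-baseline proportional-hazards model
#' with administrative censoring at the configured horizon. Bit-identical
#' output for identical `(config, seed)`.
#'
#' Morbidity endpoints are appended separately by [simulate_orm_endpoints()];
#' missingness is injected by [inject_missingness()].
#'
#' @param config A [sim_config()] object.
#' @return A data frame, one row per participant, with a `provenance`
#'   attribute (seed and config hash). `n_participants = 0` yields an empty
#'   table with the full column schema.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  if (n == 0L) {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0,
                                  ncol = length(cohort_schema(0L))))
    names(empty) <- cohort_schema(0L)
    attr(empty, "provenance") <- list(seed = config$seed,
                                      config_hash = config_hash(unclass(config)))
    return(empty)
  }
  cv <- config$covariate_dists
  fp <- config$factor_prevalences

  set.seed(substream(config$seed, 1L))
  age <- stats::runif(n, cv$age_range[1], cv$age_range[2])
  sex <- ifelse(stats::runif(n) < cv$female_fraction, "female", "male")
  education <- stats::rbinom(n, 1, 0.43)
  deprivation <- sample(c("least", "intermediate", "most"), n, replace = TRUE,
                        prob = c(0.2, 0.6, 0.2))
  smoking <- sample(c("never", "previous", "current"), n, replace = TRUE,
                    prob = c(0.55, 0.35, 0.10))
  diabetes <- stats::rbinom(n, 1, 0.025)
  cond_depression <- stats::rbinom(n, 1, 0.006)
  cond_cushing <- stats::rbinom(n, 1, 0.0001)
  cond_hypothyroid <- stats::rbinom(n, 1, 0.009)
  cond_pcos <- stats::rbinom(n, 1, 0.0002)
  weight_gain_med <- stats::rbinom(n, 1, 0.06)
  array_flag <- stats::rbinom(n, 1, 0.1)
  pcs <- matrix(stats::rnorm(n * 10, sd = cv$pc_sd), nrow = n,
                dimnames = list(NULL, paste0("pc", 1:10)))

  set.seed(substream(config$seed, 2L))
  pgs_raw <- stats::rnorm(n)

  set.seed(substream(config$seed, 3L))
  met_min_week <- stats::rlnorm(n, calibrate_met_meanlog(fp[["activity"]]), 1.1)
  diet_criteria_met <- stats::rbinom(n, 8, calibrate_diet_prob(fp[["diet"]]))
  screen_hours_day <- stats::rgamma(n, shape = 2,
                                    rate = calibrate_screen_rate(fp[["sedentary"]]))
  thr <- ifelse(sex == "female", 14, 28)
  alcohol_g_day <- stats::rlnorm(n, calibrate_alcohol_meanlog(fp[["alcohol"]], thr), 1.3)
  sleep_hours_day <- pmax(stats::rnorm(n, 7, calibrate_sleep_sd(fp[["sleep"]])), 0)

  ind <- classify_factors(data.frame(diet_criteria_met = diet_criteria_met,
                                     met_min_week = met_min_week,
                                     screen_hours_day = screen_hours_day,
                                     alcohol_g_day = alcohol_g_day,
                                     sleep_hours_day = sleep_hours_day,
                                     sex = sex))
  unfav <- 5 - rowSums(ind)

  bm <- config$bmi_model
  set.seed(substream(config$seed, 4L))
  bmi <- bm$intercept + bm$per_sd_pgs * pgs_raw + bm$per_factor * unfav +
    stats::rnorm(n, sd = bm$noise_sd)
  body_fat_pct <- 8 + 0.8 * bmi + ifelse(sex == "female", 9, 0) + stats::rnorm(n, sd = 3)
  waist_circumference_cm <- 30 + 2.2 * bmi + ifelse(sex == "female", -8, 0) +
    stats::rnorm(n, sd = 5)
  waist_hip_ratio <- pmax(0.55 + 0.009 * bmi + ifelse(sex == "female", -0.05, 0.03) +
                            stats::rnorm(n, sd = 0.05), 0.4)

  set.seed(substream(config$seed, 5L))
  # lifestyle burden: scalar coefficient on the unfavorable count, or
  # per-factor coefficients on the individual unfavorable indicators
  burden <- if (length(config$beta_lifestyle) == 1L) {
    config$beta_lifestyle * unfav
  } else {
    as.numeric(as.matrix(1 - ind) %*% config$beta_lifestyle)
  }
  eta <- config$beta0 + config$beta_pgs * pgs_raw + burden +
    config$beta_interaction * pgs_raw * unfav
  obese_prev <- stats::rbinom(n, 1, stats::plogis(eta))

  hz <- config$hazard_model$obesity
  set.seed(substream(config$seed, 6L))
  rate <- config$hazard_model$obesity$rate *
    exp(hz$per_bmi * (bmi - config$hazard_model$bmi_center) +
          hz$per_sd_pgs * pgs_raw + hz$per_factor * unfav)
  t_raw <- stats::rexp(n, rate = pmax(rate, 1e-12))
  obesity_event <- as.integer(t_raw <= config$censor_years)
  obesity_time <- pmin(t_raw, config$censor_years)

  cohort <- data.frame(
    participant_id = sprintf("P%07d", seq_len(n)),
    age_enroll = age, sex = sex, pgs_raw = pgs_raw, bmi = bmi,
    body_fat_pct = body_fat_pct, waist_circumference_cm = waist_circumference_cm,
    waist_hip_ratio = waist_hip_ratio,
    diet_criteria_met = diet_criteria_met, met_min_week = met_min_week,
    screen_hours_day = screen_hours_day, alcohol_g_day = alcohol_g_day,
    sleep_hours_day = sleep_hours_day,
    education = education, deprivation = deprivation, smoking = smoking,
    diabetes = diabetes, cond_depression = cond_depression,
    cond_cushing = cond_cushing, cond_hypothyroid = cond_hypothyroid,
    cond_pcos = cond_pcos, weight_gain_med = weight_gain_med,
    array_flag = array_flag, pcs,
    obese_prev = obese_prev,
    obesity_event = obesity_event, obesity_time = obesity_time,
    stringsAsFactors = FALSE)
  attr(cohort, "provenance") <- list(seed = config$seed,
                                     config_hash = config_hash(unclass(config)))
  cohort
}

#' Append simulated obesity-related morbidity endpoints
#'
#' Adds `config$n_orm` independent time-to-event endpoints
#' (`orm_01_event/time`, ...), each from an exponential-baseline
#' proportional-hazards model whose log-hazard is linear in baseline BMI
#' (the mediated path), the PGS (direct path, 0 by default so the genetic
#' effect acts only through BMI), and the unfavorable-factor count. Events are
#' administratively censored at the configured horizon. Rows with missing BMI
#' get missing endpoint fields.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param config The same [sim_config()].
#' @return The cohort with `2 * n_orm` appended columns.
#' @export
simulate_orm_endpoints <- function(cohort, config) {
  validate_sim_config(config)
  n <- nrow(cohort)
  hm <- config$hazard_model
  unfav <- 5 - rowSums(classify_factors(cohort))
  for (j in seq_len(config$n_orm)) {
    set.seed(substream(config$seed, 100L + j))
    rate <- hm$orm_rate[j] * exp(hm$orm_per_bmi[j] * (cohort$bmi - hm$bmi_center) +
                                   hm$orm_per_sd_pgs[j] * cohort$pgs_raw +
                                   hm$orm_per_factor[j] * unfav)
    rate[is.na(rate)] <- 1  # missing-BMI rows are blanked below
    t_raw <- stats::rexp(n, rate = pmax(rate, 1e-12))
    ev <- as.integer(t_raw <= config$censor_years)
    tt <- pmin(t_raw, config$censor_years)
    miss <- is.na(cohort$bmi)
    ev[miss] <- NA_integer_
    tt[miss] <- NA_real_
    cohort[[sprintf("orm_%02d_event", j)]] <- ev
    cohort[[sprintf("orm_%02d_time", j)]] <- tt
  }
  cohort
}

#' Inject independent missingness into BMI and outcome fields
#'
#' Sets baseline BMI and outcome fields (incident obesity and any morbidity
#' endpoint columns) to missing, independently per participant at the
#' configured rates, emulating missing measurement and missing record linkage.
#' Overlap between the two patterns occurs only by chance. Counts of each
#' missingness pattern are recorded in the cohort's `provenance` attribute.
#'
#' @param cohort A cohort data frame.
#' @param config A [sim_config()]; uses `missing_rates` and `seed`.
#' @return The cohort with missingness applied.
#' @export
inject_missingness <- function(cohort, config) {
  mr <- config$missing_rates
  if (any(mr < 0 | mr > 1)) stop_gx("missing rates must be in [0,1]")
  n <- nrow(cohort)
  set.seed(substream(config$seed, 7L))
  miss_bmi <- stats::runif(n) < mr[["bmi"]]
  miss_out <- stats::runif(n) < mr[["outcome"]]
  cohort$bmi[miss_bmi] <- NA_real_
  out_cols <- grep("^(obesity|orm_\\d+)_(event|time)$", names(cohort), value = TRUE)
  for (cl in out_cols) cohort[[cl]][miss_out] <- NA
  prov <- attr(cohort, "provenance") %||% list()
  prov$missingness <- list(n_missing_bmi = sum(miss_bmi),
                           n_missing_outcome = sum(miss_out),
                           n_missing_both = sum(miss_bmi & miss_out))
  attr(cohort, "provenance") <- prov
  cohort
}

#' Write / read a cohort as tab-delimited text with a JSON provenance sidecar
#'
#' @param cohort Cohort data frame.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".provenance.json")`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort with its provenance attribute restored if the sidecar exists.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(cohort, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    attr(cohort, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cohort
}
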