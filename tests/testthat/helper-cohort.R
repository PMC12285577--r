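# Shared synthetic cohorts, generated once per test run and cached.

.cohort_cache <- new.env(parent = emptyenv())

scored_cohort <- function(n = 50000, seed = 421, config = NULL,
                          with_orm = TRUE) {
  key <- paste0("c", n, "_", seed, "_", with_orm, "_",
                if (is.null(config)) "default" else gxlife:::config_hash(unclass(config)))
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- config %||% sim_config(n_participants = n, seed = seed)
  cfg$n_participants <- n
  cfg$seed <- as.integer(seed)
  co <- generate_cohort(cfg)
  if (with_orm && cfg$n_orm > 0) co <- simulate_orm_endpoints(co, cfg)
  co <- add_genetic_risk(co)
  co <- add_lifestyle(co)
  co$U <- 5 - co$lifestyle_score
  .cohort_cache[[key]] <- co
  co
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-row lifestyle profile for boundary checks
profile_row <- function(diet = 4, met = 3200, screen = 1.5, alcohol = 10,
                        sleep = 7, sex = "female") {
  data.frame(diet_criteria_met = diet, met_min_week = met,
             screen_hours_day = screen, alcohol_g_day = alcohol,
             sleep_hours_day = sleep, sex = sex)
}

# all 32 indicator combinations
indicator_grid <- function() {
  g <- expand.grid(activity = 0:1, diet = 0:1, sedentary = 0:1,
                   alcohol = 0:1, sleep = 0:1)
  g[, c("activity", "diet", "sedentary", "alcohol", "sleep")]
}
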