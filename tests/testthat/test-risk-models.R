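# brute-force Breslow partial-likelihood for one binary covariate
grid_cox_mle <- function(time, event, x, grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      at_risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[at_risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

test_that("Cox coefficient matches the brute-force partial-likelihood maximizer", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(1, 0, 1))
  fit <- fit_cox(d, "time", "event", "x")
  expect_equal(unname(coef(fit)[["x"]]),
               grid_cox_mle(d$time, d$event, d$x), tolerance = 1e-3)
  # a second configuration with both covariate values among events
  d2 <- data.frame(time = c(2, 5, 1, 4, 3), event = c(1, 0, 1, 1, 0),
                   x = c(1, 1, 0, 0, 1))
  fit2 <- fit_cox(d2, "time", "event", "x")
  expect_equal(unname(coef(fit2)[["x"]]),
               grid_cox_mle(d2$time, d2$event, d2$x), tolerance = 1e-3)
})

test_that("a constant covariate yields coefficient 0 and hazard ratio 1", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                  x = c(0, 0, 0, 0), y = c(1, 0, 1, 0))
  fit <- fit_cox(d, "time", "event", c("x", "y"))
  expect_equal(unname(coef(fit)[["x"]]), 0)
  expect_equal(summary(fit)[summary(fit)$term == "x", "ratio"], 1)
})

test_that("hazard fits reject event-free data", {
  d <- data.frame(time = 1:4, event = rep(0, 4), x = c(1, 0, 1, 0))
  expect_error(fit_cox(d, "time", "event", "x"), "no events")
})

test_that("logistic log-OR equals the 2x2 closed form", {
  tab <- c(a = 10, b = 90, c = 30, d = 70)  # exposed cases/non, unexposed
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), tab),
    x = rep(c(1, 1, 0, 0), tab))
  fit <- fit_logistic(d, "y", "x")
  expect_equal(unname(coef(fit)[["x"]]),
               log(tab["a"] * tab["d"] / (tab["b"] * tab["c"])),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("intercept-only logistic recovers the sample prevalence", {
  d <- data.frame(y = rbinom(500, 1, 0.37))
  fit <- fit_logistic(d, "y", "1")
  expect_equal(plogis(unname(coef(fit)[["(Intercept)"]])), mean(d$y),
               tolerance = 1e-8)
})

test_that("independent predictor gives an OR whose CI covers 1", {
  set.seed(404)
  d <- data.frame(y = rbinom(4000, 1, 0.3), x = rnorm(4000))
  s <- summary(fit_logistic(d, "y", "x"))
  expect_gt(s$ci_high[s$term == "x"], 1)
  expect_lt(s$ci_low[s$term == "x"], 1)
})

test_that("logistic fit errors on a one-class outcome and separation", {
  expect_error(fit_logistic(data.frame(y = rep(1, 20), x = rnorm(20)), "y", "x"),
               "single class")
  d <- data.frame(y = rep(c(0, 1), each = 25), x = rep(c(0, 1), each = 25))
  expect_error(fit_logistic(d, "y", "x"), "separation")
})

test_that("Wald intervals reproduce the reported-CI construction", {
  set.seed(7)
  d <- data.frame(y = rbinom(2000, 1, 0.25), x = rnorm(2000))
  d$y[d$x > 0.5] <- rbinom(sum(d$x > 0.5), 1, 0.45)
  fit <- fit_logistic(d, "y", "x")
  s <- summary(fit)
  i <- which(s$term == "x")
  expect_equal(s$ci_low[i], exp(s$estimate[i] - qnorm(0.975) * s$se[i]),
               tolerance = 1e-12)
  expect_equal(s$ci_high[i], exp(s$estimate[i] + qnorm(0.975) * s$se[i]),
               tolerance = 1e-12)
  ci <- confint(fit, "x")
  expect_equal(exp(ci[1, "lower"]), s$ci_low[i], tolerance = 1e-12)
})

test_that("category effects recover a known hazard gradient", {
  set.seed(62)
  n <- 50000
  gc <- factor(sample(c("low", "intermediate", "high"), n, replace = TRUE,
                      prob = c(0.2, 0.6, 0.2)),
               levels = c("low", "intermediate", "high"))
  lam <- 0.004 * exp(0.31 * (gc == "intermediate") + 0.62 * (gc == "high"))
  t_raw <- rexp(n, lam)
  d <- data.frame(time = pmin(t_raw, 12), event = as.integer(t_raw <= 12),
                  genetic_category = gc)
  fit <- fit_cox(d, "time", "event", "genetic_category")
  s <- summary(fit)
  hi <- s[s$term == "genetic_categoryhigh", ]
  expect_lt(abs(hi$estimate - 0.62), 3 * hi$se)
})

# minimal cohort whose liability is exactly additive in the category indicators,
# so the joint grid's no-interaction null is known in closed form
category_cohort <- function(n, seed, extra_high_poor = 0) {
  set.seed(seed)
  gc <- factor(sample(c("low", "intermediate", "high"), n, TRUE, c(.2, .6, .2)),
               levels = c("low", "intermediate", "high"))
  lc <- factor(sample(c("healthy", "intermediate", "poor"), n, TRUE, c(.2, .6, .2)),
               levels = c("healthy", "intermediate", "poor"))
  eta <- -2 + 0.5 * (gc == "intermediate") + 1.0 * (gc == "high") +
    0.4 * (lc == "intermediate") + 0.8 * (lc == "poor") +
    extra_high_poor * (gc == "high" & lc == "poor")
  data.frame(genetic_category = gc, lifestyle_category = lc,
             obese_prev = rbinom(n, 1, plogis(eta)))
}

test_that("joint grid has nine cells with a unit reference", {
  co <- scored_cohort(n = 20000, seed = 1009)
  grid <- joint_category_grid(co, "prevalent")
  expect_equal(nrow(grid), 9)
  ref <- grid$genetic == "low" & grid$lifestyle == "healthy"
  expect_equal(grid$ratio[ref], 1)
  expect_true(all(is.na(grid$ci_low[ref])))
  expect_true(all(grid$estimable))
  expect_equal(sum(grid$n), sum(!is.na(co$obese_prev)))
})

test_that("without interaction the corner cell equals the product of margins", {
  co <- category_cohort(60000, seed = 9001)
  grid <- joint_category_grid(co, "prevalent")
  fit <- attr(grid, "fit")
  cf <- coef(fit); vc <- vcov(fit)
  corner <- "jointhigh/poor"; g_edge <- "jointhigh/healthy"; l_edge <- "jointlow/poor"
  diff <- cf[corner] - cf[g_edge] - cf[l_edge]
  se <- sqrt(vc[corner, corner] + vc[g_edge, g_edge] + vc[l_edge, l_edge]
             - 2 * vc[corner, g_edge] - 2 * vc[corner, l_edge]
             + 2 * vc[g_edge, l_edge])
  expect_lt(abs(diff), 3 * se)
})

test_that("a positive interaction pushes the corner above the margin product", {
  co <- category_cohort(60000, seed = 9002, extra_high_poor = 0.6)
  grid <- joint_category_grid(co, "prevalent")
  fit <- attr(grid, "fit")
  cf <- coef(fit)
  expect_gt(cf["jointhigh/poor"],
            cf["jointhigh/healthy"] + cf["jointlow/poor"])
})

test_that("an empty cell is flagged non-estimable", {
  co <- category_cohort(5000, seed = 77)
  co <- co[!(co$genetic_category == "high" & co$lifestyle_category == "poor"), ]
  grid <- joint_category_grid(co, "prevalent")
  row <- grid$genetic == "high" & grid$lifestyle == "poor"
  expect_false(grid$estimable[row])
  expect_equal(grid$n[row], 0L)
})

test_that("isolated effects match the unadjusted fit when domains are independent", {
  co <- scored_cohort(n = 50000, seed = 421)
  iso <- isolated_effect(co, "prevalent", "genetic")
  expect_s3_class(iso, "gxe_isolated")
  expect_lt(attr(iso, "trend_p"), 0.001)
  # generator draws PGS and lifestyle independently, so adjustment barely moves
  # the genetic estimate
  covs <- gxlife:::active_covariates(co)
  un <- summary(fit_logistic(co, "obese_prev", c("genetic_category", covs)))
  hi_adj <- iso[iso$term == "genetic_categoryhigh", ]
  hi_un <- un[un$term == "genetic_categoryhigh", ]
  expect_lt(abs(hi_adj$estimate - hi_un$estimate),
            3 * sqrt(hi_adj$se^2 + hi_un$se^2))
  expect_error(isolated_effect(co, "prevalent", "nonsense"))
})

test_that("adjustment recovers the truth when domains are confounded", {
  set.seed(555)
  n <- 40000
  z <- rnorm(n)
  # unfavorable lifestyle correlated with genetic liability
  u <- pmin(pmax(round(2.4 + 0.8 * z + rnorm(n, 0, 1)), 0), 5)
  y <- rbinom(n, 1, plogis(-2 + 0.5 * z + 0.2 * u))
  d <- data.frame(pgs_z = z, U = u, obese_prev = y)
  crude <- summary(fit_logistic(d, "obese_prev", "pgs_z"))
  adj <- summary(fit_logistic(d, "obese_prev", c("pgs_z", "U")))
  b_crude <- crude$estimate[crude$term == "pgs_z"]
  b_adj <- adj$estimate[adj$term == "pgs_z"]
  expect_gt(b_crude, 0.55)             # confounding inflates the crude effect
  expect_lt(abs(b_adj - 0.5), 3 * adj$se[adj$term == "pgs_z"])
})

test_that("absolute risk matches the exponential-survival closed form", {
  set.seed(2718)
  n <- 20000
  lc <- factor(sample(c("healthy", "intermediate", "poor"), n, TRUE, c(.3, .4, .3)),
               levels = c("healthy", "intermediate", "poor"))
  z <- rnorm(n)
  lam0 <- 0.02
  b_int <- 0.3; b_poor <- 0.6; b_z <- 0.25
  lam <- lam0 * exp(b_int * (lc == "intermediate") + b_poor * (lc == "poor") + b_z * z)
  t_raw <- rexp(n, lam)
  horizon <- 10
  co <- data.frame(lifestyle_category = lc, pgs_z = z,
                   age_enroll = runif(n, 40, 70),
                   sex = sample(c("female", "male"), n, TRUE),
                   pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
                   obese_prev = 0L,
                   obesity_time = pmin(t_raw, horizon),
                   obesity_event = as.integer(t_raw <= horizon))
  model <- fit_risk_model(co)
  t_star <- 5
  for (grp in c("healthy", "poor")) {
    got <- absolute_risk_by_age(model, grp, 50,
                                target_age = model$mean_age + t_star)
    eta_true <- b_poor * (grp == "poor")  # z at median = 0, covariates null
    want <- 100 * (1 - exp(-lam0 * t_star * exp(eta_true)))
    expect_lt(abs(got - want) / want, 0.12)
  }
  # degenerate target age and percentile guards
  expect_error(absolute_risk_by_age(model, "poor", 50, target_age = 30), "not beyond")
  expect_error(absolute_risk_by_age(model, "poor", 0), "strictly in")
  expect_error(absolute_risk_by_age(model, "poor", 100), "strictly in")

  # age-as-timescale mode with delayed entry: the hazard is constant, so the
  # same closed form applies between the mean enrollment age and the target
  model_age <- fit_risk_model(co, timescale = "age")
  for (grp in c("healthy", "poor")) {
    got <- absolute_risk_by_age(model_age, grp, 50,
                                target_age = model_age$mean_age + t_star)
    eta_true <- b_poor * (grp == "poor")
    want <- 100 * (1 - exp(-lam0 * t_star * exp(eta_true)))
    expect_lt(abs(got - want) / want, 0.12)
  }
})

test_that("risk is nondecreasing in the PGS percentile when its effect is positive", {
  co <- scored_cohort(n = 50000, seed = 421)
  model <- fit_risk_model(co)
  expect_gt(coef(model$fit)[["pgs_z"]], 0)
  risks <- absolute_risk_by_age(model, "poor", seq(5, 95, by = 5))
  expect_true(all(diff(risks) >= 0))
})

test_that("risk curve differences are zero iff the lifestyle effect is zero", {
  co <- scored_cohort(n = 50000, seed = 421)
  model <- fit_risk_model(co)
  curve <- risk_gradient_curve(model, percentiles = seq(5, 95, 5))
  expect_equal(curve$difference, curve$poor - curve$healthy)
  expect_true(all(curve$difference > 0))
  # widening on the absolute scale with no interaction term in the model
  expect_gt(curve$difference[nrow(curve)], curve$difference[1])
  # zero out the lifestyle coefficients: difference becomes identically 0
  null_model <- model
  lt <- grep("lifestyle_category", names(null_model$fit$coef))
  null_model$fit$coef[lt] <- 0
  curve0 <- risk_gradient_curve(null_model, percentiles = seq(5, 95, 5))
  expect_true(all(abs(curve0$difference) < 1e-12))
})

test_that("the stored Breslow baseline is a nondecreasing step function", {
  co <- scored_cohort(n = 20000, seed = 1009)
  model <- fit_risk_model(co)
  bh <- model$basehaz
  expect_true(all(bh$hazard >= 0))
  expect_true(all(diff(bh$hazard) >= 0))
  sub <- co[gxlife:::analysis_rows(co, "incident"), ]
  expect_true(all(bh$time %in% sub$obesity_time))
})
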