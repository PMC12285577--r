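test_that("RERI from three relative risks follows the defining arithmetic", {
  expect_equal(reri_binary(4, 2, 2), 1)
  expect_equal(reri_binary(1, 1, 1), 0)
  # exact additivity: RR11 = RR10 + RR01 - 1
  expect_equal(reri_binary(3.4, 2.2, 2.2), 0, tolerance = 1e-12)
  expect_error(reri_binary(0, 1, 1), "positive")
  expect_error(reri_binary(2, -1, 1), "positive")
})

test_that("continuous RERI reproduces the four-corner formula exactly", {
  fit <- structure(list(coef = c(pgs_z = 0.5, lifestyle_score = 0.3,
                                 `pgs_z:lifestyle_score` = 0.2)),
                   class = "gxe_fit")
  contrast <- list(g = c(0, 1), l = c(0, 1))
  dec <- reri_continuous(fit, contrast)
  expect_equal(dec$RERI, exp(1.0) - exp(0.5) - exp(0.3) + 1, tolerance = 1e-12)
  expect_equal(dec$RR11, exp(1.0), tolerance = 1e-12)
  # zero product coefficient: RERI is the pure curvature term
  fit0 <- structure(list(coef = c(pgs_z = 0.5, lifestyle_score = 0.3,
                                  `pgs_z:lifestyle_score` = 0)),
                    class = "gxe_fit")
  dec0 <- reri_continuous(fit0, contrast)
  expect_equal(dec0$RERI, (exp(0.5) - 1) * (exp(0.3) - 1), tolerance = 1e-12)
  expect_gt(dec0$RERI, 0)
  # label symmetry: swapping the exposures and their contrasts changes nothing
  fit_sw <- structure(list(coef = c(lifestyle_score = 0.5, pgs_z = 0.3,
                                    `pgs_z:lifestyle_score` = 0.2)),
                      class = "gxe_fit")
  dec_sw <- reri_continuous(fit_sw, list(g = c(0, 1), l = c(0, 1)),
                            g_term = "lifestyle_score", l_term = "pgs_z")
  expect_equal(dec_sw$RERI, dec$RERI, tolerance = 1e-12)
  # general (non-unit) contrast against a hand-computed linear predictor
  ct <- list(g = c(-1.4, 1.4), l = c(4.5, 0.5))
  d2 <- reri_continuous(fit, ct)
  rr <- function(g, l) exp(0.5 * (g + 1.4) + 0.3 * (l - 4.5) +
                             0.2 * (g * l - (-1.4) * 4.5))
  expect_equal(d2$RERI, rr(1.4, 0.5) - rr(1.4, 4.5) - rr(-1.4, 0.5) + 1,
               tolerance = 1e-12)
})

test_that("attributable proportions decompose the joint excess and sum to one", {
  ap <- decompose(5, 3, 2)
  expect_equal(ap$AP_G, 0.5)
  expect_equal(ap$AP_L, 0.25)
  expect_equal(ap$AP_I, 0.25)
  set.seed(123)
  for (i in 1:25) {
    rr10 <- runif(1, 0.5, 4); rr01 <- runif(1, 0.5, 4)
    rr11 <- runif(1, 1.01, 8)
    ap <- decompose(rr11, rr10, rr01)
    expect_equal(ap$AP_G + ap$AP_L + ap$AP_I, 1, tolerance = 1e-12)
  }
  expect_error(decompose(0.9, 1.2, 1.1), "undefined")
})

test_that("binary and continuous RERI agree on 0/1 coded exposures", {
  set.seed(515)
  n <- 50000
  g <- rbinom(n, 1, 0.3); l <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-2 + 0.8 * g + 0.5 * l + 0.3 * g * l))
  d <- data.frame(pgs_z = g, lifestyle_score = l, y = y)
  fit <- fit_logistic(d, "y", c("pgs_z", "lifestyle_score",
                                "pgs_z:lifestyle_score"))
  dec <- reri_continuous(fit, list(g = c(0, 1), l = c(0, 1)))
  # independent route: odds ratios from the saturated four-cell model
  d$cell <- factor(paste0(g, l), levels = c("00", "10", "01", "11"))
  cf <- coef(fit_logistic(d, "y", "cell"))
  rr10 <- exp(cf[["cell10"]]); rr01 <- exp(cf[["cell01"]]); rr11 <- exp(cf[["cell11"]])
  expect_equal(dec$RERI, reri_binary(rr11, rr10, rr01), tolerance = 1e-6)
  expect_equal(dec$RR11, rr11, tolerance = 1e-6)
})

test_that("the product-term Wald test detects a generative interaction", {
  for (s in 1:3) {
    cfg <- sim_config(n_participants = 20000, seed = 3300 + s,
                      beta_interaction = 0.1, n_orm = 0)
    co <- scored_cohort(n = 20000, seed = 3300 + s, config = cfg,
                        with_orm = FALSE)
    mt <- multiplicative_test(co)
    expect_true(mt$estimable)
    expect_lt(mt$p, 0.001)
  }
})

test_that("a degenerate product term is flagged non-estimable", {
  co <- scored_cohort(n = 2000, seed = 6, with_orm = FALSE)
  co$lifestyle_score <- 3  # constant: product collinear with the main term
  mt <- multiplicative_test(co, covariates = character(0))
  expect_false(mt$estimable)
  expect_true(is.na(mt$p))
})

test_that("RERI is centered at zero under the fully null generative model", {
  reris <- vapply(1:200, function(i) {
    cfg <- sim_config(n_participants = 5000, seed = 9000 + i,
                      beta_pgs = 0, beta_lifestyle = 0, beta_interaction = 0,
                      n_orm = 0)
    co <- generate_cohort(cfg)
    co <- add_genetic_risk(co)
    co <- add_lifestyle(co)
    fit <- fit_logistic(co, "obese_prev",
                        c("pgs_z", "lifestyle_score", "pgs_z:lifestyle_score"))
    reri_continuous(fit, default_contrast(co))$RERI
  }, numeric(1))
  mc_se <- sd(reris) / sqrt(length(reris))
  expect_lt(abs(mean(reris)), 3 * mc_se)
})

test_that("bootstrap intervals are deterministic and collapse on constants", {
  set.seed(41)
  d <- data.frame(x = rnorm(200, mean = 2))
  est <- function(dd) c(m = mean(dd$x))
  a <- bootstrap_ci(d, est, B = 100, seed = 7)
  b <- bootstrap_ci(d, est, B = 100, seed = 7)
  expect_identical(a$ci, b$ci)
  c2 <- bootstrap_ci(d, est, B = 100, seed = 8)
  expect_false(identical(a$ci, c2$ci))
  dconst <- data.frame(x = rep(3, 50))
  cc <- bootstrap_ci(dconst, est, B = 100, seed = 1)
  expect_equal(unname(cc$ci[1, "lower"]), 3)
  expect_equal(unname(cc$ci[1, "upper"]), 3)
  expect_error(bootstrap_ci(d, est, B = 50, seed = 1), "at least 100")
  # persistent estimator failure on resamples is reported, not absorbed:
  # this estimator rejects the tied rows every resample of 10 contains
  flaky <- function(dd) {
    if (any(duplicated(dd$x))) stop("ties")
    c(m = mean(dd$x))
  }
  expect_error(bootstrap_ci(data.frame(x = rnorm(10)), flaky, B = 100, seed = 2),
               "resamples failed")
})

test_that("the full interaction analysis attaches coherent intervals", {
  co <- scored_cohort(n = 20000, seed = 1009)
  dec <- gxe_interaction(co, ci = "delta")
  expect_s3_class(dec, "gxe_decomposition")
  expect_equal(dec$AP_G + dec$AP_L + dec$AP_I, 1, tolerance = 1e-12)
  expect_equal(dec$RERI, dec$RR11 - dec$RR10 - dec$RR01 + 1, tolerance = 1e-12)
  expect_true(all(c("RERI", "AP_G", "AP_L", "AP_I") %in% rownames(dec$ci)))
  expect_true(all(dec$ci[, "lower"] <= dec$ci[, "estimate"] + 1e-12))
  expect_true(all(dec$ci[, "upper"] >= dec$ci[, "estimate"] - 1e-12))
  # bootstrap route on a subsample, deterministic given the seed
  sub <- co[1:4000, ]
  b1 <- gxe_interaction(sub, ci = "bootstrap", B = 100, seed = 3,
                        covariates = c("age_enroll", "sex"))
  b2 <- gxe_interaction(sub, ci = "bootstrap", B = 100, seed = 3,
                        covariates = c("age_enroll", "sex"))
  expect_identical(b1$ci, b2$ci)
  expect_equal(b1$B, 100)
})

test_that("decomposition serializes to JSON and TSV", {
  co <- scored_cohort(n = 20000, seed = 1009)
  dec <- gxe_interaction(co, ci = "none")
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_decomposition(dec, fj, ft)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$RERI, dec$RERI, tolerance = 1e-12)
  expect_equal(back$AP_G + back$AP_L + back$AP_I, 1, tolerance = 1e-10)
  tab <- read.delim(ft)
  expect_equal(tab$RR11, dec$RR11, tolerance = 1e-10)
})
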