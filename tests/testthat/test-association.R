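test_that("percentage-change rescaling is exactly 100/1.1 on estimate and CI", {
  set.seed(42)
  n <- 500
  d <- data.frame(adherence = NA, x = rbinom(n, 1, 0.4),
                  year_of_birth = sample(1940:1980, n, TRUE))
  d$adherence <- 0.9 + 0.011 * d$x + rnorm(n, 0, 0.04)
  fit <- fit_adherence(d, "x")
  r <- fit$results[fit$results$term == "x", ]
  expect_equal(r$pct_change, 100 * r$estimate / 1.1, tolerance = 1e-12)
  lmfit <- fit$fit
  ci <- confint(lmfit)["x", ]
  expect_equal(c(r$ci_low, r$ci_high), unname(100 * ci / 1.1),
               tolerance = 1e-9)
  # a ~0.011 MPR-scale coefficient reads as ~1% change in adherence
  expect_equal(r$pct_change, 1.0, tolerance = 0.5)
})

test_that("logistic and linear fits recover injected effects on a synthetic cohort", {
  cfg <- sim_config(
    n_persons = 20000, seed = 2024,
    covariate_effects = list(
      social_assistance = c(adherence_effect = -0.03,
                            persistence_logodds_effect = -0.5)),
    covariate_prevalences = c(social_assistance = 0.3))
  d <- analysis_table(cfg)
  fa <- fit_adherence(d, "social_assistance")
  ra <- fa$results[fa$results$term == "social_assistance", ]
  expect_true(ra$ci_low < 100 * (-0.03) / 1.1 &&
                100 * (-0.03) / 1.1 < ra$ci_high)
  fp <- fit_persistence(d, "social_assistance")
  rp <- fp$results[fp$results$term == "social_assistance", ]
  expect_true(rp$ci_low < exp(-0.5) && exp(-0.5) < rp$ci_high)
  expect_true(rp$p_value < 0.05)
})

test_that("degenerate inputs are rejected or flagged", {
  d <- data.frame(persistence_primary = rep("persistent", 50),
                  x = rbinom(50, 1, 0.5), year_of_birth = 1950)
  expect_error(fit_persistence(d, "x"), "single class")
  expect_error(fit_adherence(data.frame(adherence = numeric(),
                                        x = numeric(),
                                        year_of_birth = numeric()), "x"),
               "no rows")
  # collinear design: duplicated predictor is flagged, not silent
  set.seed(9)
  dd <- data.frame(adherence = runif(100, 0.5, 1.1),
                   x = rbinom(100, 1, 0.5),
                   year_of_birth = sample(1940:1980, 100, TRUE))
  dd$x2 <- dd$x
  expect_warning(f <- fit_adherence(dd, c("x", "x2")), "collinear")
  expect_false(f$converged)
})

test_that("fit results are invariant to row and covariate order", {
  cfg <- sim_config(n_persons = 2000, seed = 77,
                    covariate_effects = list(
                      social_assistance = c(adherence_effect = -0.03,
                                            persistence_logodds_effect = 0)),
                    covariate_prevalences = c(social_assistance = 0.3,
                                              urban = 0.7))
  d <- analysis_table(cfg)
  f1 <- fit_adherence(d, c("social_assistance", "urban"))
  f2 <- fit_adherence(d[sample(nrow(d)), ], c("urban", "social_assistance"))
  r1 <- f1$results[order(f1$results$term), ]
  r2 <- f2$results[order(f2$results$term), ]
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("variance explained: null and near-deterministic limits", {
  set.seed(5)
  n <- 400
  d <- data.frame(x = rnorm(n), year_of_birth = sample(1940:1980, n, TRUE))
  d$adherence <- 0.9 + rnorm(n, 0, 0.05)          # null
  ve0 <- variance_explained(fit_adherence(d, "x"))
  expect_lt(abs(as.numeric(ve0)), 0.02)
  d$adherence <- 0.6 + 0.05 * d$x + rnorm(n, 0, 1e-6)  # fully determined
  ve1 <- variance_explained(fit_adherence(d, "x"))
  expect_gt(as.numeric(ve1), 0.999)
  # logistic null model: McFadden 0
  y <- rbinom(n, 1, 0.6)
  null_fit <- glm(y ~ 1, family = binomial())
  expect_equal(as.numeric(variance_explained(null_fit)), 0, tolerance = 1e-9)
  expect_equal(attr(variance_explained(null_fit), "label"),
               "McFadden pseudo-R2")
})

test_that("categorical phenotypes: suppression below five, two-level consistency", {
  cfg <- sim_config(n_persons = 3000, seed = 313)
  d <- analysis_table(cfg)
  set.seed(1)
  d$metab <- sample(c("normal", "intermediate", "poor"), nrow(d), TRUE,
                    prob = c(0.85, 0.12, 0.03))
  d$metab[d$metab == "poor"][-(1:3)] <- "normal"  # force a tiny level
  expect_message(
    f <- fit_categorical_phenotype(d, "metab", reference = "normal"),
    "suppressing")
  expect_true("poor" %in% f$suppressed_levels)
  expect_false(any(grepl("poor", f$results$term)))

  # a two-level factor reduces to the plain logistic fit on an indicator
  d$bin <- ifelse(d$metab == "intermediate", "intermediate", "normal")
  f2 <- fit_categorical_phenotype(d, "bin", reference = "normal")
  d$ind <- as.integer(d$bin == "intermediate")
  f3 <- fit_persistence(d, "ind")
  expect_equal(f2$results$estimate[grepl("intermediate", f2$results$term)],
               f3$results$estimate[f3$results$term == "ind"],
               tolerance = 1e-9)
  expect_error(fit_categorical_phenotype(d, "metab", reference = "ultrarapid"),
               "reference level absent")
})

test_that("analytic power: identities, monotonicity, printed-scale value", {
  expect_equal(gwas_power(1000, 0.3, 0, 0.118, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  expect_error(gwas_power(100, 1.2, 0.1, 1), "maf")
  expect_error(gwas_power(100, 0.3, 0.1, 0), "trait_sd")
  # monotone in n, |beta|, and maf(1-maf)
  p <- function(...) gwas_power(..., alpha = 5e-8)
  expect_lt(p(n = 500, maf = 0.3, beta = 0.027, trait_sd = 0.118),
            p(n = 5000, maf = 0.3, beta = 0.027, trait_sd = 0.118))
  expect_lt(p(n = 500, maf = 0.3, beta = 0.02, trait_sd = 0.118),
            p(n = 500, maf = 0.3, beta = 0.03, trait_sd = 0.118))
  expect_lt(p(n = 500, maf = 0.05, beta = 0.027, trait_sd = 0.118),
            p(n = 500, maf = 0.3, beta = 0.027, trait_sd = 0.118))
  expect_lt(p(n = 500, maf = 0.3, beta = -0.027, trait_sd = 0.118) -
              p(n = 500, maf = 0.3, beta = 0.027, trait_sd = 0.118), 1e-12)
})

test_that("null covariates keep nominal coverage in the logistic model", {
  # small-scale coverage check: 40 replicates, a covariate independent of
  # the outcome; the 95% CI should cover OR = 1 in the vast majority
  cover <- 0L
  for (s in 1:40) {
    cfg <- sim_config(n_persons = 1500, seed = 9000 + s)
    d <- analysis_table(cfg)
    f <- fit_persistence(d, "urban")
    r <- f$results[f$results$term == "urban", ]
    if (r$ci_low <= 1 && 1 <= r$ci_high) cover <- cover + 1L
  }
  expect_gte(cover, 35L)
})
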