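test_that("identical seed gives byte-identical registers", {
  cfg <- sim_config(n_persons = 120, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$purchases, b$purchases)
  expect_identical(a$persons, b$persons)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$groundtruth, b$groundtruth)
  c2 <- simulate_cohort(sim_config(n_persons = 120, seed = 100))
  expect_false(identical(a$purchases, c2$purchases))
})

test_that("configuration is validated", {
  expect_error(sim_config(n_persons = 10), "seed")
  expect_error(sim_config(n_persons = 10, seed = 1,
                          archetype_mix = c(regular = 0.7)), "sum to 1")
  expect_error(sim_config(n_persons = 10, seed = 1,
                          archetype_mix = c(couch_potato = 1)), "archetype")
  expect_error(sim_config(n_persons = 10, seed = 1,
                          study_start = "2020-01-01",
                          study_end = "2010-01-01"), "precede")
  expect_error(sim_config(n_persons = 10, seed = 1,
                          covariate_effects = list(
                            wealth = c(adherence_effect = 0.1)),
                          covariate_prevalences = c(urban = 0.5)),
               "prevalence")
})

test_that("degenerate mix: pure early discontinuers make one purchase each", {
  cfg <- sim_config(n_persons = 100, seed = 3,
                    archetype_mix = c(early_discontinuer = 1))
  coh <- simulate_cohort(cfg)
  counts <- table(coh$purchases$person_id)
  expect_equal(length(counts), 100L)
  expect_true(all(counts == 1L))
})

test_that("archetypes are recovered by the phenotyping stage", {
  rs <- adherence_ruleset()
  one_arch <- function(name, n = 200, seed = 17) {
    mix <- setNames(1, name)
    coh <- simulate_cohort(sim_config(n_persons = n, seed = seed,
                                      archetype_mix = mix))
    build_phenotypes(coh$purchases, coh$persons, coh$diagnoses,
                     "statins", rs)
  }
  # stockpilers: dense cadence pushes the MPR over the cap
  st <- one_arch("stockpiler")
  expect_gte(mean(st$adherence_excluded_reason == "mpr_above_cap"), 0.95)
  # break takers: at least one excluded break purchase, still eligible
  coh <- simulate_cohort(sim_config(n_persons = 200, seed = 18,
                                    archetype_mix = c(break_taker = 1)))
  traj <- adherekit:::traj_engine(
    data.table::as.data.table(coh$purchases), rs)
  broke <- traj[, any(reason == "break"), by = person_id]$V1
  expect_gte(mean(broke), 0.95)
  # early discontinuers: non-persistent whenever censoring allows
  ed <- one_arch("early_discontinuer")
  allow <- ed$persistence_primary != "excluded_censored"
  expect_gte(mean(ed$persistence_primary[allow] == "non_persistent"), 0.95)
  # short courses stop within a year
  sc <- one_arch("short_course")
  expect_gte(mean(sc$persistence_sensitivity[
    sc$persistence_sensitivity != "excluded_censored"] == "non_persistent"),
    0.95)
  # switchers: the engine records truncated supply at the switch
  cohs <- simulate_cohort(sim_config(n_persons = 200, seed = 19,
                                     archetype_mix = c(switcher = 1)))
  trs <- adherekit:::traj_engine(
    data.table::as.data.table(cohs$purchases), rs)
  truncated <- trs[, any(effective_tablets < tablets), by = person_id]$V1
  expect_gte(mean(truncated), 0.95)
})

test_that("latent adherence targets are realized by the refill mechanism", {
  cfg <- sim_config(n_persons = 400, seed = 23,
                    archetype_mix = c(regular = 1))
  coh <- simulate_cohort(cfg)
  ph <- build_phenotypes(coh$purchases, coh$persons, coh$diagnoses,
                         "statins", adherence_ruleset())
  m <- merge(ph, coh$groundtruth, by = "person_id")
  m <- m[m$adherence_eligible, ]
  expect_gt(cor(m$adherence, m$target_mpr), 0.9)
  expect_lt(mean(abs(m$adherence - m$target_mpr)), 0.03)
})

test_that("diagnosis simulation: prevention fraction bounds and CCI burden", {
  base <- sim_config(n_persons = 300, seed = 5,
                     secondary_prevention_fraction = 0, cci_burden = 0)
  coh0 <- simulate_cohort(base)
  expect_equal(nrow(coh0$diagnoses), 0L)

  all_sp <- sim_config(n_persons = 300, seed = 5,
                       secondary_prevention_fraction = 1, cci_burden = 0)
  coh1 <- simulate_cohort(all_sp)
  codes <- medication_codelist("statins")
  got <- vapply(split(coh1$diagnoses, coh1$diagnoses$person_id),
                function(d) any(adherekit:::icd10_matches(d$icd10, codes)),
                logical(1))
  expect_equal(sum(got), 300L)
  # every qualifying code precedes the first purchase
  first <- coh1$groundtruth$first_purchase_date[
    match(coh1$diagnoses$person_id, coh1$groundtruth$person_id)]
  expect_true(all(as.Date(coh1$diagnoses$date) < first))

  # expected Charlson index equals the configured burden
  burden <- 2
  cfg <- sim_config(n_persons = 5000, seed = 6,
                    secondary_prevention_fraction = 0, cci_burden = burden)
  coh <- simulate_cohort(cfg)
  cci <- vapply(split(coh$diagnoses$icd10, coh$diagnoses$person_id),
                compute_cci, integer(1))
  cci_all <- c(cci, rep(0L, 5000 - length(cci)))
  se <- sd(cci_all) / sqrt(length(cci_all))
  expect_lt(abs(mean(cci_all) - burden), 3 * se)

  expect_error(sim_config(n_persons = 10, seed = 1,
                          secondary_prevention_fraction = 1.5))
})

test_that("dose-distribution persons are emitted flagged and excluded downstream", {
  cfg <- sim_config(n_persons = 300, seed = 8,
                    dose_distribution_fraction = 0.2)
  coh <- simulate_cohort(cfg)
  dd <- unique(coh$purchases$person_id[coh$purchases$dose_distribution == 1])
  expect_gt(length(dd), 20)
  ph <- build_phenotypes(coh$purchases, coh$persons, coh$diagnoses,
                         "statins", adherence_ruleset())
  expect_false(any(dd %in% ph$person_id))
  excl <- attr(ph, "exclusions")
  expect_equal(excl$count[excl$reason == "only_dose_distribution"],
               length(dd))
})

test_that("register round-trips through CSV exactly", {
  coh <- simulate_cohort(sim_config(n_persons = 50, seed = 12,
                                    death_fraction = 0.2,
                                    emigration_fraction = 0.1))
  dir <- tempfile("reg")
  write_register(coh, dir)
  back <- read_register(dir)
  for (nm in c("purchases", "diagnoses", "persons"))
    expect_equal(back[[nm]], coh[[nm]], ignore_attr = TRUE)
  expect_equal(back$groundtruth$target_mpr, coh$groundtruth$target_mpr)

  # empty purchase table: header-only file still round-trips
  empty <- coh
  empty$purchases <- coh$purchases[0, ]
  dir2 <- tempfile("reg")
  write_register(empty, dir2)
  expect_equal(nrow(read_register(dir2)$purchases), 0L)

  # schema violations
  bad <- coh
  bad$purchases$n_packages[1] <- -1L
  expect_error(write_register(bad, tempfile()), "negative")
  bad2 <- coh
  bad2$purchases$date <- NULL
  expect_error(write_register(bad2, tempfile()), "missing required column")
})
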