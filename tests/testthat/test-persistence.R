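rs <- adherence_ruleset()
reg_end <- as.Date("2020-01-01")

single <- function(date, n_packages = 1L, tablets = 100) {
  data.frame(person_id = "p1", date = as.Date(date), atc = "C10AA01",
             n_packages = n_packages, tablets = tablets)
}

test_that("primary: a single purchase well before end of follow-up is non-persistent", {
  expect_equal(classify_persistence_primary(single("2015-01-01"), rs, reg_end),
               "non_persistent")
  # inside the 2-year buffer: censored, a later refill cannot be ruled out
  expect_equal(classify_persistence_primary(single("2019-06-01"), rs, reg_end),
               "excluded_censored")
  # exactly 730 days before end of follow-up still counts
  expect_equal(classify_persistence_primary(single(reg_end - 730), rs,
                                            reg_end),
               "non_persistent")
  expect_equal(classify_persistence_primary(single(reg_end - 729), rs,
                                            reg_end),
               "excluded_censored")
})

test_that("primary: persistent requires adherence eligibility; intermediates are excluded", {
  p <- purchase_days(c(0, 100, 200, 300, 400))
  expect_equal(classify_persistence_primary(p, rs, reg_end), "persistent")
  # two purchases only 200 days apart: neither persistent nor discontinuing
  p2 <- purchase_days(c(0, 200))
  expect_equal(classify_persistence_primary(p2, rs, reg_end),
               "excluded_intermediate")
  # stockpiler: above the MPR cap, excluded from both sides of the contrast
  dense <- purchase_days(seq(0, 400, by = 50))
  expect_equal(classify_persistence_primary(dense, rs, reg_end),
               "excluded_intermediate")
})

test_that("EstBB dialect restricts the single discontinuation purchase", {
  est <- adherence_ruleset("estbb")
  # 3 packages: not countable as early discontinuation
  expect_equal(classify_persistence_primary(
    single("2015-01-01", n_packages = 3L, tablets = 90), est, reg_end),
    "excluded_intermediate")
  # 100 tablets: not countable either (must be < 100)
  expect_equal(classify_persistence_primary(
    single("2015-01-01", n_packages = 1L, tablets = 100), est, reg_end),
    "excluded_intermediate")
  ok <- single("2015-01-01", n_packages = 2L, tablets = 90)
  expect_equal(classify_persistence_primary(ok, est, reg_end),
               "non_persistent")
  # purchase after the dialect censoring date
  late <- single("2022-06-01", n_packages = 1L, tablets = 30)
  expect_equal(classify_persistence_primary(late, est,
                                            as.Date("2023-03-28")),
               "excluded_censored")
  # death within a year of the purchase
  expect_equal(classify_persistence_primary(
    ok, est, as.Date("2015-06-01"), death_date = as.Date("2015-06-01")),
    "excluded_censored")
})

test_that("sensitivity: stopping within a year is non-persistent regardless of purchase count", {
  p <- purchase_days(c(0, 90, 180))
  expect_equal(classify_persistence_sensitivity(p, rs, reg_end),
               "non_persistent")
  expect_equal(classify_persistence_sensitivity(purchase_days(c(0, 400)),
                                                rs, reg_end),
               "persistent")
  # overbuying is not excluded here
  dense <- purchase_days(seq(0, 400, by = 50))
  expect_equal(classify_persistence_sensitivity(dense, rs, reg_end),
               "persistent")
  # first purchase inside the one-year observability window
  late <- single("2019-10-01")
  expect_equal(classify_persistence_sensitivity(late, rs, reg_end),
               "excluded_censored")
})

test_that("missing end of follow-up is an error", {
  expect_error(classify_persistence_primary(single("2015-01-01"), rs,
                                            as.Date(NA)),
               "end_of_followup")
})

test_that("cohort filters: age, sex and prerequisite diagnoses", {
  persons <- data.frame(
    person_id = c("a", "b", "c"),
    sex = c("male", "female", "female"),
    birth_date = as.Date(c("1990-01-01", "1950-01-01", "2000-06-01")),
    death_date = as.Date(NA), emigration_date = as.Date(NA))
  pur <- data.frame(
    person_id = c("a", "b", "c"),
    date = as.Date(c("2012-01-01", "2012-01-01", "2012-01-01")),
    atc = "L02BA01", n_packages = 1L, tablets_per_package = 100L,
    dose_distribution = 0L)
  dia <- data.frame(person_id = "b", date = as.Date("2010-05-05"),
                    icd10 = "C50")
  ph <- build_phenotypes(pur, persons, dia, "breast_cancer", rs)
  # male excluded, minor excluded, undiagnosed excluded
  expect_equal(ph$person_id, "b")
  excl <- attr(ph, "exclusions")
  expect_setequal(excl$reason, c("age_below_18", "not_female"))
  expect_equal(sum(excl$count) + nrow(ph), attr(ph, "n_persons_in"))

  # DOAC requires a prior qualifying diagnosis
  pur$atc <- "B01AF01"
  persons$birth_date[3] <- as.Date("1960-01-01")
  dia2 <- data.frame(person_id = c("a", "b"),
                     date = as.Date(c("2011-01-01", "2013-01-01")),
                     icd10 = c("I48", "I48"))
  ph2 <- build_phenotypes(pur, persons, dia2, "doac", rs)
  # b's diagnosis is after the first purchase; only a qualifies
  expect_equal(ph2$person_id, "a")
})

test_that("antiplatelets: persistence marked not applicable, adherence kept", {
  pur <- data.frame(person_id = "p", date = as.Date("2012-01-01") +
                      c(0, 100, 200, 300, 400),
                    atc = "B01AC04", n_packages = 1L,
                    tablets_per_package = 100L, dose_distribution = 0L)
  persons <- data.frame(person_id = "p", sex = "male",
                        birth_date = as.Date("1950-01-01"),
                        death_date = as.Date(NA),
                        emigration_date = as.Date(NA))
  ph <- build_phenotypes(pur, persons, NULL, "antiplatelets", rs)
  expect_equal(ph$persistence_primary, "not_applicable")
  expect_true(ph$adherence_eligible)
})

test_that("persistence statuses partition the cohort", {
  coh <- random_trajectory_cohort(300, seed = 31)
  ph <- build_phenotypes(coh$purchases, coh$persons, coh$diagnoses,
                         "statins", rs)
  expect_true(all(ph$persistence_primary %in%
                    c("persistent", "non_persistent", "excluded_censored",
                      "excluded_intermediate")))
  expect_equal(nrow(ph) + sum(attr(ph, "exclusions")$count),
               attr(ph, "n_persons_in"))
  # persistent implies adherence-eligible; adherence only when eligible
  expect_true(all(ph$adherence_eligible[ph$persistence_primary ==
                                          "persistent"]))
  expect_true(all(is.na(ph$adherence) == !ph$adherence_eligible))
  expect_true(all(ph$adherence[!is.na(ph$adherence)] <= rs$mpr_cap))
})
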