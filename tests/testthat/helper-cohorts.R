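# Joined phenotype + covariate analysis table straight from a simulated
# cohort, using the generator's own covariates (ground truth) rather than the
# derived ones — the fast path for model-calibration experiments.
analysis_table <- function(cfg, dialect = "finregistry") {
  coh <- simulate_cohort(cfg)
  ph <- build_phenotypes(coh$purchases, coh$persons, coh$diagnoses,
                         cfg$medication_class, adherence_ruleset(dialect),
                         registry_end = cfg$study_end)
  d <- merge(ph, coh$persons, by = "person_id")
  d$year_of_birth <- as.integer(format(as.Date(d$birth_date), "%Y"))
  d
}

# Monte-Carlo power oracle: simulate Wald tests of the additive single-variant
# model directly (genotype ~ Binomial(2, maf), trait = beta * g + noise)
mc_gwas_power <- function(n, maf, beta, trait_sd, alpha, n_sim, seed) {
  set.seed(seed)
  resid_sd <- sqrt(max(trait_sd^2 - 2 * maf * (1 - maf) * beta^2, 1e-12))
  hits <- 0L
  for (s in seq_len(n_sim)) {
    g <- rbinom(n, 2L, maf)
    y <- beta * g + rnorm(n, 0, resid_sd)
    sxx <- sum((g - mean(g))^2)
    if (sxx == 0) next
    b <- sum((g - mean(g)) * y) / sxx
    res <- y - mean(y) - b * (g - mean(g))
    se <- sqrt(sum(res^2) / (n - 2) / sxx)
    if ((b / se)^2 > qchisq(1 - alpha, 1)) hits <- hits + 1L
  }
  hits / n_sim
}
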