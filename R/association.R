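# ---------------------------------------------------------------------------
# Multivariable association models.
#
# Persistence: maximum-likelihood logistic regression, effects reported as
# odds ratios with Wald 95% CIs and two-sided p-values from the normal
# reference. Adherence: ordinary least squares on the MPR scale, coefficients
# rescaled by 100/1.1 to the percentage change in adherence (1.1 is the
# maximum admissible adherence value), CIs rescaled identically, p-values
# from the t reference. No multiplicity adjustment.
# ---------------------------------------------------------------------------

assoc_terms <- function(data, covariate_names, outcome) {
  miss <- setdiff(c(outcome, covariate_names), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  # constant predictors (e.g. secondary prevention in cohorts where inclusion
  # makes it always true) carry no information and break the fit
  keep <- vapply(covariate_names, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))
  dropped <- covariate_names[!keep]
  list(terms = covariate_names[keep], dropped_constant = dropped)
}

new_assoc_fit <- function(subclass, fit, results, outcome, n, ve, converged,
                          dropped = character(), suppressed = NULL) {
  structure(list(results = results, fit = fit, outcome = outcome, n = n,
                 variance_explained = ve, converged = converged,
                 dropped_constant = dropped,
                 suppressed_levels = suppressed,
                 call = sys.call(-1)),
            class = c(subclass, "assoc_fit"))
}

#' Fit the multivariable persistence model
#'
#' Logistic regression of persistence (persistent vs non-persistent; persons
#' with excluded statuses are dropped) on the supplied covariates, always
#' adjusting for year of birth. Effects are reported as odds ratios with Wald
#' 95% confidence intervals and two-sided p-values from the standard normal
#' reference (coefficient / SE); the model's McFadden pseudo-R-squared is
#' attached.
#'
#' @param data a joined phenotype + covariate `data.frame`.
#' @param covariates character vector of covariate column names to test.
#' @param outcome `"persistence_primary"` or `"persistence_sensitivity"` (a
#'   status column), or the name of a 0/1 column.
#' @param adjust columns always included but still reported (default
#'   `"year_of_birth"`).
#' @return An object of class `c("persistence_fit", "assoc_fit")`: fields
#'   `results` (term, estimate = log-odds, odds_ratio, ci_low, ci_high on the
#'   OR scale, p_value, n), `fit` (the underlying `glm`),
#'   `variance_explained` (McFadden), `converged`.
#' @examples
#' cfg <- sim_config(n_persons = 400, seed = 11,
#'                   covariate_effects = list(
#'                     social_assistance = c(adherence_effect = 0,
#'                                           persistence_logodds_effect = -1)))
#' coh <- simulate_cohort(cfg)
#' ph <- build_phenotypes(coh$purchases, coh$persons, coh$diagnoses)
#' d <- merge(ph, coh$persons, by = "person_id")
#' d$year_of_birth <- as.integer(format(as.Date(d$birth_date), "%Y"))
#' fit <- fit_persistence(d, c("social_assistance", "urban"))
#' coef(fit)
#' @export
fit_persistence <- function(data, covariates,
                            outcome = "persistence_primary",
                            adjust = "year_of_birth") {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    keep <- y %in% c("persistent", "non_persistent")
    data <- data[keep, , drop = FALSE]
    ybin <- as.integer(y[keep] == "persistent")
  } else {
    keep <- !is.na(y)
    data <- data[keep, , drop = FALSE]
    ybin <- as.integer(y[keep])
  }
  if (length(unique(ybin)) < 2L)
    stop("outcome has a single class; cannot fit a logistic model")
  tt <- assoc_terms(data, unique(c(covariates, adjust)), outcome)
  data$.y <- ybin
  data <- data[complete.cases(data[, c(".y", tt$terms), drop = FALSE]), ,
               drop = FALSE]
  f <- as.formula(paste(".y ~", paste(tt$terms, collapse = " + ")))
  fit <- glm(f, data = data, family = binomial())
  converged <- isTRUE(fit$converged) &&
    all(abs(coef(fit)[-1]) < 15, na.rm = TRUE)  # crude separation guard
  if (!converged)
    warning("logistic fit did not converge cleanly (possible separation); ",
            "estimates flagged")
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  z <- est / se
  res <- data.frame(
    term = names(est),
    estimate = unname(est),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - qnorm(0.975) * se)),
    ci_high = exp(unname(est + qnorm(0.975) * se)),
    p_value = 2 * pnorm(-abs(unname(z))),
    n = nrow(data),
    row.names = NULL
  )
  ve <- variance_explained(fit)
  new_assoc_fit("persistence_fit", fit, res, outcome, nrow(data), ve,
                converged, dropped = tt$dropped_constant)
}

#' Fit the multivariable adherence model
#'
#' Ordinary least squares regression of adherence (MPR, in (0, 1.1]) on the
#' supplied covariates, adjusting for year of birth. Coefficients and their
#' Wald 95% confidence intervals are rescaled by 100/1.1 to the percentage
#' change in adherence (`pct_change`); p-values are two-sided from the t
#' reference. Adjusted R-squared is attached.
#'
#' @inheritParams fit_persistence
#' @param outcome name of the adherence column (default `"adherence"`); rows
#'   with missing adherence (ineligible persons) are dropped.
#' @return An object of class `c("adherence_fit", "assoc_fit")`: `results`
#'   has `term`, `estimate` (MPR-scale coefficient), `pct_change`, `ci_low`,
#'   `ci_high` (percentage scale), `p_value`, `n`.
#' @export
fit_adherence <- function(data, covariates, outcome = "adherence",
                          adjust = "year_of_birth") {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  data <- data[!is.na(y), , drop = FALSE]
  if (nrow(data) == 0L) stop("no rows with observed adherence")
  tt <- assoc_terms(data, unique(c(covariates, adjust)), outcome)
  data <- data[complete.cases(data[, c(outcome, tt$terms), drop = FALSE]), ,
               drop = FALSE]
  f <- as.formula(paste(outcome, "~", paste(tt$terms, collapse = " + ")))
  fit <- lm(f, data = data)
  est <- coef(fit)[-1]
  if (anyNA(est)) {
    warning("collinear design: some coefficients not estimable; flagged")
    converged <- FALSE
    est[is.na(est)] <- NA_real_
  } else converged <- TRUE
  se <- rep(NA_real_, length(est))
  ok <- !is.na(est)
  se[ok] <- sqrt(diag(vcov(fit)))[names(est)[ok]]
  dfree <- fit$df.residual
  tstat <- est / se
  scale <- 100 / 1.1
  res <- data.frame(
    term = names(est),
    estimate = unname(est),
    pct_change = scale * unname(est),
    ci_low = scale * unname(est - qt(0.975, dfree) * se),
    ci_high = scale * unname(est + qt(0.975, dfree) * se),
    p_value = 2 * pt(-abs(unname(tstat)), dfree),
    n = nrow(data),
    row.names = NULL
  )
  ve <- variance_explained(fit)
  new_assoc_fit("adherence_fit", fit, res, outcome, nrow(data), ve,
                converged, dropped = tt$dropped_constant)
}

#' Association of a categorical phenotype with persistence or adherence
#'
#' Fits the same logistic/linear machinery with one indicator per
#' non-reference level of a categorical predictor (e.g. metabolizer status
#' from an external star-allele caller). Levels observed in fewer than
#' `min_group` analysis rows are suppressed: their rows are dropped and the
#' level is recorded in `suppressed_levels` with no estimate emitted.
#'
#' @inheritParams fit_persistence
#' @param phenotype_column name of the categorical column.
#' @param reference reference level (e.g. normal function/metabolizer).
#' @param outcome outcome column, as in [fit_persistence()] /
#'   [fit_adherence()].
#' @param model `"logistic"` or `"linear"`.
#' @param min_group minimum analysis-set size per level (default 5).
#' @param adjust adjustment columns.
#' @return A `persistence_fit` or `adherence_fit`; `suppressed_levels` lists
#'   the levels removed for small counts.
#' @export
fit_categorical_phenotype <- function(data, phenotype_column,
                                      reference,
                                      outcome = "persistence_primary",
                                      model = c("logistic", "linear"),
                                      min_group = 5L,
                                      adjust = "year_of_birth") {
  model <- match.arg(model)
  x <- as.character(data[[phenotype_column]])
  if (is.null(x)) stop("phenotype column not found: ", phenotype_column)
  if (!reference %in% x) stop("reference level absent: ", reference)

  # the min-group rule applies to the analysis denominator
  if (model == "logistic") {
    yv <- as.character(data[[outcome]])
    in_analysis <- if (all(yv %in% c("0", "1"), na.rm = TRUE))
      !is.na(yv) else yv %in% c("persistent", "non_persistent")
  } else in_analysis <- !is.na(data[[outcome]])
  counts <- table(x[in_analysis])
  small <- names(counts)[counts < min_group]
  small <- setdiff(small, reference)
  if (length(small))
    message("suppressing level(s) with fewer than ", min_group,
            " individuals: ", paste(small, collapse = ", "))
  keep <- !x %in% small
  data <- data[keep, , drop = FALSE]
  data$.pheno <- stats::relevel(factor(x[keep]), ref = reference)

  fit <- if (model == "logistic")
    fit_persistence(data, ".pheno", outcome = outcome, adjust = adjust)
  else
    fit_adherence(data, ".pheno", outcome = outcome, adjust = adjust)
  fit$suppressed_levels <- small
  fit$results$term <- sub("^\\.pheno", paste0(phenotype_column, ":"),
                          fit$results$term)
  fit
}

#' Variance explained by a fitted model
#'
#' Adjusted R-squared for linear models; McFadden pseudo-R-squared
#' (1 - logLik(model)/logLik(null)) for logistic models. The label records
#' which statistic was used.
#'
#' @param fit an `lm`, `glm`, or `assoc_fit`.
#' @return Numeric with attribute `"label"`.
#' @export
variance_explained <- function(fit) {
  if (inherits(fit, "assoc_fit")) fit <- fit$fit
  if (inherits(fit, "glm")) {
    ll <- as.numeric(logLik(fit))
    null <- glm(fit$y ~ 1, family = binomial())
    ll0 <- as.numeric(logLik(null))
    out <- 1 - ll / ll0
    attr(out, "label") <- "McFadden pseudo-R2"
  } else if (inherits(fit, "lm")) {
    out <- summary(fit)$adj.r.squared
    attr(out, "label") <- "adjusted R2"
  } else stop("unsupported model class")
  out
}

# ------------------------------- S3 methods --------------------------------

#' @export
print.assoc_fit <- function(x, digits = 3, ...) {
  kind <- if (inherits(x, "persistence_fit")) "logistic (persistence)"
  else "linear (adherence)"
  cat("Multivariable", kind, "model, n =", x$n, "\n")
  eff <- if (inherits(x, "persistence_fit")) "odds_ratio" else "pct_change"
  res <- x$results
  res[-1] <- lapply(res[-1], function(v)
    if (is.numeric(v)) signif(v, digits) else v)
  print(res[, c("term", eff, "ci_low", "ci_high", "p_value")],
        row.names = FALSE)
  cat(sprintf("%s: %.4f\n", attr(x$variance_explained, "label"),
              as.numeric(x$variance_explained)))
  if (!x$converged) cat("WARNING: fit flagged as not cleanly converged\n")
  if (length(x$suppressed_levels))
    cat("suppressed levels:", paste(x$suppressed_levels, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.assoc_fit <- function(object, ...) {
  print(object, ...)
  invisible(object$results)
}

#' @export
coef.assoc_fit <- function(object, ...) {
  setNames(object$results$estimate, object$results$term)
}

#' @export
confint.assoc_fit <- function(object, parm, level = 0.95, ...) {
  res <- object$results
  ci <- cbind(res$ci_low, res$ci_high)
  rownames(ci) <- res$term
  colnames(ci) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.assoc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, ...)
  else predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.assoc_fit <- function(object, ...) residuals(object$fit, ...)

# ------------------------------ GWAS power ---------------------------------

#' Analytic power of a single-variant additive association test
#'
#' Power to detect an additive allelic effect `beta` on a quantitative trait
#' at significance level `alpha` in a sample of size `n`, assuming
#' Hardy-Weinberg genotype variance 2 maf (1 - maf). The Wald chi-square test
#' statistic (1 df) has noncentrality
#' `lambda = n * 2 * maf * (1 - maf) * (beta / trait_sd)^2`;
#' power is the upper-tail probability of the noncentral chi-square beyond
#' the central chi-square critical value. Covariate adjustment is ignored
#' (standardized-residual approximation).
#'
#' @param n sample size.
#' @param maf minor allele frequency, in (0, 1).
#' @param beta absolute allelic effect on the trait scale (e.g. MPR units).
#' @param trait_sd trait standard deviation (same scale as `beta`).
#' @param alpha significance level, default genome-wide 5e-8 (1e-8 is the
#'   other conventional threshold).
#' @return Power, in \[0, 1\]; equals `alpha` when `beta = 0`.
#' @examples
#' gwas_power(n = 116439, maf = 0.3, beta = 0.027, trait_sd = 0.118)
#' @export
gwas_power <- function(n, maf, beta, trait_sd, alpha = 5e-8) {
  if (!(n > 0)) stop("n must be positive")
  if (!(maf > 0 && maf < 1)) stop("maf must be in (0, 1)")
  if (!(trait_sd > 0)) stop("trait_sd must be positive")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  lambda <- n * 2 * maf * (1 - maf) * (beta / trait_sd)^2
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}
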