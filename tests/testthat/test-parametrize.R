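test_that("binomial GLM recovers generating parameters (per-genotype coding)", {
  truth <- true_mortality_params()
  d <- generate_mortality_dataset(truth, n_vials_per_genotype = 200,
                                  seed = 71)
  fit <- fit_mortality_glm(d, coding = "per_genotype")
  cf <- coef(fit$fit)
  se <- sqrt(diag(vcov(fit$fit)))
  for (g in GENOTYPES) {
    ic <- paste0("genotype", g)
    sc <- paste0("genotype", g, ":dose_ml")
    expect_lt(abs(cf[[ic]] - truth$intercepts[[g]]), 3 * se[[ic]])
    expect_lt(abs(cf[[sc]] - truth$slopes[[g]]), 3 * se[[sc]])
  }
  # determinism: refitting gives the identical likelihood
  refit <- fit_mortality_glm(d, coding = "per_genotype")
  expect_identical(as.numeric(logLik(fit)), as.numeric(logLik(refit)))
})

test_that("mortality GLM enforces preconditions and flags separation", {
  d <- generate_mortality_dataset(n_vials_per_genotype = 10, seed = 72)
  expect_error(fit_mortality_glm(d[0, ]), "empty")
  expect_error(fit_mortality_glm(d[d$genotype == "SR", ]), "2 genotypes")
  d1 <- d
  d1$dose_ml <- 1
  expect_error(fit_mortality_glm(d1), "identical")
  # all-dead genotype class: quasi-complete separation
  d2 <- d[d$genotype %in% c("SR", "ST"), ]
  d2$n_dead[d2$genotype == "SR"] <- d2$n_exposed[d2$genotype == "SR"]
  d2$n_dead[d2$genotype == "ST"] <- floor(d2$n_exposed[d2$genotype == "ST"] / 2)
  fit <- suppressWarnings(fit_mortality_glm(d2, coding = "per_genotype"))
  expect_true(fit$separation)
})

test_that("lrt_drop does the bookkeeping and rejects non-nested models", {
  d <- generate_mortality_dataset(n_vials_per_genotype = 30, seed = 73)
  full <- fit_mortality_glm(d) # sex + drive_class * dose_ml
  reduced <- fit_mortality_glm(
    d, formula = cbind(n_dead, n_alive) ~ sex + drive_class + dose_ml)
  res <- lrt_drop(full, reduced)
  expect_s3_class(res, "lrt_result")
  expect_equal(res$df, 2L) # interaction has 2 df
  expect_equal(res$dropped, "drive_class:dose_ml")
  expect_gte(res$chisq, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # identical models: chisq = 0, p = 1
  same <- lrt_drop(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt_drop(reduced, full), "not nested")
})

test_that("LRT statistic is invariant to factor coding", {
  d <- generate_mortality_dataset(n_vials_per_genotype = 30, seed = 74)
  fit_pair <- function() {
    full <- fit_mortality_glm(d)
    red <- fit_mortality_glm(
      d, formula = cbind(n_dead, n_alive) ~ sex + drive_class + dose_ml)
    lrt_drop(full, red)$chisq
  }
  old <- options(contrasts = c("contr.treatment", "contr.poly"))
  chi_treatment <- fit_pair()
  options(contrasts = c("contr.sum", "contr.poly"))
  chi_sum <- fit_pair()
  options(old)
  expect_equal(chi_treatment, chi_sum, tolerance = 1e-8)
})

test_that("dose-response curves equal fitted predictions to machine tolerance", {
  d <- generate_mortality_dataset(n_vials_per_genotype = 25, seed = 75)
  for (coding in c("drive_class", "per_genotype")) {
    fit <- fit_mortality_glm(d, coding = coding)
    curves <- build_dose_response(fit)
    expect_equal(nrow(curves), 5L)
    set.seed(76)
    doses <- runif(20, 0, 2.5)
    for (g in GENOTYPES) {
      want <- predict_mortality(fit, g, doses)$fit
      cur <- curves[curves$genotype == g, ]
      got <- plogis(cur$intercept + cur$slope * doses)
      expect_equal(got, want, tolerance = 1e-12)
      # dose 0 is the inverse-logit of the class's intercept combination
      expect_equal(death_prob(curves, 0)[[g]],
                   predict_mortality(fit, g, 0)$fit, tolerance = 1e-12)
      # logit-linearity: monotone whenever the class slope >= 0
      if (cur$slope >= 0) expect_true(all(diff(got[order(doses)]) >= 0))
    }
  }
  expect_error(build_dose_response(
    fit_mortality_glm(d[d$genotype %in% c("SR", "ST", "SRSR", "SRST"), ],
                      coding = "per_genotype")), "STST")
})

test_that("Poisson GLMM falls back to vial-only when the nested fit is singular", {
  # sigma_id = 0 generator matches the final empirical model structure
  d <- generate_fecundity_dataset(n_females_per_genotype = 150, seed = 81)
  fit <- fit_fecundity_mixed(d)
  expect_true(fit$singular)
  expect_equal(fit$random_spec, "vial_only")
  expect_error(fit_fecundity_mixed(transform(d, offspring = 0L)), ">= 1")
})

test_that("genotype contrasts: pair count, Tukey monotonicity, null case", {
  d <- generate_fecundity_dataset(n_females_per_genotype = 80, seed = 82)
  fit <- fit_fecundity_mixed(d, random_spec = "vial_only")
  ct <- genotype_contrasts(fit)
  expect_equal(nrow(ct), choose(3, 2))
  expect_true(all(ct$p_adjusted >= ct$p_value - 1e-12))
  expect_true(all(ct$p_adjusted <= 1 & ct$p_value >= 0))
  # adjusted p monotone non-increasing in |z|
  o <- order(abs(ct$z))
  expect_true(all(diff(ct$p_adjusted[o]) <= 1e-12))
  # two genotypes built from identical records -> contrast exactly zero
  half <- d[d$genotype == "STST", ]
  twin <- half
  twin$genotype <- "SRST"
  twin$female_id <- paste0(twin$female_id, "b")
  twin$vial_id <- paste0(twin$vial_id, "b")
  sym <- fit_fecundity_mixed(rbind(half, twin), random_spec = "vial_only")
  ct2 <- genotype_contrasts(sym)
  expect_equal(nrow(ct2), 1L)
  expect_lt(abs(ct2$estimate), 1e-4)
  expect_gt(ct2$p_value, 0.99)
  expect_gt(ct2$p_adjusted, 0.99)
})

test_that("brood-size parameters are genotype means with a +/-10 band", {
  rec <- data.frame(
    female_id = c("a", "a", "b", "c", "d", "e"),
    vial_id = "v1",
    genotype = c("SRSR", "SRSR", "SRST", "SRST", "STST", "STST"),
    dose_ml = 0, measure = 1L,
    offspring = c(10L, 20L, 30L, 34L, 18L, 22L))
  fp <- build_fecundity_params(rec)
  expect_equal(unname(fp$b), c(15, 32, 20))
  expect_equal(unname(fp$ranges[, "SRSR"]), c(5, 25))
  expect_error(build_fecundity_params(rec[rec$genotype != "SRSR", ]),
               "SRSR")
  # zero-truncated Poisson data: recovered mean matches the closed form
  p <- true_fecundity_params(
    log_means = setNames(rep(log(20), 3), FEMALE_GENOTYPES),
    dose_effect = 0, sigma_vial = 0)
  big <- generate_fecundity_dataset(p, n_females_per_genotype = 2000,
                                    seed = 83)
  fp2 <- build_fecundity_params(big)
  want <- 20 / (1 - exp(-20))
  expect_equal(unname(fp2$b), rep(want, 3), tolerance = 0.01)
})
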