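test_that("genotype simulation follows Hardy-Weinberg expectations", {
  w <- toy_weights()
  cfg <- cohort_config(n_subjects = 10000, weights = w,
                       mafs = c(0, 1, 0.3, 0.5))
  set.seed(1)
  g <- simulate_genotypes(cfg)
  expect_true(all(g[, 1] == 0))
  expect_true(all(g[, 2] == 2))
  # binomial mean 2*maf within 4 standard errors
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(g[, 3]) - 0.6), 4 * se)
  expect_error(cohort_config(weights = w, mafs = c(0, 1, 2, 0.5)),
               "\\[0, 1\\]")
})

test_that("FFQ simulation is reproducible and feeds deterministic scoring", {
  cfg <- cohort_config(n_subjects = 30)
  catalog <- default_food_catalog()
  set.seed(7); a <- simulate_ffq(cfg, catalog)
  set.seed(7); b <- simulate_ffq(cfg, catalog)
  expect_identical(a, b)
  expect_setequal(unique(a$ffq$item_id), catalog$item_id)
  expect_equal(nrow(a$ffq), 30 * nrow(catalog))
  expect_error(simulate_ffq(cfg, catalog[0, ]), "empty")
})

test_that("point-mass questionnaire profiles yield exact daily grams", {
  catalog <- data.frame(item_id = "only", grams_per_serving = 100,
                        mufa_per_100g = 0, sfa_per_100g = 1,
                        group = "vegetables", stringsAsFactors = FALSE)
  ffq <- ffq_row(sprintf("s%d", 1:5), "only", "1 time/day", 1, FALSE)
  grams <- item_daily_grams(ffq, catalog)
  expect_true(all(grams$grams_per_day == 100))
  ffq$frequency_category <- "never or less than 1 time/month"
  expect_true(all(item_daily_grams(ffq, catalog)$grams_per_day == 0))
})

test_that("outcome generation is marginally specified", {
  # all effects zero, intercept logit(0.3): case fraction recovers 0.3
  # even with a strong shared latent effect
  cfg <- cohort_config(n_subjects = 5000, intercept = qlogis(0.3),
                       beta_grs_high = 0, beta_diet_low = 0,
                       beta_interaction = 0,
                       covariate_effects = c(age70_75 = 0, age_over75 = 0,
                                             male = 0, smoker = 0,
                                             exercise = 0),
                       subject_effect_sd = 1.5, missing_eye_prob = 0)
  set.seed(3)
  cov <- simulate_covariates(cfg)
  out <- simulate_outcomes(cfg, grs_high = rep(FALSE, 5000),
                           diet_low = rep(FALSE, 5000), covariates = cov)
  frac <- mean(c(out$outcome_right, out$outcome_left))
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / 5000))

  # a hopeless intercept produces no cases at all
  cfg0 <- cohort_config(n_subjects = 200, intercept = -30)
  set.seed(4)
  cov0 <- simulate_covariates(cfg0)
  out0 <- simulate_outcomes(cfg0, rep(FALSE, 200), rep(FALSE, 200), cov0)
  expect_true(all(c(out0$outcome_right, out0$outcome_left) == 0,
                  na.rm = TRUE))
})

test_that("the shared latent effect raises inter-eye concordance", {
  base <- list(n_subjects = 2000, missing_eye_prob = 0)
  concord <- function(sd) {
    cfg <- do.call(cohort_config,
                   c(base, list(subject_effect_sd = sd)))
    set.seed(8)
    cov <- simulate_covariates(cfg)
    out <- simulate_outcomes(cfg, rep(c(TRUE, FALSE), 1000),
                             rep(c(FALSE, TRUE), 1000), cov)
    mean(out$outcome_right == out$outcome_left)
  }
  expect_gt(concord(3), concord(0))
})

test_that("a full cohort is deterministic under a fixed seed", {
  cfg <- cohort_config(n_subjects = 80)
  a <- simulate_cohort(cfg, seed = 31)
  b <- simulate_cohort(cfg, seed = 31)
  expect_identical(a$ffq, b$ffq)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_cohort(cfg, seed = 32)
  expect_false(identical(a$phenotypes, c$phenotypes))
  # every subject has at least one gradable eye
  expect_true(all(!is.na(a$phenotypes$stage_right) |
                    !is.na(a$phenotypes$stage_left)))
})

test_that("written cohorts reload through the standard readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_config(n_subjects = 40), seed = 5)
  write_cohort(co, dir)
  catalog <- read_food_catalog(file.path(dir, "catalog.csv"))
  weights <- read_variant_weights(file.path(dir, "weights.csv"),
                                  canonical = TRUE)
  ffq <- read_ffq_table(file.path(dir, "ffq.csv"), catalog)
  geno <- read_genotypes(file.path(dir, "genotypes.csv"), weights)
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ffq), nrow(co$ffq))
  expect_identical(geno, co$genotypes)
  expect_equal(nrow(ph), 40)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
})

test_that("exposure margins track the configured generating model", {
  co <- simulate_cohort(cohort_config(n_subjects = 3000), seed = 13)
  diet <- score_diet(co$ffq, co$catalog,
                     sex = co$phenotypes[c("subject_id", "sex")])
  grs <- dichotomize_grs(compute_grs(co$genotypes, co$weights))
  # the >=-median rule puts about half the cohort in the high-GRS arm
  expect_lt(abs(mean(grs$high_grs) - 0.5), 0.02)
  # high adherence sits near the configured one-in-five margin
  expect_gt(mean(diet$high_adherence), 0.1)
  expect_lt(mean(diet$high_adherence), 0.35)
})
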