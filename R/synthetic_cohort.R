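#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator with defaults anchored to the
#' margins and effect sizes a paired-eye AMD case-control study of this
#' design reports: 612 subjects, a case fraction near 26%, a high-adherence
#' fraction near 20%, genetic and dietary exposure effects of
#' log(1.788) and log(2.327) with a log(1.111) interaction, and covariate
#' effects of the magnitude seen for age bands, sex, smoking and exercise.
#'
#' @param n_subjects Number of subjects.
#' @param mafs Risk-allele frequencies, one per variant (defaults pair with
#'   [default_variant_weights()]).
#' @param weights Variant-weight table; defaults to the packaged synthetic
#'   52-variant table.
#' @param intercept Log-odds of an eye being affected in the joint
#'   reference group (low GRS, high adherence, reference covariates).
#' @param beta_grs_high,beta_diet_low,beta_interaction Log odds ratios for
#'   the dichotomized exposures and their product term.
#' @param covariate_effects Named log-OR vector: `age70_75`, `age_over75`,
#'   `male`, `smoker`, `exercise`.
#' @param covariate_dist Named list of covariate margins: `age_mean`,
#'   `age_sd` (truncated to [55, 95]), `p_female`, `p_smoker`,
#'   `p_exercise`.
#' @param subject_effect_sd Standard deviation of the shared per-subject
#'   latent effect that induces inter-eye correlation (logit scale).
#' @param missing_eye_prob Probability an eye is ungradable (at least one
#'   eye per subject is always retained).
#' @param geno_missing_prob Probability a genotype call is missing.
#' @param diet_profile List controlling FFQ answers: `freq_mean` (named
#'   per-group mean frequency level on the 1-9 category scale), `freq_sd`
#'   (within-item spread, in levels), `quality_sd` (strength of the
#'   subject-level healthy-eating gradient, in levels per unit latent
#'   quality), `serving_sdlog` (log-normal spread of servings per
#'   occasion), `seasonal_prob` (chance a fruit/vegetable answer is marked
#'   seasonal).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 612,
                          weights = default_variant_weights(),
                          mafs = default_mafs(nrow(weights)),
                          intercept = -3.15,
                          beta_grs_high = log(1.788),
                          beta_diet_low = log(2.327),
                          beta_interaction = log(1.111),
                          covariate_effects = c(age70_75 = log(1.467),
                                                age_over75 = log(2.839),
                                                male = log(0.514),
                                                smoker = log(2.072),
                                                exercise = log(0.688)),
                          covariate_dist = list(age_mean = 72.5,
                                                age_sd = 6.5,
                                                p_female = 0.575,
                                                p_smoker = 0.144,
                                                p_exercise = 0.443),
                          subject_effect_sd = 1,
                          missing_eye_prob = 0.0065,
                          geno_missing_prob = 0,
                          diet_profile = list(
                            freq_mean = c(vegetables = 5.5, legumes = 3.8,
                                          fruits = 5.8, cereals = 6.0,
                                          fish = 4.3, meat = 4.8,
                                          dairy = 6.0, alcohol = 2.0,
                                          fat_only = 5.8, other = 4.5),
                            freq_sd = 1.2,
                            quality_sd = 0.25,
                            serving_sdlog = 0.3,
                            seasonal_prob = 0.15)) {
  cfg <- list(n_subjects = n_subjects, weights = weights, mafs = mafs,
              intercept = intercept, beta_grs_high = beta_grs_high,
              beta_diet_low = beta_diet_low,
              beta_interaction = beta_interaction,
              covariate_effects = covariate_effects,
              covariate_dist = covariate_dist,
              subject_effect_sd = subject_effect_sd,
              missing_eye_prob = missing_eye_prob,
              geno_missing_prob = geno_missing_prob,
              diet_profile = diet_profile)
  stopifnot(n_subjects >= 2, subject_effect_sd >= 0,
            missing_eye_prob >= 0, missing_eye_prob <= 1,
            geno_missing_prob >= 0, geno_missing_prob <= 1)
  if (length(cfg$mafs) != nrow(cfg$weights)) {
    stop("mafs must have one entry per weight-table variant", call. = FALSE)
  }
  if (any(cfg$mafs < 0 | cfg$mafs > 1)) {
    stop("mafs must lie in [0, 1]", call. = FALSE)
  }
  req <- c("age70_75", "age_over75", "male", "smoker", "exercise")
  if (!all(req %in% names(cfg$covariate_effects))) {
    stop("covariate_effects must name: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Packaged synthetic 52-variant weight table
#'
#' A stand-in for a real AMD variant panel: the five major risk variants
#' carry their published rsIDs with plausible effect sizes; the remaining
#' 47 variants are synthetic (ids `rsSIM...`), with small effects frozen
#' once. Shipped as `inst/extdata/synthetic_variant_weights.csv`.
#'
#' @return Validated weight table (52 rows, 5 major).
#' @export
default_variant_weights <- function() {
  path <- system.file("extdata", "synthetic_variant_weights.csv",
                      package = "eyegee", mustWork = TRUE)
  read_variant_weights(path, canonical = TRUE)
}

#' Default risk-allele frequencies for simulation
#'
#' An even spread over [0.08, 0.48]; real panels mix common and rarer
#' variants, and an even spread covers that range deterministically.
#'
#' @param n Number of variants.
#' @return Numeric vector of length `n`.
#' @export
default_mafs <- function(n = 52) round(seq(0.08, 0.48, length.out = n), 3)

#' Packaged synthetic food catalog
#'
#' A 25-item synthetic catalog covering all nine mediSCORE groups plus
#' fat-only and unscored items; serving sizes and lipid contents are
#' realistic round numbers. Alcohol items are denominated in grams of
#' ethanol per serving, so the alcohol group total is ethanol g/day.
#'
#' @return Validated catalog data frame.
#' @export
default_food_catalog <- function() {
  path <- system.file("extdata", "synthetic_food_catalog.csv",
                      package = "eyegee", mustWork = TRUE)
  read_food_catalog(path)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Risk-allele counts are drawn Binomial(2, maf) independently per subject
#' and variant (linkage equilibrium). Randomness comes from R's global
#' generator (Mersenne-Twister); seed with [set.seed()] or use
#' [simulate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param subject_ids Optional ids; defaults to `S0001`, `S0002`, ...
#' @return Integer matrix subjects x variants with `NA`s inserted at rate
#'   `geno_missing_prob`.
#' @export
simulate_genotypes <- function(config, subject_ids = NULL) {
  n <- config$n_subjects
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n))
  m <- length(config$mafs)
  counts <- matrix(stats::rbinom(n * m, 2L,
                                 rep(config$mafs, each = n)), n, m)
  if (config$geno_missing_prob > 0) {
    counts[stats::runif(n * m) < config$geno_missing_prob] <- NA_integer_
  }
  dimnames(counts) <- list(subject_ids, config$weights$variant_id)
  counts
}

#' Simulate food-frequency questionnaire answers
#'
#' Every subject answers every catalog item. A latent healthy-eating
#' quality per subject shifts beneficial items (vegetables, legumes,
#' fruits, cereals, fish, olive-oil-type fats) towards higher frequency
#' categories and detrimental items (meat, dairy) towards lower ones,
#' inducing the between-component correlation real diets show; alcohol and
#' unscored items do not load on it. Frequency categories are drawn by
#' rounding a normal deviate on the 1-9 level scale.
#'
#' @param config A [cohort_config()].
#' @param catalog Food catalog; defaults to [default_food_catalog()].
#' @param subject_ids Optional ids (matched to the genotype matrix).
#' @return List: `ffq` (long response table) and `quality` (the latent
#'   per-subject diet quality, useful for diagnostics).
#' @export
simulate_ffq <- function(config, catalog = default_food_catalog(),
                         subject_ids = NULL) {
  if (nrow(catalog) == 0) stop("empty food catalog", call. = FALSE)
  n <- config$n_subjects
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n))
  pr <- config$diet_profile
  direction <- c(vegetables = 1, legumes = 1, fruits = 1, cereals = 1,
                 fish = 1, meat = -1, dairy = -1, alcohol = 0,
                 fat_only = 1, other = 0)
  quality <- stats::rnorm(n)
  rows <- vector("list", nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    gr <- catalog$group[j]
    lvl <- pr$freq_mean[[gr]] + direction[[gr]] * pr$quality_sd * quality +
      stats::rnorm(n, 0, pr$freq_sd)
    lvl <- pmin(pmax(round(lvl), 1L), 9L)
    seasonal <- if (gr %in% c("fruits", "vegetables")) {
      stats::runif(n) < pr$seasonal_prob
    } else {
      rep(FALSE, n)
    }
    rows[[j]] <- data.frame(
      subject_id = subject_ids,
      item_id = catalog$item_id[j],
      frequency_category = FREQ_LEVELS[lvl],
      servings_per_occasion = stats::rlnorm(n, 0, pr$serving_sdlog),
      seasonal = seasonal,
      stringsAsFactors = FALSE)
  }
  ffq <- do.call(rbind, rows)
  ffq <- ffq[order(match(ffq$subject_id, subject_ids)), ]
  rownames(ffq) <- NULL
  list(ffq = ffq, quality = stats::setNames(quality, subject_ids))
}

#' Simulate subject-level covariates
#'
#' @param config A [cohort_config()].
#' @param subject_ids Optional ids.
#' @return Data frame: `subject_id`, `age`, `sex`, `smoking`, `exercise`.
#' @export
simulate_covariates <- function(config, subject_ids = NULL) {
  n <- config$n_subjects
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n))
  cd <- config$covariate_dist
  age <- pmin(pmax(stats::rnorm(n, cd$age_mean, cd$age_sd), 55), 95)
  data.frame(
    subject_id = subject_ids,
    age = round(age, 1),
    sex = factor(ifelse(stats::runif(n) < cd$p_female, "female", "male"),
                 levels = SEX_LEVELS),
    smoking = factor(ifelse(stats::runif(n) < cd$p_smoker,
                            "smoker/ex-smoker", "non-smoker"),
                     levels = SMOKING_LEVELS),
    exercise = stats::runif(n) < cd$p_exercise,
    stringsAsFactors = FALSE)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (for integrating against
# exp(-x^2)).
gauss_hermite <- function(n = 25) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

# Solve, per element, for the offset d such that E[plogis(d + u)] = p with
# u ~ N(0, sd^2): Newton iterations on a Gauss-Hermite quadrature of the
# logistic-normal mean. Makes the generating model marginally specified.
marginal_offset <- function(p, sd, gh = gauss_hermite(25)) {
  if (sd == 0) return(stats::qlogis(p))
  shift <- sqrt(2) * sd * gh$nodes
  w <- gh$weights / sqrt(pi)
  # attenuation-based start (logistic-normal approximation)
  d <- stats::qlogis(p) * sqrt(1 + (16 * sqrt(3) / (15 * pi))^2 * sd^2)
  for (it in 1:40) {
    M <- outer(d, shift, "+")
    f <- drop(stats::plogis(M) %*% w) - p
    fp <- drop((stats::plogis(M) * (1 - stats::plogis(M))) %*% w)
    d <- d - f / pmax(fp, 1e-12)
    if (max(abs(f)) < 1e-12) break
  }
  d
}

#' Simulate paired-eye binary outcomes
#'
#' Outcomes follow a marginally specified logistic model: the linear
#' predictor (intercept, dichotomized GRS and diet exposures, their
#' product, and covariate effects) defines each eye's *marginal*
#' probability, and a shared per-subject normal latent effect induces
#' inter-eye correlation without shifting those marginals (the conditional
#' probability is solved by quadrature so that its average over the latent
#' effect equals the marginal). Marginal regression estimated by GEE on
#' such data is therefore centred on the generating coefficients.
#'
#' @param config A [cohort_config()].
#' @param grs_high Logical per subject: high genetic risk.
#' @param diet_low Logical per subject: low Mediterranean-diet adherence
#'   (the risk coding).
#' @param covariates Data frame from [simulate_covariates()].
#' @return Data frame: `subject_id`, `eta` (marginal log-odds),
#'   `outcome_right`, `outcome_left` (`NA` = ungradable eye).
#' @export
simulate_outcomes <- function(config, grs_high, diet_low, covariates) {
  n <- config$n_subjects
  stopifnot(length(grs_high) == n, length(diet_low) == n,
            nrow(covariates) == n)
  ce <- config$covariate_effects
  age_cat <- age_category(covariates$age)
  eta <- config$intercept +
    config$beta_grs_high * as.numeric(grs_high) +
    config$beta_diet_low * as.numeric(diet_low) +
    config$beta_interaction * as.numeric(grs_high & diet_low) +
    ce[["age70_75"]] * (!is.na(age_cat) & age_cat == "70-75") +
    ce[["age_over75"]] * (!is.na(age_cat) & age_cat == ">75") +
    ce[["male"]] * (covariates$sex == "male") +
    ce[["smoker"]] * (covariates$smoking == "smoker/ex-smoker") +
    ce[["exercise"]] * covariates$exercise
  p <- stats::plogis(eta)
  u <- stats::rnorm(n, 0, config$subject_effect_sd)
  d <- marginal_offset(p, config$subject_effect_sd)
  pc <- stats::plogis(d + u)
  right <- stats::rbinom(n, 1L, pc)
  left <- stats::rbinom(n, 1L, pc)
  miss_r <- stats::runif(n) < config$missing_eye_prob
  miss_l <- stats::runif(n) < config$missing_eye_prob
  miss_l[miss_r & miss_l] <- FALSE   # keep at least one gradable eye
  right[miss_r] <- NA_integer_
  left[miss_l] <- NA_integer_
  data.frame(subject_id = covariates$subject_id, eta = eta,
             outcome_right = right, outcome_left = left,
             stringsAsFactors = FALSE)
}

# Map a simulated binary eye outcome to a Rotterdam stage.
stage_from_outcome <- function(outcome, n) {
  stage <- rep(NA_character_, n)
  aff <- which(!is.na(outcome) & outcome == 1L)
  ctl <- which(!is.na(outcome) & outcome == 0L)
  stage[aff] <- sample(CASE_STAGES, length(aff), replace = TRUE,
                       prob = c(0.35, 0.2, 0.2, 0.25))
  stage[ctl] <- ifelse(stats::runif(length(ctl)) < 0.9, "0", "1")
  stage
}

#' Generate a complete synthetic cohort
#'
#' Draws genotypes, questionnaire answers, covariates and paired-eye
#' outcomes in one pass and assembles the five tables the analysis
#' pipeline consumes. The generator is fully deterministic given `seed`
#' (R's Mersenne-Twister).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param catalog Food catalog; defaults to the packaged synthetic one.
#' @return List of class `synthetic_cohort`: `ffq`, `catalog`,
#'   `genotypes` (count matrix), `weights`, `phenotypes`, plus `truth`
#'   (config, seed, per-subject exposures and latent diet quality) for
#'   parameter-recovery work.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            catalog = default_food_catalog()) {
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(config$n_subjects))
  genotypes <- simulate_genotypes(config, ids)
  grs <- dichotomize_grs(compute_grs(genotypes, config$weights))
  ffq_sim <- simulate_ffq(config, catalog, ids)
  covariates <- simulate_covariates(config, ids)
  diet <- score_diet(ffq_sim$ffq, catalog,
                     sex = covariates[c("subject_id", "sex")])
  high_grs <- grs$high_grs[match(ids, grs$subject_id)]
  # excluded-GRS subjects still need outcomes; use the low-risk stratum
  grs_for_sim <- !is.na(high_grs) & high_grs
  diet_low <- !diet$high_adherence[match(ids, diet$subject_id)]
  out <- simulate_outcomes(config, grs_for_sim, diet_low, covariates)
  phenotypes <- data.frame(
    covariates,
    stage_right = stage_from_outcome(out$outcome_right, config$n_subjects),
    stage_left = stage_from_outcome(out$outcome_left, config$n_subjects),
    stringsAsFactors = FALSE)
  structure(list(
    ffq = ffq_sim$ffq, catalog = catalog, genotypes = genotypes,
    weights = config$weights, phenotypes = phenotypes,
    truth = list(config = config, seed = seed,
                 high_grs = stats::setNames(grs_for_sim, ids),
                 diet_low = stats::setNames(diet_low, ids),
                 eta = stats::setNames(out$eta, ids),
                 diet_quality = ffq_sim$quality)
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes the five pipeline inputs as CSV plus a plain-text manifest
#' recording the seed and configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(cohort$ffq, file.path(dir, "ffq.csv"))
  write_cohort_table(cohort$catalog, file.path(dir, "catalog.csv"))
  write_genotype_csv(cohort$genotypes, file.path(dir, "genotypes.csv"))
  write_cohort_table(cohort$weights, file.path(dir, "weights.csv"))
  ph <- cohort$phenotypes
  ph$sex <- as.character(ph$sex)
  ph$smoking <- as.character(ph$smoking)
  write_cohort_table(ph, file.path(dir, "phenotypes.csv"))
  cfg <- cohort$truth$config
  cfg$weights <- NULL
  manifest <- c(sprintf("package: eyegee %s",
                        as.character(utils::packageVersion("eyegee"))),
                sprintf("seed: %d", cohort$truth$seed),
                "rng: Mersenne-Twister (R default)",
                utils::capture.output(utils::str(cfg)))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
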