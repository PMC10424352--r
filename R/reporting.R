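#' Descriptive case/control comparison
#'
#' Summarises each variable by group and tests for a difference:
#' continuous variables with the two-sample Wilcoxon rank-sum test
#' (mean and SD reported), categorical variables with Pearson's
#' chi-squared test on the contingency table, switching to Fisher's exact
#' test when any expected cell count falls below `exact_threshold`.
#' Single-level variables are summarised with the test skipped.
#'
#' @param subject_table Data frame with a `group` column
#'   (`"case"`/`"control"`) and the variables to compare.
#' @param variables Which columns to compare; defaults to everything
#'   except `subject_id` and `group`.
#' @param exact_threshold Expected-count rule for switching to the exact
#'   test.
#' @return Data frame with one row per variable level (categorical) or per
#'   variable (continuous): `variable`, `level`, `cases`, `controls`
#'   (formatted `n (pct)` or `mean (SD)`), `test`, `p` (test and p on the
#'   variable's first row).
#' @export
compare_cases_controls <- function(subject_table,
                                   variables = NULL,
                                   exact_threshold = 5) {
  stopifnot("group" %in% names(subject_table))
  g <- factor(subject_table$group, levels = c("case", "control"))
  if (anyNA(g)) stop("group must be 'case' or 'control'", call. = FALSE)
  if (is.null(variables)) {
    variables <- setdiff(names(subject_table), c("subject_id", "group"))
  }
  rows <- list()
  for (v in variables) {
    x <- subject_table[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      msd <- vapply(levels(g), function(lev) {
        sprintf("%.1f (%.1f)", mean(x[g == lev], na.rm = TRUE),
                stats::sd(x[g == lev], na.rm = TRUE))
      }, character(1))
      p <- stats::wilcox.test(x ~ g, exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, cases = msd[["case"]],
        controls = msd[["control"]], test = "rank-sum", p = p,
        stringsAsFactors = FALSE)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      if (nlevels(x) < 2) {
        test <- NA_character_
        p <- NA_real_
        note <- "single level; test skipped"
      } else {
        cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        if (any(cs$expected < exact_threshold)) {
          test <- "exact"
          p <- stats::fisher.test(tab)$p.value
        } else {
          test <- "chi-squared"
          p <- cs$p.value
        }
        note <- NA_character_
      }
      pct <- prop.table(tab, margin = 2) * 100
      for (k in seq_len(nlevels(x))) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = levels(x)[k],
          cases = sprintf("%d (%.1f%%)", tab[k, "case"], pct[k, "case"]),
          controls = sprintf("%d (%.1f%%)", tab[k, "control"],
                             pct[k, "control"]),
          test = if (k == 1L) test else NA_character_,
          p = if (k == 1L) p else NA_real_,
          stringsAsFactors = FALSE)
      }
      if (!is.na(note)) {
        rows[[length(rows)]]$test <- note
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end: simulate (or load) a cohort,
#' score the diet, compute and dichotomize the genetic risk score,
#' classify case/control and expand to eye records, fit the adjusted GEE
#' models with and without the interaction term, and assemble the
#' descriptive comparison and the interaction report.
#'
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param seed Seed for simulation and bootstrap.
#' @param cohort Optional pre-built cohort: a `synthetic_cohort` object or
#'   a named list of file paths (`ffq`, `catalog`, `genotypes`, `weights`,
#'   `phenotypes`) to load via the cohort readers.
#' @param n_boot Bootstrap replicates for the additive measures (0 = delta
#'   method only).
#' @param cutoffs Optional fixed mediSCORE cut-offs
#'   (`mediscore_cutoffs`).
#' @return Object of class `eyegee_pipeline`: `table1`, `records`,
#'   `exclusions`, `grs`, `diet`, `fit_main` (no interaction),
#'   `interaction` (an `interaction_report`), and a `manifest` recording
#'   seed and configuration.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         cohort = NULL, n_boot = 0, cutoffs = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(cohort)) {
    cohort <- stage("simulate", simulate_cohort(config, seed))
  } else if (!inherits(cohort, "synthetic_cohort")) {
    cohort <- stage("load", {
      catalog <- read_food_catalog(cohort$catalog)
      weights <- read_variant_weights(cohort$weights)
      list(ffq = read_ffq_table(cohort$ffq, catalog), catalog = catalog,
           weights = weights,
           genotypes = read_genotypes(cohort$genotypes, weights),
           phenotypes = read_phenotypes(cohort$phenotypes))
    })
  }
  diet <- stage("score-diet", score_diet(
    cohort$ffq, cohort$catalog,
    sex = cohort$phenotypes[c("subject_id", "sex")], cutoffs = cutoffs))
  grs <- stage("grs",
               dichotomize_grs(compute_grs(cohort$genotypes,
                                           cohort$weights)))
  records <- stage("classify",
                   build_eye_records(cohort$phenotypes, grs, diet))
  if (nrow(records) == 0) stop("pipeline stage 'classify' retained no eyes",
                               call. = FALSE)
  fit_main <- stage("fit", amd_gee(records, include_interaction = FALSE))
  inter <- stage("interact",
                 interaction_report(records, n_boot = n_boot, seed = seed))
  subj <- records[!duplicated(records$subject_id),
                  c("subject_id", "group", "sex", "smoking", "exercise",
                    "age_cat", "high_grs", "high_mediscore")]
  subj$age <- cohort$phenotypes$age[match(subj$subject_id,
                                          cohort$phenotypes$subject_id)]
  table1 <- stage("table1", compare_cases_controls(
    subj, variables = c("age", "sex", "smoking", "exercise", "high_grs",
                        "high_mediscore")))
  structure(list(
    table1 = table1, records = records,
    exclusions = attr(records, "exclusions"),
    grs = grs, diet = diet, fit_main = fit_main, interaction = inter,
    manifest = list(seed = seed,
                    n_subjects = length(unique(cohort$phenotypes$subject_id)),
                    n_retained = length(unique(records$subject_id)),
                    n_records = nrow(records),
                    package = as.character(utils::packageVersion("eyegee")))
  ), class = "eyegee_pipeline")
}

#' @export
print.eyegee_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("Gene-diet interaction pipeline\n")
  cat(sprintf("  %d subjects in, %d retained (%d eye records); seed %s\n",
              m$n_subjects, m$n_retained, m$n_records, m$seed))
  n_case <- sum(x$records$group[!duplicated(x$records$subject_id)] ==
                  "case")
  cat(sprintf("  cases %d / controls %d\n", n_case,
              m$n_retained - n_case))
  cat("\nMain-effects model (protective diet coding):\n")
  print(odds_ratios(x$fit_main), digits = 3)
  cat("\n")
  print(x$interaction)
  invisible(x)
}
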