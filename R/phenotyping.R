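#' Classify subjects as case, control or excluded
#'
#' The subject-level phenotype is determined by the most severe eye
#' (Rotterdam stage). Stages 2a, 2b, 3 and 4 define a case. Controls must
#' be free of the case stages in both gradable eyes and old enough that
#' later progression is unlikely: worst stage 0 requires age above 60,
#' worst stage 1 requires age above 70 (strict inequalities). Everyone else
#' is excluded.
#'
#' @param phenotypes Validated phenotype table ([read_phenotypes()]).
#' @return Character vector (`"case"`, `"control"`, `"excluded"`), one per
#'   subject, named by `subject_id`.
#' @export
classify_subjects <- function(phenotypes) {
  worst <- worst_stage(phenotypes$stage_right, phenotypes$stage_left)
  age <- phenotypes$age
  out <- ifelse(worst %in% CASE_STAGES, "case",
         ifelse(worst == "0" & age > 60, "control",
         ifelse(worst == "1" & age > 70, "control", "excluded")))
  stats::setNames(out, phenotypes$subject_id)
}

worst_stage <- function(right, left) {
  r <- match(right, ROTTERDAM_STAGES)
  l <- match(left, ROTTERDAM_STAGES)
  idx <- pmax(r, l, na.rm = TRUE)
  ROTTERDAM_STAGES[idx]
}

#' Categorize age for the eye-level model
#'
#' Half-open bands \code{[60, 70)}, \code{[70, 75)} and \code{[75, Inf)},
#' labelled `60-70` (reference), `70-75`, `>75`. Ages below 60 get `NA`
#' (such subjects cannot be controls and cases below 60 fall outside the
#' model's age range).
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels `60-70`, `70-75`, `>75`.
#' @export
age_category <- function(age) {
  cut(age, breaks = c(60, 70, 75, Inf), labels = AGE_CAT_LEVELS,
      right = FALSE)
}

#' Expand classified subjects into eye-level analysis records
#'
#' One record per gradable eye of each retained subject. The eye-level
#' outcome is 1 when that eye's stage is 2a, 2b, 3 or 4 (the same stage set
#' that defines a case subject), so a case's unaffected eye contributes an
#' outcome of 0. Subjects are dropped -- with a logged reason -- when their
#' classification is `excluded`, their genetic risk score is invalid, their
#' diet score is unavailable, or their age falls below the model's age
#' bands.
#'
#' @param phenotypes Validated phenotype table.
#' @param grs_results Output of [dichotomize_grs()].
#' @param mediscore_results Output of [mediscore()] / [score_diet()].
#' @return Data frame of eye records (`subject_id`, `eye`, `outcome`,
#'   `age_cat`, `sex`, `smoking`, `exercise`, `high_grs`,
#'   `high_mediscore`, `group`), with attribute `"exclusions"` -- a data
#'   frame of `subject_id`, `reason` for every dropped subject.
#' @export
build_eye_records <- function(phenotypes, grs_results, mediscore_results) {
  cls <- classify_subjects(phenotypes)
  gi <- match(phenotypes$subject_id, grs_results$subject_id)
  mi <- match(phenotypes$subject_id, mediscore_results$subject_id)
  age_cat <- age_category(phenotypes$age)

  reason <- rep(NA_character_, nrow(phenotypes))
  reason[cls == "excluded"] <- "not classifiable as case or control"
  reason[is.na(reason) & (is.na(gi) | !grs_results$included[gi])] <-
    "no valid genetic risk score"
  reason[is.na(reason) & is.na(mi)] <- "no diet score"
  reason[is.na(reason) & is.na(age_cat)] <- "age below 60"
  keep <- is.na(reason)

  base <- data.frame(
    subject_id = phenotypes$subject_id,
    age_cat = age_cat,
    sex = phenotypes$sex,
    smoking = phenotypes$smoking,
    exercise = phenotypes$exercise,
    high_grs = grs_results$high_grs[gi],
    high_mediscore = mediscore_results$high_adherence[mi],
    group = unname(cls),
    stringsAsFactors = FALSE)[keep, ]
  one_eye <- function(eye, stage) {
    ok <- !is.na(stage)
    cbind(base[ok, ], eye = eye,
          outcome = as.integer(stage[ok] %in% CASE_STAGES))
  }
  out <- rbind(one_eye("right", phenotypes$stage_right[keep]),
               one_eye("left", phenotypes$stage_left[keep]))
  out <- out[order(match(out$subject_id, phenotypes$subject_id)), ]
  rownames(out) <- NULL
  cols <- c("subject_id", "eye", "outcome", "age_cat", "sex", "smoking",
            "exercise", "high_grs", "high_mediscore", "group")
  out <- out[cols]
  out$age_cat <- factor(out$age_cat, levels = AGE_CAT_LEVELS)
  attr(out, "exclusions") <- data.frame(
    subject_id = phenotypes$subject_id[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  out
}
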