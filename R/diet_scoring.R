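#' Convert an FFQ frequency category to occasions per day
#'
#' The questionnaire records intake frequency in nine ordered categories.
#' The default conversion takes each category's midpoint, expressed per day
#' (months averaged at 30.44 days): 0, 2/30.44, 1/7, 3/7, 5.5/7, 1, 2.5,
#' 4.5 and 6 occasions/day. "Never or less than 1 time/month" is floored
#' at zero.
#'
#' @param frequency_category Character vector of category labels.
#' @param mapping Named numeric vector overriding the default conversion
#'   (names must be the nine canonical labels).
#' @return Numeric vector of occasions per day.
#' @export
frequency_to_daily <- function(frequency_category, mapping = FREQ_PER_DAY) {
  stopifnot(setequal(names(mapping), FREQ_LEVELS))
  bad <- which(!(frequency_category %in% names(mapping)))
  if (length(bad)) {
    stop("unknown frequency category: ",
         dQuote(frequency_category[bad[1]]), call. = FALSE)
  }
  unname(mapping[frequency_category])
}

#' Average daily intake in grams for each FFQ response
#'
#' grams/day = occasions/day x servings per occasion x grams per serving,
#' multiplied by 0.25 for seasonal items to spread a roughly three-month
#' availability window over the year.
#'
#' @param ffq Validated FFQ table ([read_ffq_table()]).
#' @param catalog Food catalog ([read_food_catalog()]); must cover all items.
#' @param mapping Frequency conversion, see [frequency_to_daily()].
#' @param seasonal_factor Annualisation weight for seasonal items.
#' @return Data frame `subject_id`, `item_id`, `grams_per_day`.
#' @export
item_daily_grams <- function(ffq, catalog, mapping = FREQ_PER_DAY,
                             seasonal_factor = 0.25) {
  idx <- match(ffq$item_id, catalog$item_id)
  if (anyNA(idx)) {
    stop("item_id absent from catalog: ",
         dQuote(ffq$item_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  occ <- frequency_to_daily(ffq$frequency_category, mapping)
  grams <- occ * ffq$servings_per_occasion * catalog$grams_per_serving[idx] *
    ifelse(ffq$seasonal, seasonal_factor, 1)
  data.frame(subject_id = ffq$subject_id, item_id = ffq$item_id,
             grams_per_day = grams, stringsAsFactors = FALSE)
}

#' Aggregate item intakes into mediSCORE food groups
#'
#' Sums grams/day into the eight food groups (vegetables, legumes, fruits,
#' cereals, fish, meat, dairy, alcohol) and computes the
#' monounsaturated/saturated lipid ratio over all items (including fat_only
#' and other items, which feed only the ratio).
#'
#' @param intakes Output of [item_daily_grams()].
#' @param catalog Food catalog with `group`, `mufa_per_100g`, `sfa_per_100g`.
#' @param sex Optional named vector or data frame (`subject_id`, `sex`)
#'   attaching sex to each subject; required downstream for sex-specific
#'   cut-offs.
#' @return Data frame with one row per subject: the eight group totals, the
#'   `mufa_sfa_ratio` (NA when total saturated fat is zero), and `sex` if
#'   supplied.
#' @export
aggregate_groups <- function(intakes, catalog, sex = NULL) {
  idx <- match(intakes$item_id, catalog$item_id)
  if (anyNA(idx)) {
    stop("item_id absent from catalog: ",
         dQuote(intakes$item_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  subjects <- unique(intakes$subject_id)
  group <- catalog$group[idx]
  g <- intakes$grams_per_day
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  scored <- setdiff(DIET_GROUPS, c("fat_only", "other"))
  for (gr in scored) {
    tot <- tapply(g * (group == gr), intakes$subject_id, sum)
    out[[gr]] <- as.numeric(tot[subjects])
  }
  mufa <- tapply(g * catalog$mufa_per_100g[idx] / 100,
                 intakes$subject_id, sum)
  sfa <- tapply(g * catalog$sfa_per_100g[idx] / 100,
                intakes$subject_id, sum)
  ratio <- ifelse(sfa[subjects] > 0, mufa[subjects] / sfa[subjects], NA)
  out$mufa_sfa_ratio <- as.numeric(ratio)
  if (!is.null(sex)) {
    if (is.data.frame(sex)) {
      out$sex <- sex$sex[match(out$subject_id, sex$subject_id)]
    } else {
      out$sex <- sex[out$subject_id]
    }
    out$sex <- factor(as.character(out$sex), levels = SEX_LEVELS)
    if (anyNA(out$sex)) stop("sex missing for some subjects", call. = FALSE)
  }
  out
}

#' Sex-specific median cut-offs for the mediSCORE
#'
#' Medians are taken per sex over the supplied population (the reference
#' population may be larger than the analysis sample). Even-sized strata use
#' the midpoint-of-the-middle-two convention. Alcohol uses fixed moderate
#' windows rather than a median: 10-50 g/day for men, 5-25 g/day for women,
#' endpoints inclusive.
#'
#' @param group_intakes Output of [aggregate_groups()] with a `sex` column.
#' @return Object of class `mediscore_cutoffs`: per-sex medians for the five
#'   beneficial groups, the two detrimental groups and the lipid ratio, plus
#'   the alcohol windows.
#' @export
sex_specific_medians <- function(group_intakes) {
  if (is.null(group_intakes$sex)) {
    stop("group_intakes must carry a sex column", call. = FALSE)
  }
  vars <- c(BENEFICIAL_GROUPS, DETRIMENTAL_GROUPS, "mufa_sfa_ratio")
  med <- lapply(SEX_LEVELS, function(s) {
    rows <- group_intakes$sex == s
    if (!any(rows)) stop("no subjects of sex ", s,
                         " to compute medians from", call. = FALSE)
    vapply(vars, function(v) {
      stats::median(group_intakes[[v]][rows], na.rm = TRUE)
    }, numeric(1))
  })
  names(med) <- SEX_LEVELS
  structure(list(medians = med, alcohol = ALCOHOL_RANGE),
            class = "mediscore_cutoffs")
}

#' @export
print.mediscore_cutoffs <- function(x, ...) {
  cat("mediSCORE sex-specific cut-offs (g/day; ratio unitless)\n")
  print(do.call(cbind, x$medians))
  cat(sprintf("alcohol window: male [%g, %g], female [%g, %g] g/day\n",
              x$alcohol$male[1], x$alcohol$male[2],
              x$alcohol$female[1], x$alcohol$female[2]))
  invisible(x)
}

#' Write/read mediSCORE cut-offs as CSV
#'
#' @param cutoffs A `mediscore_cutoffs` object.
#' @param path CSV path.
#' @return The path (write) or a `mediscore_cutoffs` object (read).
#' @export
write_cutoffs <- function(cutoffs, path) {
  df <- data.frame(variable = names(cutoffs$medians$female),
                   female = unname(cutoffs$medians$female),
                   male = unname(cutoffs$medians$male))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  df <- read_table_checked(path, c("variable", "female", "male"))
  med <- list(female = stats::setNames(df$female, df$variable),
              male = stats::setNames(df$male, df$variable))
  vars <- c(BENEFICIAL_GROUPS, DETRIMENTAL_GROUPS, "mufa_sfa_ratio")
  if (!setequal(df$variable, vars)) {
    stop("cut-off table must cover exactly: ", paste(vars, collapse = ", "),
         call. = FALSE)
  }
  structure(list(medians = lapply(med, function(m) m[vars]),
                 alcohol = ALCOHOL_RANGE),
            class = "mediscore_cutoffs")
}

#' Compute the nine-component Mediterranean-diet adherence score
#'
#' One point per food group: the five beneficial groups (vegetables,
#' legumes, fruits, cereals, fish) score 1 when intake is strictly above the
#' sex-specific median; the two detrimental groups (meat, dairy) score 1
#' when intake is at or below it; alcohol scores 1 inside the sex's moderate
#' window (inclusive); the lipid component scores 1 when the MUFA/SFA ratio
#' is strictly above the sex-specific median ratio (0, with a flag, when the
#' ratio is undefined). The total ranges 0-9; a total of 6 or more marks
#' high adherence.
#'
#' @param group_intakes Output of [aggregate_groups()] with `sex`.
#' @param cutoffs `mediscore_cutoffs`; defaults to medians of
#'   `group_intakes` itself via [sex_specific_medians()].
#' @param high_threshold Total at or above which adherence is high.
#' @return Data frame: `subject_id`, the nine 0/1 components, `total`,
#'   `high_adherence`, and `ratio_missing` flagging subjects whose lipid
#'   ratio was undefined.
#' @export
mediscore <- function(group_intakes, cutoffs = NULL, high_threshold = 6) {
  if (is.null(cutoffs)) cutoffs <- sex_specific_medians(group_intakes)
  stopifnot(inherits(cutoffs, "mediscore_cutoffs"))
  sex <- as.character(group_intakes$sex)
  med <- function(v) {
    vapply(seq_along(sex), function(i) cutoffs$medians[[sex[i]]][[v]],
           numeric(1))
  }
  out <- data.frame(subject_id = group_intakes$subject_id,
                    stringsAsFactors = FALSE)
  for (v in BENEFICIAL_GROUPS) {
    out[[v]] <- as.integer(group_intakes[[v]] > med(v))
  }
  for (v in DETRIMENTAL_GROUPS) {
    out[[v]] <- as.integer(group_intakes[[v]] <= med(v))
  }
  rng <- do.call(rbind, ALCOHOL_RANGE[sex])
  out$alcohol <- as.integer(group_intakes$alcohol >= rng[, 1] &
                              group_intakes$alcohol <= rng[, 2])
  ratio <- group_intakes$mufa_sfa_ratio
  out$fat_ratio <- ifelse(is.na(ratio), 0L,
                          as.integer(ratio > med("mufa_sfa_ratio")))
  out$ratio_missing <- is.na(ratio)
  comp <- c(BENEFICIAL_GROUPS, DETRIMENTAL_GROUPS, "alcohol", "fat_ratio")
  out$total <- as.integer(rowSums(out[comp]))
  out$high_adherence <- out$total >= high_threshold
  out[c("subject_id", comp, "total", "high_adherence", "ratio_missing")]
}

#' Score a cohort's diet end to end
#'
#' Convenience wrapper: FFQ responses -> daily grams -> group totals ->
#' mediSCORE, with cut-offs computed on the scored population unless an
#' external `mediscore_cutoffs` object is given.
#'
#' @inheritParams item_daily_grams
#' @param sex `subject_id`/`sex` mapping passed to [aggregate_groups()].
#' @param cutoffs Optional fixed cut-offs.
#' @return See [mediscore()].
#' @export
score_diet <- function(ffq, catalog, sex, cutoffs = NULL,
                       mapping = FREQ_PER_DAY) {
  intakes <- item_daily_grams(ffq, catalog, mapping)
  groups <- aggregate_groups(intakes, catalog, sex)
  mediscore(groups, cutoffs)
}
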