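#' Read and validate a food-frequency questionnaire table
#'
#' Loads a long-format FFQ table (one row per subject x food item) and
#' validates every row against the nine canonical frequency categories and,
#' optionally, against a food catalog's item identifiers.
#'
#' @param path Path to a CSV file with columns `subject_id`, `item_id`,
#'   `frequency_category`, `servings_per_occasion`, `seasonal`.
#' @param item_catalog Optional food catalog (see [read_food_catalog()]);
#'   when supplied, every `item_id` must appear in it.
#' @return A data frame of validated responses, one row per answer.
#'   `seasonal` is logical, `servings_per_occasion` numeric and positive.
#' @seealso [frequency_levels()] for the legal category labels.
#' @export
read_ffq_table <- function(path, item_catalog = NULL) {
  df <- read_table_checked(path, c("subject_id", "item_id",
                                   "frequency_category",
                                   "servings_per_occasion", "seasonal"))
  validate_ffq(df, item_catalog)
}

validate_ffq <- function(df, item_catalog = NULL) {
  df$subject_id <- as.character(df$subject_id)
  df$item_id <- as.character(df$item_id)
  df$frequency_category <- as.character(df$frequency_category)
  df$servings_per_occasion <- as.numeric(df$servings_per_occasion)
  df$seasonal <- as_flag(df$seasonal, "seasonal")
  bad <- which(!(df$frequency_category %in% FREQ_LEVELS))
  if (length(bad)) {
    stop(sprintf("row %d: unknown frequency category %s", bad[1],
                 dQuote(df$frequency_category[bad[1]])), call. = FALSE)
  }
  bad <- which(!is.finite(df$servings_per_occasion) |
                 df$servings_per_occasion <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: servings_per_occasion must be a positive number",
                 bad[1]), call. = FALSE)
  }
  if (!is.null(item_catalog)) {
    bad <- which(!(df$item_id %in% item_catalog$item_id))
    if (length(bad)) {
      stop(sprintf("row %d: unknown item_id %s", bad[1],
                   dQuote(df$item_id[bad[1]])), call. = FALSE)
    }
  }
  df
}

#' Read a food composition and group-mapping catalog
#'
#' @param path CSV with columns `item_id`, `grams_per_serving`,
#'   `mufa_per_100g`, `sfa_per_100g`, `group`. `group` must be one of
#'   vegetables, legumes, fruits, cereals, fish, meat, dairy, alcohol,
#'   fat_only, other.
#' @return A validated data frame keyed by `item_id`.
#' @export
read_food_catalog <- function(path) {
  df <- read_table_checked(path, c("item_id", "grams_per_serving",
                                   "mufa_per_100g", "sfa_per_100g", "group"))
  validate_catalog(df)
}

validate_catalog <- function(df) {
  df$item_id <- as.character(df$item_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$item_id)) {
    stop("duplicated item_id in catalog: ",
         df$item_id[duplicated(df$item_id)][1], call. = FALSE)
  }
  bad <- which(!(df$group %in% DIET_GROUPS))
  if (length(bad)) {
    stop(sprintf("row %d: unknown food group %s", bad[1],
                 dQuote(df$group[bad[1]])), call. = FALSE)
  }
  stopifnot(all(df$grams_per_serving > 0),
            all(df$mufa_per_100g >= 0), all(df$sfa_per_100g >= 0))
  df
}

#' Read a variant-weight table
#'
#' The weight table carries, per variant, the risk allele and its per-allele
#' log odds ratio, plus a flag for the five major risk variants whose
#' complete genotyping is required for a valid genetic risk score.
#'
#' @param path CSV with columns `variant_id`, `risk_allele`, `beta`,
#'   `is_major`.
#' @param canonical If `TRUE`, enforce the canonical-table invariants:
#'   exactly 52 variants, exactly 5 of them flagged major. Leave `FALSE`
#'   for reduced tables (toy examples, subsets).
#' @return A validated data frame keyed by `variant_id`.
#' @export
read_variant_weights <- function(path, canonical = FALSE) {
  df <- read_table_checked(path, c("variant_id", "risk_allele", "beta",
                                   "is_major"))
  validate_weights(df, canonical)
}

validate_weights <- function(df, canonical = FALSE) {
  df$variant_id <- as.character(df$variant_id)
  df$risk_allele <- toupper(as.character(df$risk_allele))
  df$beta <- as.numeric(df$beta)
  df$is_major <- as_flag(df$is_major, "is_major")
  if (anyDuplicated(df$variant_id)) {
    stop("duplicated variant_id in weights: ",
         df$variant_id[duplicated(df$variant_id)][1], call. = FALSE)
  }
  if (!all(grepl("^[ACGT]+$", df$risk_allele))) {
    stop("risk_allele must be a nucleotide or indel string (A/C/G/T)",
         call. = FALSE)
  }
  if (any(!is.finite(df$beta))) stop("non-finite beta in weights",
                                     call. = FALSE)
  if (canonical) {
    if (nrow(df) != 52) stop("canonical weight table must have 52 variants, got ",
                             nrow(df), call. = FALSE)
    if (sum(df$is_major) != 5) stop("canonical weight table must flag 5 major variants, got ",
                                    sum(df$is_major), call. = FALSE)
  }
  df
}

#' Read a genotype matrix from VCF or CSV
#'
#' Genotypes are returned as risk-allele counts in \{0, 1, 2, NA\}, oriented
#' against the `risk_allele` of the weight table -- never assumed to be the
#' ALT allele. For CSV input the file is one column per variant
#' (`subject_id` first), values already risk-oriented 0/1/2/NA.
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file or a CSV count matrix.
#' @param weights Variant-weight table ([read_variant_weights()]).
#' @return Integer matrix, subjects x variants, dimnames set; entries in
#'   \{0, 1, 2, NA\}.
#' @details VCF handling: VCFv4.x, `GT` field only (phased `|` and unphased
#'   `/` separators both accepted; dosage fields ignored). A VCF variant
#'   absent from `weights` is skipped with a warning; a genotype whose
#'   alleles cannot be resolved against REF/ALT, or a risk allele matching
#'   neither REF nor ALT, yields `NA`.
#' @export
read_genotypes <- function(path, weights) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotype_vcf(path, weights)
  } else {
    read_genotype_csv(path, weights)
  }
}

#' @rdname read_genotypes
#' @export
read_genotype_csv <- function(path, weights) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id") {
    stop("genotype CSV must have subject_id as its first column",
         call. = FALSE)
  }
  ids <- as.character(df$subject_id)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  unknown <- setdiff(colnames(mat), weights$variant_id)
  if (length(unknown)) {
    warning("skipping variants absent from weights: ",
            paste(unknown, collapse = ", "))
    mat <- mat[, setdiff(colnames(mat), unknown), drop = FALSE]
  }
  bad <- !(mat %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    stop("genotype counts must be 0, 1, 2 or NA; first offending value: ",
         mat[which(bad)[1]], call. = FALSE)
  }
  mat
}

#' @rdname read_genotypes
#' @export
read_genotype_vcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- ids %in% weights$variant_id
  if (any(!keep)) {
    warning("skipping variants absent from weights: ",
            paste(ids[!keep], collapse = ", "))
  }
  subjects <- colnames(gt)
  out <- matrix(NA_integer_, nrow = length(subjects), ncol = sum(keep),
                dimnames = list(subjects, ids[keep]))
  for (j in which(keep)) {
    risk <- toupper(weights$risk_allele[match(ids[j], weights$variant_id)])
    alleles <- toupper(c(fix[j, "REF"],
                         strsplit(fix[j, "ALT"], ",", fixed = TRUE)[[1]]))
    risk_idx <- which(alleles == risk) - 1L   # VCF allele index (0 = REF)
    out[, ids[j]] <- count_risk_alleles(gt[j, ], risk_idx)
  }
  out
}

# Count occurrences of the risk allele index in GT strings like "0/1", "1|1",
# "./.". Unresolvable calls (missing, malformed, haploid) or an empty
# risk_idx (risk allele matches neither REF nor ALT) give NA.
count_risk_alleles <- function(gt, risk_idx) {
  vapply(gt, function(g) {
    if (length(risk_idx) != 1L || is.na(g)) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2L || any(parts == ".")) return(NA_integer_)
    idx <- suppressWarnings(as.integer(parts))
    if (any(is.na(idx))) return(NA_integer_)
    sum(idx == risk_idx)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read and validate a phenotype table
#'
#' @param path CSV with columns `subject_id`, `age`, `sex`, `smoking`,
#'   `exercise`, `stage_right`, `stage_left`. Stages are Rotterdam stages
#'   (0, 1, 2a, 2b, 3, 4) or missing (`NA`/empty) for an ungradable eye.
#' @return Validated data frame; `sex` and `smoking` as factors, `exercise`
#'   logical, stages as character with `NA` for ungradable eyes.
#' @details Enforced invariants: enrolment age at least 55 years; at least
#'   one gradable eye per subject.
#' @export
read_phenotypes <- function(path) {
  df <- read_table_checked(path, c("subject_id", "age", "sex", "smoking",
                                   "exercise", "stage_right", "stage_left"))
  validate_phenotypes(df)
}

validate_phenotypes <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  df$age <- as.numeric(df$age)
  df$sex <- canonical_level(df$sex, SEX_LEVELS, "sex")
  df$smoking <- canonical_level(df$smoking, SMOKING_LEVELS, "smoking")
  df$exercise <- as_flag(df$exercise, "exercise")
  df$stage_right <- canonical_stage(df$stage_right)
  df$stage_left <- canonical_stage(df$stage_left)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1], call. = FALSE)
  }
  bad <- which(!is.finite(df$age) | df$age < 55)
  if (length(bad)) {
    stop(sprintf("row %d: age %s is below the enrolment floor of 55",
                 bad[1], df$age[bad[1]]), call. = FALSE)
  }
  bad <- which(is.na(df$stage_right) & is.na(df$stage_left))
  if (length(bad)) {
    stop(sprintf("row %d: subject %s has no gradable eye", bad[1],
                 df$subject_id[bad[1]]), call. = FALSE)
  }
  df
}

canonical_stage <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x[x %in% c("", "na", "missing")] <- NA_character_
  bad <- which(!is.na(x) & !(x %in% ROTTERDAM_STAGES))
  if (length(bad)) {
    stop(sprintf("row %d: unknown Rotterdam stage %s", bad[1],
                 dQuote(x[bad[1]])), call. = FALSE)
  }
  x
}

canonical_level <- function(x, levels, what) {
  x <- trimws(tolower(as.character(x)))
  bad <- which(!(x %in% levels))
  if (length(bad)) {
    stop(sprintf("row %d: %s must be one of %s, got %s", bad[1], what,
                 paste(levels, collapse = "/"), dQuote(x[bad[1]])),
         call. = FALSE)
  }
  factor(x, levels = levels)
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "0")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("column %s: cannot interpret %s as TRUE/FALSE", what,
                 dQuote(x[which(is.na(out))[1]])), call. = FALSE)
  }
  out
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write pipeline tables to CSV
#'
#' Plain `write.csv` wrappers kept as named entry points so that a written
#' table reads back field-for-field through the matching reader.
#'
#' @param df Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @param mat Genotype count matrix (subjects x variants).
#' @export
write_genotype_csv <- function(mat, path) {
  df <- data.frame(subject_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The nine canonical FFQ frequency categories
#'
#' @return Character vector of the nine legal frequency labels, ordered from
#'   least to most frequent.
#' @export
frequency_levels <- function() FREQ_LEVELS
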