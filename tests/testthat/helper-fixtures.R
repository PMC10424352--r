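# Small in-code fixtures shared across tests.

# One item per scored food group plus two fat-only items; 100 g servings
# except alcohol (grams of ethanol per serving) and the fats.
toy_catalog <- function() {
  data.frame(
    item_id = c("veg", "leg", "fru", "cer", "fis", "mea", "dai", "alc",
                "oil", "but"),
    grams_per_serving = c(rep(100, 7), 10, 10, 10),
    mufa_per_100g = c(rep(0, 7), 0, 80, 20),
    sfa_per_100g = c(rep(0, 7), 0, 10, 60),
    group = c("vegetables", "legumes", "fruits", "cereals", "fish",
              "meat", "dairy", "alcohol", "fat_only", "fat_only"),
    stringsAsFactors = FALSE)
}

ffq_row <- function(subject, item, freq = "1 time/day", servings = 1,
                    seasonal = FALSE) {
  data.frame(subject_id = subject, item_id = item,
             frequency_category = freq, servings_per_occasion = servings,
             seasonal = seasonal, stringsAsFactors = FALSE)
}

# Group-intake table built directly (bypassing the FFQ), for scoring tests.
toy_group_intake <- function(subject_id, sex, vegetables = 0, legumes = 0,
                             fruits = 0, cereals = 0, fish = 0, meat = 0,
                             dairy = 0, alcohol = 0, mufa_sfa_ratio = 1) {
  data.frame(subject_id = subject_id, vegetables = vegetables,
             legumes = legumes, fruits = fruits, cereals = cereals,
             fish = fish, meat = meat, dairy = dairy, alcohol = alcohol,
             mufa_sfa_ratio = mufa_sfa_ratio,
             sex = factor(sex, levels = c("female", "male")),
             stringsAsFactors = FALSE)
}

# Minimal weight table; two majors keep the exclusion rule testable.
toy_weights <- function() {
  data.frame(variant_id = c("rs570618", "rs3750846", "v1", "v2"),
             risk_allele = c("T", "T", "A", "G"),
             beta = c(0.9, 1.0, 0.5, -0.2),
             is_major = c(TRUE, TRUE, FALSE, FALSE),
             stringsAsFactors = FALSE)
}

toy_genotypes <- function(counts, subjects = NULL,
                          variants = toy_weights()$variant_id) {
  m <- matrix(as.integer(counts), ncol = length(variants), byrow = TRUE)
  if (is.null(subjects)) subjects <- sprintf("P%02d", seq_len(nrow(m)))
  dimnames(m) <- list(subjects, variants)
  m
}

# Eye-level records with independent subjects (one eye each) built from a
# 2x2 exposure/outcome layout, for GEE cross-checks against glm().
records_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    outcome = rep(c(1L, 0L, 1L, 0L), c(a, b, c_, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c_, d)))
}

# A small but well-behaved synthetic analysis cohort, cached per session.
small_records <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(cohort_config(n_subjects = 500), seed = 2024)
      diet <- score_diet(co$ffq, co$catalog,
                         sex = co$phenotypes[c("subject_id", "sex")])
      grs <- dichotomize_grs(compute_grs(co$genotypes, co$weights))
      cache <<- build_eye_records(co$phenotypes, grs, diet)
    }
    cache
  }
})
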