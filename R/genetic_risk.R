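#' Compute the weighted genetic risk score
#'
#' GRS = sum over variants of (risk-allele count x per-allele log odds
#' ratio). Missing genotypes are never imputed: a subject missing any of the
#' five major risk variants gets a null (NA) score and is excluded from
#' downstream analysis; a missing non-major variant simply contributes
#' nothing, and the per-subject count of missing variants is reported so
#' heavy missingness can be filtered downstream.
#'
#' @param genotypes Risk-allele count matrix (subjects x variants), entries
#'   in \{0, 1, 2, NA\} ([read_genotypes()]).
#' @param weights Variant-weight table ([read_variant_weights()]); must
#'   cover every matrix column.
#' @return Data frame: `subject_id`, `grs` (NA when excluded),
#'   `n_missing_variants`, `included`.
#' @export
compute_grs <- function(genotypes, weights) {
  unknown <- setdiff(colnames(genotypes), weights$variant_id)
  if (length(unknown)) {
    stop("variants without weights: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  w <- weights[match(colnames(genotypes), weights$variant_id), ]
  counts <- genotypes
  miss <- is.na(counts)
  counts[miss] <- 0L
  grs <- as.numeric(counts %*% w$beta)
  major_cols <- which(w$is_major)
  major_missing <- if (length(major_cols)) {
    rowSums(miss[, major_cols, drop = FALSE]) > 0
  } else {
    rep(FALSE, nrow(genotypes))
  }
  grs[major_missing] <- NA_real_
  data.frame(subject_id = rownames(genotypes),
             grs = grs,
             n_missing_variants = as.integer(rowSums(miss)),
             included = !major_missing,
             stringsAsFactors = FALSE)
}

#' Dichotomize genetic risk scores at the population median
#'
#' The median is computed over included subjects only (midpoint convention
#' for even counts); a score equal to or above the median is high risk.
#'
#' @param results Output of [compute_grs()].
#' @return `results` with columns `high_grs` (NA for excluded subjects) and
#'   an attribute `"median_grs"` recording the cut point.
#' @export
dichotomize_grs <- function(results) {
  inc <- results$included
  if (!any(inc)) stop("no included subjects to compute the GRS median",
                      call. = FALSE)
  m <- stats::median(results$grs[inc])
  results$high_grs <- ifelse(inc, results$grs >= m, NA)
  attr(results, "median_grs") <- m
  results
}
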