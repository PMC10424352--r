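#' Recode the diet score so low adherence is the risk factor
#'
#' Additive interaction measures are defined for risk factors, so the
#' protective high-adherence indicator is flipped into a low-adherence
#' indicator; the joint reference category becomes (high adherence, low
#' genetic risk). Applying the function twice restores the original
#' coding.
#'
#' @param records Eye-level records with a `high_mediscore` (or, already
#'   recoded, `low_mediscore`) logical column.
#' @return The records with the diet indicator flipped.
#' @export
recode_protective <- function(records) {
  if ("low_mediscore" %in% names(records)) {
    records$high_mediscore <- !records$low_mediscore
    records$low_mediscore <- NULL
  } else if ("high_mediscore" %in% names(records)) {
    records$low_mediscore <- !records$high_mediscore
    records$high_mediscore <- NULL
  } else {
    stop("records carry neither high_mediscore nor low_mediscore",
         call. = FALSE)
  }
  records
}

#' Fit the adjusted eye-level exposure model
#'
#' The canonical model of the analysis: eye-level AMD outcome on the
#' dichotomized genetic risk score and Mediterranean-diet adherence,
#' adjusted for age band, sex, smoking and physical exercise, fitted by
#' logistic GEE with exchangeable inter-eye correlation. Without the
#' interaction term the diet enters in its protective coding
#' (`high_mediscore`); with it, in the risk coding (`low_mediscore`), so
#' the joint reference is (high adherence, low genetic risk).
#'
#' @param records Eye-level records from [build_eye_records()].
#' @param include_interaction Add the GRS x diet product term?
#' @param ... Passed to [eyegee()].
#' @return An [eyegee()] fit.
#' @export
amd_gee <- function(records, include_interaction = TRUE, ...) {
  d <- records
  d$high_grs <- as.numeric(d$high_grs)
  if (include_interaction) {
    if (!("low_mediscore" %in% names(d))) d <- recode_protective(d)
    d$low_mediscore <- as.numeric(d$low_mediscore)
    f <- outcome ~ high_grs * low_mediscore + age_cat + sex + smoking +
      exercise
  } else {
    if (!("high_mediscore" %in% names(d))) d <- recode_protective(d)
    d$high_mediscore <- as.numeric(d$high_mediscore)
    f <- outcome ~ high_grs + high_mediscore + age_cat + sex + smoking +
      exercise
  }
  eyegee(f, id = subject_id, data = d, ...)
}

# Locate the exposure terms of an interaction fit.
interaction_terms <- function(fit) {
  nm <- names(fit$coefficients)
  g <- match("high_grs", nm)
  d <- match("low_mediscore", nm)
  gd <- grep(":", nm)
  if (is.na(g) || is.na(d) || length(gd) != 1L) {
    stop("fit must carry high_grs, low_mediscore and their product term ",
         "(use amd_gee(records, include_interaction = TRUE))",
         call. = FALSE)
  }
  c(g = g, d = d, gd = gd)
}

# Delta-method OR for a linear combination L'beta of the fit coefficients.
lincomb_or <- function(fit, L, level = 0.95) {
  est <- sum(L * fit$coefficients)
  se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(est), lower = exp(est - z * se), upper = exp(est + z * se),
    p = if (se > 0) 2 * stats::pnorm(-abs(est / se)) else NA_real_)
}

#' Joint-exposure odds ratios with a single reference category
#'
#' From an interaction fit, the odds ratios of the three exposed strata
#' against the joint reference (high adherence, low genetic risk):
#' `or01` = high GRS alone = exp(beta_G); `or10` = low adherence alone =
#' exp(beta_D); `or11` = both = exp(beta_G + beta_D + beta_GD).
#' Confidence intervals are Wald intervals on each linear combination
#' using the robust covariance.
#'
#' @param fit An interaction [amd_gee()] fit.
#' @param level Confidence level.
#' @return Object of class `joint_ors`: a data frame of the three ORs with
#'   CI and p, carrying the exposure coefficients and their covariance as
#'   attributes for downstream measures.
#' @export
joint_odds_ratios <- function(fit, level = 0.95) {
  idx <- interaction_terms(fit)
  p <- length(fit$coefficients)
  L01 <- replace(numeric(p), idx["g"], 1)
  L10 <- replace(numeric(p), idx["d"], 1)
  L11 <- replace(numeric(p), idx, 1)
  tab <- rbind(or01 = lincomb_or(fit, L01, level),
               or10 = lincomb_or(fit, L10, level),
               or11 = lincomb_or(fit, L11, level))
  out <- data.frame(
    exposure = c("high GRS, high mediSCORE", "low GRS, low mediSCORE",
                 "high GRS, low mediSCORE"),
    tab, stringsAsFactors = FALSE)
  attr(out, "beta") <- fit$coefficients[idx]
  attr(out, "vcov") <- fit$vcov[idx, idx]
  class(out) <- c("joint_ors", "data.frame")
  out
}

#' Interaction on the multiplicative scale
#'
#' The multiplicative interaction odds ratio exp(beta_GD) =
#' OR11 / (OR01 x OR10), with robust Wald CI and p (null value 1: the
#' joint effect equals the product of the single-exposure effects).
#'
#' @param fit An interaction [amd_gee()] fit.
#' @param level Confidence level.
#' @return Named vector `or`, `lower`, `upper`, `p`.
#' @export
multiplicative_measure <- function(fit, level = 0.95) {
  idx <- interaction_terms(fit)
  L <- replace(numeric(length(fit$coefficients)), idx["gd"], 1)
  lincomb_or(fit, L, level)
}

#' Additive interaction measures from three joint-exposure odds ratios
#'
#' RERI = OR11 - OR01 - OR10 + 1 (relative excess risk due to
#' interaction), AP = RERI / OR11 (attributable proportion), and
#' SI = (OR11 - 1) / ((OR01 - 1) + (OR10 - 1)) (synergy index). Under
#' pure additivity RERI = AP = 0 and SI = 1.
#'
#' @param or11,or01,or10 Odds ratios of the jointly and singly exposed
#'   strata versus the joint reference; alternatively pass a
#'   [joint_odds_ratios()] object as `or11`.
#' @return List `reri`, `ap`, `si` (`si` is `NA` with flag
#'   `si_undefined = TRUE` when its denominator is zero).
#' @export
interaction_from_ors <- function(or11, or01 = NULL, or10 = NULL) {
  if (inherits(or11, "joint_ors")) {
    j <- or11
    or11 <- j["or11", "or"]
    or01 <- j["or01", "or"]
    or10 <- j["or10", "or"]
  }
  stopifnot(or11 > 0, or01 > 0, or10 > 0)
  reri <- or11 - or01 - or10 + 1
  ap <- reri / or11
  denom <- (or01 - 1) + (or10 - 1)
  if (denom == 0) {
    list(reri = reri, ap = ap, si = NA_real_, si_undefined = TRUE)
  } else {
    list(reri = reri, ap = ap, si = (or11 - 1) / denom,
         si_undefined = FALSE)
  }
}

#' @rdname interaction_from_ors
#' @export
additive_measures <- interaction_from_ors

# Analytic gradients of RERI, AP and log SI with respect to
# (beta_G, beta_D, beta_GD).
reri_gradient <- function(b) {
  E <- exp(sum(b))
  c(E - exp(b[1]), E - exp(b[2]), E)
}
ap_gradient <- function(b) {
  Em <- exp(-sum(b))
  c(exp(-(b[1] + b[3])) - Em,
    exp(-(b[2] + b[3])) - Em,
    exp(-(b[1] + b[3])) + exp(-(b[2] + b[3])) - Em)
}
logsi_gradient <- function(b) {
  E <- exp(sum(b))
  denom <- exp(b[1]) + exp(b[2]) - 2
  c(E / (E - 1) - exp(b[1]) / denom,
    E / (E - 1) - exp(b[2]) / denom,
    E / (E - 1))
}

#' Delta-method confidence intervals for RERI, AP and SI
#'
#' Each measure is a smooth function of the exposure coefficients
#' (beta_G, beta_D, beta_GD); its variance follows by first-order Taylor
#' propagation of the robust covariance. RERI and AP are handled on their
#' natural scales against a null of 0; the synergy index is handled on the
#' log scale (CI back-transformed, p against log SI = 0), which is what
#' lets SI reach significance when RERI and AP do not.
#'
#' @param fit An interaction [amd_gee()] fit.
#' @param level Confidence level.
#' @return Data frame `measure`, `estimate`, `lower`, `upper`, `p`.
#' @export
delta_cis <- function(fit, level = 0.95) {
  idx <- interaction_terms(fit)
  b <- unname(fit$coefficients[idx])
  V <- fit$vcov[idx, idx]
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("robust covariance is not positive semidefinite", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- interaction_from_ors(exp(sum(b)), exp(b[1]), exp(b[2]))
  dm_row <- function(name, est, grad) {
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    data.frame(measure = name, estimate = est, lower = est - z * se,
               upper = est + z * se,
               p = if (se > 0) 2 * stats::pnorm(-abs(est / se)) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(dm_row("reri", m$reri, reri_gradient(b)),
               dm_row("ap", m$ap, ap_gradient(b)))
  E <- exp(sum(b))
  denom <- exp(b[1]) + exp(b[2]) - 2
  if (E > 1 && denom > 0) {
    g <- logsi_gradient(b)
    se <- sqrt(drop(t(g) %*% V %*% g))
    lsi <- log(m$si)
    si_row <- data.frame(measure = "si", estimate = m$si,
                         lower = exp(lsi - z * se),
                         upper = exp(lsi + z * se),
                         p = if (se > 0) 2 * stats::pnorm(-abs(lsi / se))
                         else NA_real_,
                         stringsAsFactors = FALSE)
  } else {
    si_row <- data.frame(measure = "si", estimate = m$si, lower = NA_real_,
                         upper = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE)
  }
  rbind(out, si_row)
}

#' Cluster-bootstrap confidence intervals for RERI, AP and SI
#'
#' Subjects (clusters) are resampled with replacement, both eyes carried
#' together; the full GEE interaction model is refitted on each replicate
#' and the three measures recomputed. Percentile intervals are taken over
#' converged replicates.
#'
#' @param records Eye-level records (any diet coding).
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed for the resampling.
#' @param level Confidence level.
#' @return Data frame `measure`, `estimate`, `lower`, `upper` with
#'   attributes `n_failed` (non-converged or failed refits, reported and
#'   warned about when above 20%) and `replicates` (the raw draws).
#' @export
bootstrap_cis <- function(records, n_boot = 2000, seed = NULL,
                          level = 0.95) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (!("low_mediscore" %in% names(records))) {
    records <- recode_protective(records)
  }
  subjects <- unique(records$subject_id)
  by_subject <- split(seq_len(nrow(records)), records$subject_id)
  fit0 <- amd_gee(records)
  m0 <- interaction_from_ors(joint_odds_ratios(fit0))
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("reri", "ap", "si")))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(subjects, length(subjects), replace = TRUE)
    rows <- unlist(by_subject[take], use.names = FALSE)
    boot <- records[rows, ]
    # resampled clusters must stay distinct
    boot$subject_id <- rep(seq_along(take),
                           lengths(by_subject[take]))
    res <- tryCatch(suppressWarnings({
      fit <- amd_gee(boot)
      if (!fit$converged) stop("not converged")
      interaction_from_ors(joint_odds_ratios(fit))
    }), error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- c(res$reri, res$ap, res$si)
    }
  }
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, n_boot))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(draws, 2, stats::quantile, probs = probs, na.rm = TRUE,
              names = FALSE)
  out <- data.frame(measure = colnames(draws),
                    estimate = c(m0$reri, m0$ap, m0$si),
                    lower = qs[1, ], upper = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_failed") <- n_failed
  attr(out, "replicates") <- draws
  out
}

#' Within-stratum odds ratios for each exposure
#'
#' From the interaction fit: the diet (low-adherence) OR within each GRS
#' stratum -- exp(beta_D) at low genetic risk, exp(beta_D + beta_GD) at
#' high -- and the GRS OR within each diet stratum. Because high adherence
#' is protective, forest plots conventionally show the protective
#' direction: `protective_or` gives the reciprocal (the OR for *high*
#' adherence within the stratum), with the CI flipped accordingly. When
#' `records` is supplied, each stratum is also refitted on its subset as
#' an independent route to the same quantity.
#'
#' @param fit An interaction [amd_gee()] fit.
#' @param records Optional eye-level records for the refit route.
#' @param level Confidence level.
#' @return Data frame: `exposure`, `stratum`, `or`, `lower`, `upper`,
#'   `p`, `protective_or`, `protective_lower`, `protective_upper`, and
#'   (when refitted) `or_refit`.
#' @export
stratified_ors <- function(fit, records = NULL, level = 0.95) {
  idx <- interaction_terms(fit)
  p <- length(fit$coefficients)
  combos <- list(
    c(exposure = "low_mediscore", stratum = "low GRS"),
    c(exposure = "low_mediscore", stratum = "high GRS"),
    c(exposure = "high_grs", stratum = "high mediSCORE"),
    c(exposure = "high_grs", stratum = "low mediSCORE"))
  Ls <- list(
    replace(numeric(p), idx["d"], 1),
    replace(numeric(p), c(idx["d"], idx["gd"]), 1),
    replace(numeric(p), idx["g"], 1),
    replace(numeric(p), c(idx["g"], idx["gd"]), 1))
  rows <- lapply(seq_along(combos), function(i) {
    est <- lincomb_or(fit, Ls[[i]], level)
    data.frame(exposure = combos[[i]][["exposure"]],
               stratum = combos[[i]][["stratum"]],
               or = est[["or"]], lower = est[["lower"]],
               upper = est[["upper"]], p = est[["p"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$protective_or <- 1 / out$or
  out$protective_lower <- 1 / out$upper
  out$protective_upper <- 1 / out$lower
  if (!is.null(records)) {
    if (!("low_mediscore" %in% names(records))) {
      records <- recode_protective(records)
    }
    refit_or <- function(subset, term) {
      d <- subset
      d$high_grs <- as.numeric(d$high_grs)
      d$low_mediscore <- as.numeric(d$low_mediscore)
      f <- stats::reformulate(c(term, "age_cat", "sex", "smoking",
                                "exercise"), response = "outcome")
      ft <- tryCatch(suppressWarnings(
        eyegee(f, id = subject_id, data = d)), error = function(e) NULL)
      if (is.null(ft)) NA_real_ else exp(ft$coefficients[[term]])
    }
    out$or_refit <- c(
      refit_or(records[!records$high_grs, ], "low_mediscore"),
      refit_or(records[records$high_grs, ], "low_mediscore"),
      refit_or(records[!records$low_mediscore, ], "high_grs"),
      refit_or(records[records$low_mediscore, ], "high_grs"))
  }
  out
}

#' Full interaction analysis in the Knol-VanderWeele layout
#'
#' Fits the adjusted interaction model and assembles joint-exposure ORs
#' with a single reference category, within-stratum ORs, the
#' multiplicative interaction OR, and RERI/AP/SI with delta-method (and,
#' optionally, cluster-bootstrap) confidence intervals.
#'
#' @param records Eye-level records from [build_eye_records()].
#' @param n_boot Bootstrap replicates for the additive measures; 0 skips
#'   the bootstrap.
#' @param seed Seed for the bootstrap resampling.
#' @param level Confidence level.
#' @return Object of class `interaction_report` with elements `fit`,
#'   `joint`, `stratified`, `multiplicative`, `additive_delta`,
#'   `additive_boot` (or `NULL`).
#' @export
interaction_report <- function(records, n_boot = 0, seed = NULL,
                               level = 0.95) {
  if (!("low_mediscore" %in% names(records))) {
    records <- recode_protective(records)
  }
  fit <- amd_gee(records, include_interaction = TRUE)
  joint <- joint_odds_ratios(fit, level)
  structure(list(
    fit = fit,
    joint = joint,
    stratified = stratified_ors(fit, records, level),
    multiplicative = multiplicative_measure(fit, level),
    additive_delta = delta_cis(fit, level),
    additive_boot = if (n_boot > 0) {
      bootstrap_cis(records, n_boot, seed, level)
    }
  ), class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, digits = 3, ...) {
  fmt <- function(or, lo, hi, p) {
    sprintf("%.*f (%.*f-%.*f)%s", digits, or, digits, lo, digits, hi,
            ifelse(is.na(p), "", sprintf("; p = %.3f", p)))
  }
  cat("Gene-diet interaction report (joint reference: high mediSCORE, ",
      "low GRS)\n\n", sep = "")
  cat("Joint-exposure odds ratios:\n")
  j <- x$joint
  for (i in seq_len(nrow(j))) {
    cat(sprintf("  %-28s %s\n", j$exposure[i],
                fmt(j$or[i], j$lower[i], j$upper[i], j$p[i])))
  }
  cat("\nWithin-stratum odds ratios (risk coding):\n")
  s <- x$stratified
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s within %-15s %s\n", s$exposure[i], s$stratum[i],
                fmt(s$or[i], s$lower[i], s$upper[i], s$p[i])))
  }
  m <- x$multiplicative
  cat("\nMultiplicative interaction OR: ",
      fmt(m[["or"]], m[["lower"]], m[["upper"]], m[["p"]]), "\n", sep = "")
  cat("\nAdditive interaction (delta method):\n")
  d <- x$additive_delta
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-5s %s\n", toupper(d$measure[i]),
                fmt(d$estimate[i], d$lower[i], d$upper[i], d$p[i])))
  }
  if (!is.null(x$additive_boot)) {
    b <- x$additive_boot
    cat("\nAdditive interaction (percentile bootstrap, ",
        nrow(attr(b, "replicates")), " replicates):\n", sep = "")
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %-5s %s\n", toupper(b$measure[i]),
                  fmt(b$estimate[i], b$lower[i], b$upper[i], NA)))
    }
  }
  invisible(x)
}

#' Forest plot of within-stratum diet effects
#'
#' Draws the protective-direction odds ratios for high Mediterranean-diet
#' adherence within each genetic-risk stratum on a log scale, the layout
#' used to show effect modification of a protective exposure.
#'
#' @param x An `interaction_report`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.interaction_report <- function(x, ...) {
  s <- x$stratified[x$stratified$exposure == "low_mediscore", ]
  or <- s$protective_or
  lo <- s$protective_lower
  hi <- s$protective_upper
  ypos <- rev(seq_len(nrow(s)))
  old <- graphics::par(mar = c(4, 9, 2, 2))
  on.exit(graphics::par(old))
  plot(or, ypos, xlim = range(c(lo, hi, 1)), ylim = c(0.5, nrow(s) + 0.5),
       log = "x", pch = 15, yaxt = "n", xlab = "OR for high adherence",
       ylab = "", main = "Diet effect by genetic-risk stratum")
  graphics::segments(lo, ypos, hi, ypos)
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = ypos, labels = paste("within", s$stratum),
                 las = 1)
  invisible(x)
}
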