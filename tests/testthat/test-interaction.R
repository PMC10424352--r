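test_that("protective recoding flips the diet indicator and is an involution", {
  rec <- data.frame(subject_id = 1:4, high_mediscore = c(TRUE, FALSE,
                                                         TRUE, TRUE))
  r1 <- recode_protective(rec)
  expect_identical(r1$low_mediscore, c(FALSE, TRUE, FALSE, FALSE))
  expect_null(r1$high_mediscore)
  expect_identical(recode_protective(r1)$high_mediscore,
                   rec$high_mediscore)
})

test_that("joint odds ratios combine the exposure coefficients", {
  rec <- small_records()
  fit <- amd_gee(rec)
  j <- joint_odds_ratios(fit)
  b <- coef(fit)
  bg <- b[["high_grs"]]
  bd <- b[["low_mediscore"]]
  bgd <- b[["high_grs:low_mediscore"]]
  expect_equal(j["or01", "or"], exp(bg))
  expect_equal(j["or10", "or"], exp(bd))
  expect_equal(j["or11", "or"], exp(bg + bd + bgd))
  # identity: multiplicative OR equals or11/(or01*or10) to machine precision
  m <- multiplicative_measure(fit)
  expect_equal(m[["or"]], j["or11", "or"] / (j["or01", "or"] * j["or10", "or"]))
  expect_equal(m[["or"]], exp(bgd))
  # a fit without an interaction term is refused
  expect_error(joint_odds_ratios(amd_gee(rec, include_interaction = FALSE)),
               "product term")
})

test_that("additive measures satisfy their defining identities", {
  # no interaction on the multiplicative scale: ORs multiply
  m <- interaction_from_ors(or11 = 6, or01 = 2, or10 = 3)
  expect_equal(m$reri, 6 - 2 - 3 + 1)
  expect_equal(m$ap, m$reri / 6)
  expect_equal(m$si, 5 / 3)
  # all nulls
  m0 <- interaction_from_ors(1, 1, 1)
  expect_equal(m0$reri, 0)
  expect_true(m0$si_undefined)
  # hand-composed coefficients mirror the published-style arithmetic
  or11 <- exp(0.581 + 0.845 + 0.105)
  expect_equal(or11, 4.623, tolerance = 2e-4)
  # AP sign always follows RERI when or11 > 0
  set.seed(41)
  for (i in 1:50) {
    ors <- exp(rnorm(3, 0, 1))
    m <- interaction_from_ors(ors[1], ors[2], ors[3])
    expect_equal(sign(m$ap), sign(m$reri))
  }
})

test_that("delta-method gradients match finite differences", {
  set.seed(42)
  for (i in 1:10) {
    b <- rnorm(3, 0.5, 0.4)
    fd <- function(f) {
      h <- 1e-6
      vapply(1:3, function(k) {
        bp <- b; bm <- b
        bp[k] <- bp[k] + h; bm[k] <- bm[k] - h
        (f(bp) - f(bm)) / (2 * h)
      }, numeric(1))
    }
    reri_fn <- function(b) exp(sum(b)) - exp(b[1]) - exp(b[2]) + 1
    ap_fn <- function(b) reri_fn(b) / exp(sum(b))
    lsi_fn <- function(b) log(exp(sum(b)) - 1) -
      log(exp(b[1]) + exp(b[2]) - 2)
    expect_equal(eyegee:::reri_gradient(b), fd(reri_fn), tolerance = 1e-6)
    expect_equal(eyegee:::ap_gradient(b), fd(ap_fn), tolerance = 1e-6)
    if (exp(sum(b)) > 1 && exp(b[1]) + exp(b[2]) > 2) {
      expect_equal(eyegee:::logsi_gradient(b), fd(lsi_fn),
                   tolerance = 1e-6)
    }
  }
})

test_that("delta CIs collapse to points under a zero covariance", {
  rec <- small_records()
  fit <- amd_gee(rec)
  fit$vcov[] <- 0
  d <- delta_cis(fit)
  expect_equal(d$lower, d$estimate)
  expect_equal(d$upper, d$estimate)
})

test_that("bootstrap CIs are seed-reproducible and smoke at n_boot = 2", {
  rec <- small_records()
  b1 <- bootstrap_cis(rec, n_boot = 20, seed = 99)
  b2 <- bootstrap_cis(rec, n_boot = 20, seed = 99)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$upper))
  expect_identical(colnames(attr(b1, "replicates")),
                   c("reri", "ap", "si"))
  b3 <- bootstrap_cis(rec, n_boot = 2, seed = 1)
  expect_equal(nrow(b3), 3)
  expect_error(bootstrap_cis(rec, n_boot = 1), "n_boot")
})

test_that("stratified ORs derive from the interaction coefficients", {
  rec <- small_records()
  fit <- amd_gee(rec)
  s <- stratified_ors(fit, rec)
  b <- coef(fit)
  bd <- b[["low_mediscore"]]
  bgd <- b[["high_grs:low_mediscore"]]
  expect_equal(s$or[s$exposure == "low_mediscore" &
                      s$stratum == "low GRS"], exp(bd))
  expect_equal(s$or[s$exposure == "low_mediscore" &
                      s$stratum == "high GRS"], exp(bd + bgd))
  # protective direction is the exact reciprocal with a flipped interval
  expect_equal(s$protective_or, 1 / s$or)
  expect_equal(s$protective_lower, 1 / s$upper)
  # the stratum-refit route lands near the linear-combination route
  expect_equal(log(s$or_refit), log(s$or), tolerance = 0.35)
  expect_true(all(sign(log(s$or_refit)) == sign(log(s$or))))
})

test_that("the interaction report assembles all layers coherently", {
  rec <- small_records()
  rep <- interaction_report(rec, n_boot = 10, seed = 3)
  expect_s3_class(rep, "interaction_report")
  m <- interaction_from_ors(rep$joint)
  d <- rep$additive_delta
  expect_equal(d$estimate[d$measure == "reri"], m$reri)
  expect_equal(d$estimate[d$measure == "ap"], m$ap)
  expect_equal(d$estimate[d$measure == "si"], m$si)
  expect_output(print(rep), "Joint-exposure odds ratios")
  # forest plot renders without error
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(rep))
})
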