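test_that("frequency categories map to midpoint occasions/day", {
  expect_equal(frequency_to_daily("1 time/day"), 1)
  expect_equal(frequency_to_daily("never or less than 1 time/month"), 0)
  expect_equal(frequency_to_daily("2-4 times/week"), 3 / 7)
  expect_equal(frequency_to_daily("1-3 times/month"), 2 / 30.44)
  expect_equal(frequency_to_daily("6 or more times/day"), 6)
  expect_error(frequency_to_daily("fortnightly"), "unknown")
  # custom mapping overrides
  m <- setNames(seq_along(frequency_levels()), frequency_levels())
  expect_equal(frequency_to_daily("1 time/week", m), 3)
})

test_that("daily grams combine frequency, servings, serving size, season", {
  cat <- toy_catalog()
  # seasonal item: a quarter of the annualized daily mean
  g <- item_daily_grams(ffq_row("s", "veg", "1 time/day", 1, TRUE), cat)
  expect_equal(g$grams_per_day, 25)
  g <- item_daily_grams(ffq_row("s", "veg", "never or less than 1 time/month",
                                3), cat)
  expect_equal(g$grams_per_day, 0)
  g <- item_daily_grams(ffq_row("s", "fis", "2-4 times/week", 2), cat)
  expect_equal(g$grams_per_day, (3 / 7) * 2 * 100)
  # 50 g serving via half a serving unit
  g <- item_daily_grams(ffq_row("s", "fis", "2-4 times/week", 1), cat)
  expect_equal(g$grams_per_day, (3 / 7) * 100)
})

test_that("group aggregation sums members and forms the lipid ratio", {
  cat <- data.frame(item_id = c("v1", "f1", "f2", "o1", "o2"),
                    grams_per_serving = 100,
                    mufa_per_100g = c(0, 0, 0, 10, 2),
                    sfa_per_100g = c(0, 0, 0, 5, 8),
                    group = c("vegetables", "fruits", "fruits", "fat_only",
                              "fat_only"), stringsAsFactors = FALSE)
  intakes <- data.frame(
    subject_id = "s", item_id = c("v1", "f1", "f2", "o1", "o2"),
    grams_per_day = c(100, 50, 70, 200, 100), stringsAsFactors = FALSE)
  gi <- aggregate_groups(intakes, cat)
  expect_equal(gi$vegetables, 100)
  expect_equal(gi$fruits, 120)
  expect_equal(gi$meat, 0)
  # (200*10 + 100*2)/100 MUFA over (200*5 + 100*8)/100 SFA
  expect_equal(gi$mufa_sfa_ratio, 22 / 18)

  # zero saturated fat leaves the ratio undefined
  intakes$grams_per_day <- c(100, 50, 70, 0, 0)
  expect_true(is.na(aggregate_groups(intakes, cat)$mufa_sfa_ratio))
})

test_that("sex-specific medians use the midpoint convention", {
  gi <- rbind(
    toy_group_intake(sprintf("m%d", 1:4), "male",
                     vegetables = c(10, 20, 30, 40)),
    toy_group_intake(sprintf("f%d", 1:3), "female",
                     vegetables = c(10, 20, 30)))
  cut <- sex_specific_medians(gi)
  expect_equal(cut$medians$male[["vegetables"]], 25)
  expect_equal(cut$medians$female[["vegetables"]], 20)
  expect_error(sex_specific_medians(gi[gi$sex == "male", ]), "female")
})

test_that("cut-offs export and reload identically", {
  gi <- rbind(toy_group_intake("m1", "male", vegetables = 100),
              toy_group_intake("f1", "female", vegetables = 50))
  cut <- sex_specific_medians(gi)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cutoffs(cut, path)
  expect_equal(read_cutoffs(path), cut)
})

test_that("mediSCORE components follow the median-split and window rules", {
  # reference population fixing all medians at 100 (ratio at 1)
  ref <- rbind(
    toy_group_intake(c("rm1", "rm2"), "male", 100, 100, 100, 100, 100,
                     100, 100, 0, 1),
    toy_group_intake(c("rf1", "rf2"), "female", 100, 100, 100, 100, 100,
                     100, 100, 0, 1))
  cut <- sex_specific_medians(ref)

  max_man <- toy_group_intake("hi", "male", 150, 150, 150, 150, 150,
                              50, 50, alcohol = 30, mufa_sfa_ratio = 2)
  s <- mediscore(max_man, cut)
  expect_equal(s$total, 9L)
  expect_true(s$high_adherence)

  min_man <- toy_group_intake("lo", "male", 50, 50, 50, 50, 50,
                              150, 150, alcohol = 0, mufa_sfa_ratio = 0.5)
  s <- mediscore(min_man, cut)
  expect_equal(s$total, 0L)
  expect_false(s$high_adherence)

  # intake exactly at the median: beneficial 0, detrimental 1
  at_median <- toy_group_intake("eq", "male", 100, 100, 100, 100, 100,
                                100, 100, alcohol = 0, mufa_sfa_ratio = 1)
  s <- mediscore(at_median, cut)
  expect_equal(unlist(s[c("vegetables", "meat", "fat_ratio")]),
               c(vegetables = 0L, meat = 1L, fat_ratio = 0L))

  # same 30 g/day of alcohol: inside the male window, outside the female
  both <- rbind(
    toy_group_intake("man", "male", alcohol = 30),
    toy_group_intake("woman", "female", alcohol = 30))
  s <- mediscore(both, cut)
  expect_equal(s$alcohol, c(1L, 0L))
  # window endpoints are inclusive
  ends <- rbind(toy_group_intake("m10", "male", alcohol = 10),
                toy_group_intake("m50", "male", alcohol = 50),
                toy_group_intake("f5", "female", alcohol = 5),
                toy_group_intake("f25", "female", alcohol = 25))
  expect_equal(mediscore(ends, cut)$alcohol, rep(1L, 4))

  # adherence boundary sits between totals 5 and 6
  five <- toy_group_intake("five", "male", 150, 150, 150, 150, 150,
                           150, 150, alcohol = 0, mufa_sfa_ratio = 0.5)
  six <- toy_group_intake("six", "male", 150, 150, 150, 150, 150,
                          50, 150, alcohol = 0, mufa_sfa_ratio = 0.5)
  expect_equal(mediscore(five, cut)$total, 5L)
  expect_false(mediscore(five, cut)$high_adherence)
  expect_equal(mediscore(six, cut)$total, 6L)
  expect_true(mediscore(six, cut)$high_adherence)

  # undefined lipid ratio: component 0, subject flagged
  nofat <- toy_group_intake("nf", "male", mufa_sfa_ratio = NA)
  s <- mediscore(nofat, cut)
  expect_equal(s$fat_ratio, 0L)
  expect_true(s$ratio_missing)
})

test_that("totals are order-invariant and componentwise monotone", {
  set.seed(5)
  n <- 40
  gi <- toy_group_intake(sprintf("s%02d", 1:n),
                         rep(c("male", "female"), n / 2),
                         vegetables = runif(n, 0, 200),
                         legumes = runif(n, 0, 200),
                         fruits = runif(n, 0, 200),
                         cereals = runif(n, 0, 200),
                         fish = runif(n, 0, 200),
                         meat = runif(n, 0, 200),
                         dairy = runif(n, 0, 200),
                         alcohol = runif(n, 0, 60),
                         mufa_sfa_ratio = runif(n, 0.1, 3))
  cut <- sex_specific_medians(gi)
  s1 <- mediscore(gi, cut)
  expect_true(all(s1$total >= 0 & s1$total <= 9))
  s2 <- mediscore(gi[sample(n), ], cut)
  expect_equal(s2[match(s1$subject_id, s2$subject_id), ]$total, s1$total)

  # median-split property: beneficial prevalence at most 50% per sex
  for (sx in c("male", "female")) {
    for (v in c("vegetables", "fruits", "fish")) {
      expect_lte(mean(s1[[v]][gi$sex == sx]), 0.5)
    }
  }

  # doubling intakes under fixed cut-offs can only raise beneficial
  # components and lower detrimental ones
  dbl <- gi
  num <- c("vegetables", "legumes", "fruits", "cereals", "fish", "meat",
           "dairy", "alcohol")
  dbl[num] <- dbl[num] * 2
  s3 <- mediscore(dbl, cut)
  for (v in c("vegetables", "legumes", "fruits", "cereals", "fish")) {
    expect_true(all(s3[[v]] >= s1[[v]]))
  }
  for (v in c("meat", "dairy")) {
    expect_true(all(s3[[v]] <= s1[[v]]))
  }
})
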