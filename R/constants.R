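# Canonical vocabularies shared across the package.

# The nine intake-frequency categories of the food-frequency questionnaire,
# ordered from least to most frequent. Labels use plain ASCII hyphens.
FREQ_LEVELS <- c(
  "never or less than 1 time/month",
  "1-3 times/month",
  "1 time/week",
  "2-4 times/week",
  "5-6 times/week",
  "1 time/day",
  "2-3 times/day",
  "4-5 times/day",
  "6 or more times/day"
)

# Default occasions/day for each category: the category midpoint, expressed
# per day (months averaged at 30.44 days). "never or <1/month" is floored at 0.
FREQ_PER_DAY <- c(
  0,
  2 / 30.44,
  1 / 7,
  3 / 7,
  5.5 / 7,
  1,
  2.5,
  4.5,
  6
)
names(FREQ_PER_DAY) <- FREQ_LEVELS

# mediSCORE food-group vocabulary. fat_only items feed only the MUFA/SFA
# ratio; "other" items feed nothing (but still contribute their lipids to the
# ratio, which sums over all items).
DIET_GROUPS <- c("vegetables", "legumes", "fruits", "cereals", "fish",
                 "meat", "dairy", "alcohol", "fat_only", "other")
BENEFICIAL_GROUPS <- c("vegetables", "legumes", "fruits", "cereals", "fish")
DETRIMENTAL_GROUPS <- c("meat", "dairy")

# Moderate-alcohol windows (grams ethanol/day, endpoints inclusive).
ALCOHOL_RANGE <- list(male = c(10, 50), female = c(5, 25))

# Rotterdam stages; 2a-4 define disease at both eye and subject level.
ROTTERDAM_STAGES <- c("0", "1", "2a", "2b", "3", "4")
CASE_STAGES <- c("2a", "2b", "3", "4")

SEX_LEVELS <- c("female", "male")
SMOKING_LEVELS <- c("non-smoker", "smoker/ex-smoker")
AGE_CAT_LEVELS <- c("60-70", "70-75", ">75")

# The five major risk variants whose complete genotyping is required for a
# valid genetic risk score (two in CFH; C2/CFB/SKIV2L; ARMS2/HTRA1; C3).
MAJOR_VARIANTS <- c("rs570618", "rs10922109", "rs429608", "rs3750846",
                    "rs2230199")
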