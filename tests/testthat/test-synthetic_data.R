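test_that("configuration validation rejects infeasible setups", {
  expect_error(synthetic_config(category_prevalence = rep(2, 17)), "prevalence")
  expect_error(synthetic_config(cardinality_mix = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(synthetic_config(cardinality_mix = c(1, 0, 0)), "infeasible")
  expect_error(synthetic_config(n_codes_per_category = 12), "1..9")
  expect_error(synthetic_config(frac_icd9_stays = 1.4), "frac_icd9_stays")
  # all-unmapped is allowed when nothing needs mapping
  expect_s3_class(synthetic_config(cardinality_mix = c(1, 0, 0),
                                   n_categories = 3,
                                   category_prevalence = rep(0, 3),
                                   true_weights = rep(1, 3)),
                  "synthetic_config")
})

test_that("the same seed reproduces universes, cohorts and files byte-identically", {
  cfg <- quick_config(seed = 101, n_stays = 300)
  u1 <- generate_code_universe(cfg)
  u2 <- generate_code_universe(cfg)
  expect_identical(u1, u2)
  c1 <- generate_cohort(cfg, u1)
  c2 <- generate_cohort(cfg, u2)
  expect_identical(c1, c2)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p1 <- c(write_mapping_sources(u1, d1), write_mimic_like(c1, d1))
  p2 <- c(write_mapping_sources(u2, d2), write_mimic_like(c2, d2))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
})

test_that("cardinality mix is allocated exactly before shuffling", {
  # 6 x 6 category codes + 64 noise codes = 100 codes
  cfg <- synthetic_config(seed = 5, n_categories = 6,
                          category_prevalence = rep(0.1, 6),
                          true_weights = c(1, 1, 2, 2, 3, 6),
                          n_codes_per_category = 6, n_noise_codes = 64,
                          cardinality_mix = c(0.1, 0.7, 0.2))
  u <- generate_code_universe(cfg)
  cs <- cardinality_summary(u$xw_10_11, u$icd10$code)
  expect_identical(c(cs$n_unmapped, cs$n_one, cs$n_multi), c(10L, 70L, 20L))
  expect_identical(cs$universe_size, 100L)
  # degenerate mix: everything 1-1
  cfg2 <- synthetic_config(seed = 5, n_categories = 6,
                           category_prevalence = rep(0.1, 6),
                           true_weights = c(1, 1, 2, 2, 3, 6),
                           n_codes_per_category = 6, n_noise_codes = 64,
                           cardinality_mix = c(0, 1, 0))
  u2 <- generate_code_universe(cfg2)
  cs2 <- cardinality_summary(u2$xw_10_11, u2$icd10$code)
  expect_identical(c(cs2$n_unmapped, cs2$n_one, cs2$n_multi), c(0L, 100L, 0L))
})

test_that("unmapped codes are confined to the noise block under the default mix", {
  u <- generate_code_universe(quick_config(seed = 6))
  expect_true(all(grepl("^Z8", u$unmapped)))
  # child codes are absent from the emitted crosswalk but mapped in the
  # full truth via their parent
  if (nrow(u$children)) {
    expect_false(any(u$children$code %in% u$xw_10_11$entries$source))
    for (i in seq_len(min(5, nrow(u$children)))) {
      expect_identical(map_code(u$xw_10_11_full, u$children$code[[i]]),
                       map_code(u$xw_10_11, u$children$parent[[i]]))
    }
  }
})

test_that("generated indicators are recovered exactly by flag assignment", {
  cfg <- quick_config(seed = 8, n_stays = 400)
  u <- generate_code_universe(cfg)
  coh <- generate_cohort(cfg, u)
  dg <- data.frame(stay_id = coh$diagnoses$hadm_id,
                   code = coh$diagnoses$icd_code,
                   version = ifelse(coh$diagnoses$icd_version == 9,
                                    "ICD9CM", "ICD10CM"))
  for (v in c("ICD9CM", "ICD10CM")) {
    ids <- coh$truth$stay_id[coh$truth$version == v]
    tab <- if (v == "ICD9CM") u$cat_table_icd9 else u$cat_table_icd10
    fl <- flag_matrix(dg[dg$version == v, ], v, cfg$index, tab,
                      stay_ids = ids)
    tru <- coh$truth$indicators[coh$truth$version == v, , drop = FALSE]
    expect_identical(unname(fl), unname(tru))
  }
})

test_that("mortality follows the configured logistic model", {
  # no comorbidity: death rate near plogis(baseline) within 3 SE
  cfg0 <- synthetic_config(seed = 9, n_stays = 10000, n_categories = 3,
                           category_prevalence = rep(0, 3),
                           true_weights = c(1, 2, 3), baseline_logit = -2)
  coh0 <- generate_cohort(cfg0, generate_code_universe(cfg0))
  p0 <- plogis(-2)
  se0 <- sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(mean(coh0$truth$died) - p0), 3 * se0)
  expect_true(all(coh0$truth$true_score == 0))
  # single always-present category of weight 1: rate near plogis(baseline + s)
  cfg1 <- synthetic_config(seed = 10, n_stays = 10000, n_categories = 1,
                           category_prevalence = 1, true_weights = 1,
                           baseline_logit = -2, weight_scale = 0.4)
  coh1 <- generate_cohort(cfg1, generate_code_universe(cfg1))
  p1 <- plogis(-2 + 0.4)
  se1 <- sqrt(p1 * (1 - p1) / 10000)
  expect_lt(abs(mean(coh1$truth$died) - p1), 3 * se1)
  expect_true(all(coh1$truth$indicators))
})

test_that("MIMIC-layout files round-trip and every stay parses", {
  cfg <- synthetic_config(seed = 11, n_stays = 500,
                          cardinality_mix = c(0, 1, 0))
  sim <- pipeline_simulate(cfg, file.path(tempfile(), "bundle"))
  d <- read_diagnoses(sim$paths[["diagnoses"]])
  expect_identical(nrow(d), nrow(sim$cohort$diagnoses))
  adm <- read_admissions(sim$paths[["admissions"]])
  expect_identical(nrow(adm), 500L)
  # with an all-mapped universe the filter audit passes every stay
  bx <- pipeline_build_crosswalk(dirname(sim$paths[["diagnoses"]]))
  stays <- filter_eligible(d, adm, bx$xw_10_11, bx$xw_9_11)
  expect_identical(attr(stays, "audit")$n_eligible, 500L)
  expect_identical(attr(stays, "audit")$n_unmappable, 0L)
  # every stay carries at least one code
  expect_true(all(lengths(stays$codes) >= 1L))
})
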