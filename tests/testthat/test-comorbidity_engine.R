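test_that("shipped Quan table has the expected category structure", {
  tab <- load_category_table()
  expect_identical(sort(unique(tab$category[tab$index == "CCI"])),
                   sort(names(index_categories("CCI"))))
  expect_length(index_categories("CCI"), 17L)
  expect_length(index_categories("ECI"), 31L)
  for (ix in c("CCI", "ECI")) {
    for (v in c("ICD9CM", "ICD10CM")) {
      expect_setequal(unique(tab$category[tab$index == ix & tab$version == v]),
                      names(index_categories(ix)))
    }
  }
  # every category has a weight under its index's schemes
  expect_setequal(names(weight_scheme("CHARLSON_ORIGINAL")),
                  names(index_categories("CCI")))
  expect_setequal(names(weight_scheme("QUAN_UPDATED")),
                  names(index_categories("CCI")))
  expect_setequal(names(weight_scheme("VAN_WALRAVEN")),
                  names(index_categories("ECI")))
})

test_that("complicated diabetes codes flag diabwc, and severity zeroes the mild member", {
  f <- assign_flags("E13620", "ICD10CM", "CCI")
  expect_true(f[["diabwc"]])
  expect_false(f[["diab"]])
  # a stay with both uncomplicated and complicated diabetes counts once
  f2 <- assign_flags(c("E119", "E13620"), "ICD10CM", "CCI")
  expect_true(f2[["diab"]] && f2[["diabwc"]])
  f2 <- apply_severity_hierarchy(f2, "CCI")
  expect_false(f2[["diab"]])
  expect_true(f2[["diabwc"]])
  # empty code set: all flags false, score 0
  f0 <- assign_flags(character(0), "ICD10CM", "CCI")
  expect_false(any(f0))
  expect_identical(score_flags(f0, weight_scheme("CHARLSON_ORIGINAL")), 0)
})

test_that("postcoordinated expressions match categories through their stem only", {
  tab <- as_category_table(data.frame(index = "CCI", version = "ICD11MMS",
                                      category = "mld", code = "FB83.1Y",
                                      match = "exact"))
  with_ext <- assign_flags("FB83.1Y&XT9T", "ICD11MMS", "CCI", tab)
  bare <- assign_flags("FB83.1Y", "ICD11MMS", "CCI", tab)
  expect_identical(with_ext, bare)
  expect_true(with_ext[["mld"]])
  # the extension alone matches nothing
  expect_false(any(assign_flags("XT9T", "ICD11MMS", "CCI", tab)))
})

test_that("severity hierarchy behaves as mild AND NOT severe, exhaustively", {
  for (ix in c("CCI", "ECI")) {
    cats <- names(index_categories(ix))
    for (pair in severity_pairs(ix)) {
      for (mild in c(FALSE, TRUE)) {
        for (severe in c(FALSE, TRUE)) {
          flags <- stats::setNames(rep(FALSE, length(cats)), cats)
          flags[pair] <- c(mild, severe)
          out <- apply_severity_hierarchy(flags, ix)
          expect_identical(unname(out[pair[[1L]]]), mild && !severe)
          expect_identical(unname(out[pair[[2L]]]), severe)
          expect_false(out[pair[[1L]]] && out[pair[[2L]]])
          # off-pair flags untouched
          expect_identical(out[setdiff(cats, pair)], flags[setdiff(cats, pair)])
        }
      }
    }
  }
})

test_that("scores equal an independent dot-product oracle on random flag vectors", {
  set.seed(21)
  cats <- paste0("c", 1:12)
  w <- stats::setNames(as.numeric(sample(-5:9, 12, replace = TRUE)), cats)
  scheme <- weight_scheme("CUSTOM", w)
  for (i in 1:200) {
    flags <- stats::setNames(runif(12) < 0.5, cats)
    expect_identical(score_flags(flags, scheme),
                     sum(w[names(flags)][flags]))
  }
  # matrix form agrees with the vector form
  m <- matrix(runif(60) < 0.5, ncol = 12, dimnames = list(NULL, cats))
  sm <- score_flags(m, scheme)
  for (i in seq_len(nrow(m))) {
    expect_identical(sm[[i]], score_flags(m[i, ], scheme))
  }
  expect_error(score_flags(stats::setNames(TRUE, "unknown"), scheme),
               "missing categories")
})

test_that("scoring is permutation-invariant and idempotent under duplicated codes", {
  codes <- c("E13620", "I21", "C77", "I21")
  f1 <- assign_flags(codes, "ICD10CM", "CCI")
  f2 <- assign_flags(rev(codes), "ICD10CM", "CCI")
  f3 <- assign_flags(unique(codes), "ICD10CM", "CCI")
  expect_identical(f1, f2)
  expect_identical(f1, f3)
})

test_that("ICD-11 category tables inherit the union of source categories", {
  tab10 <- load_category_table()
  xw <- toy_crosswalk(list(E13620 = c("5A13", "EB90.0")))
  inferred <- infer_icd11_category_table(tab10, xw, "CCI")
  expect_setequal(inferred$code[inferred$category == "diabwc"],
                  c("5A13", "EB90.0"))
  expect_identical(unique(inferred$version), "ICD11MMS")
  expect_identical(unique(inferred$match), "exact")
  # uncategorized sources produce an empty table
  empty <- infer_icd11_category_table(tab10, toy_crosswalk(list(Z9ZZ = "XX40")),
                                      "CCI")
  expect_identical(nrow(empty), 0L)
  # one target reached from sources in two categories is listed under both
  xw2 <- toy_crosswalk(list(I21 = "BA41", I50 = "BA41"))
  inf2 <- infer_icd11_category_table(tab10, xw2, "CCI")
  expect_setequal(inf2$category[inf2$code == "BA41"], c("mi", "chf"))
  # postcoordinated targets inherit through their stem (hypertension here)
  xw3 <- toy_crosswalk(list(I10 = "BA00.Z&XT9T"))
  inf3 <- infer_icd11_category_table(load_category_table(), xw3, "ECI")
  expect_true("BA00.Z" %in% inf3$code[inf3$category == "hypunc"])
  expect_false(any(grepl("&", inf3$code, fixed = TRUE)))
})

test_that("inherited ICD-11 scoring matches the source scoring on a toy stay", {
  tab10 <- load_category_table()
  xw <- toy_crosswalk(list(E13620 = c("5A13", "EB90.0"), I21 = "BA41"))
  tab11 <- infer_icd11_category_table(tab10, xw, "CCI")
  full <- as_category_table(rbind(as.data.frame(tab10), as.data.frame(tab11)))
  f10 <- assign_flags(c("E13620", "I21"), "ICD10CM", "CCI", full)
  f11 <- assign_flags(c("5A13", "EB90.0", "BA41"), "ICD11MMS", "CCI", full)
  expect_identical(f10, f11)
})

test_that("exported code lists round-trip and reproduce flag assignment", {
  tab10 <- load_category_table()
  xw <- toy_crosswalk(list(E13620 = c("5A13", "EB90.0"), I21 = "BA41"))
  tab11 <- infer_icd11_category_table(tab10, xw, "CCI")
  path <- tempfile(fileext = ".tsv")
  export_codelists(tab11, "CCI", "ICD11MMS", weight_scheme("CHARLSON_ORIGINAL"),
                   path)
  back <- read_codelist(path, "ICD11MMS")
  canon <- function(df) {
    df <- as.data.frame(df)[order(df$category, df$code), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(canon(back), canon(tab11), ignore_attr = TRUE)
  expect_identical(attr(back, "weights")[["diabwc"]], 2)
  f_orig <- assign_flags("EB90.0", "ICD11MMS", "CCI", tab11)
  f_back <- assign_flags("EB90.0", "ICD11MMS", "CCI", back)
  expect_identical(f_orig, f_back)
  # empty slice exports a header-only file
  path2 <- tempfile(fileext = ".tsv")
  export_codelists(tab11[0, ], "CCI", "ICD11MMS",
                   weight_scheme("CHARLSON_ORIGINAL"), path2)
  expect_identical(length(readLines(path2)), 1L)
})

test_that("flag matrices agree with per-stay assignment", {
  dg <- data.frame(stay_id = c(1, 1, 2, 3),
                   code = c("E13620", "I21", "C77", "Z999"))
  m <- flag_matrix(dg, "ICD10CM", "CCI", stay_ids = c(1, 2, 3, 4))
  expect_identical(nrow(m), 4L)
  for (s in 1:3) {
    expect_identical(m[as.character(s), ],
                     assign_flags(dg$code[dg$stay_id == s], "ICD10CM", "CCI"))
  }
  expect_false(any(m["4", ]))
  expect_lte(sum(m[1, ]), 17L)
})
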