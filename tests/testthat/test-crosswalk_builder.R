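test_that("GEM rows parse, no-map rows are excluded, multimaps union", {
  path <- write_lines_tmp(c("0010 A000 00000",
                            "0019 NoDx 11000",
                            "0011 A001 10000",
                            "0011 A009 10000"))
  xw <- load_gem_table(path)
  expect_identical(map_code(xw, "0010"), "A000")
  expect_identical(map_code(xw, "0019"), character(0))
  expect_identical(map_code(xw, "0011"), c("A001", "A009"))
  expect_identical(unique(xw$entries$provenance), "GEM")
  expect_error(load_gem_table(write_lines_tmp("0010 A000 0000X")),
               "flag string")
  expect_error(load_gem_table(tempfile()), "cannot read")
})

test_that("concept equivalences join codes sharing a CUI (cross product)", {
  row <- function(cui, sab, code) {
    paste(cui, "ENG", "P", "L", "PF", "S", "Y", "A", "", "", "", sab, "PT",
          code, "str", "0", "N", "", sep = "|")
  }
  path <- write_lines_tmp(c(row("C1", "ICD9CM", "250.00"),
                            row("C1", "ICD10CM", "E11.9"),
                            row("C2", "ICD9CM", "4280"),
                            row("C3", "ICD9CM", "0340"),
                            row("C3", "ICD10CM", "J02.0"),
                            row("C3", "ICD10CM", "J03.90")))
  xw <- load_concept_equivalences(path, "ICD9CM", "ICD10CM")
  expect_identical(map_code(xw, "25000"), "E119")     # dotted input normalized
  expect_identical(map_code(xw, "4280"), character(0)) # no partner under C2
  expect_identical(map_code(xw, "0340"), c("J020", "J0390")) # 1-N cross product
  expect_identical(unique(xw$entries$provenance), "CONCEPT_EQUIV")
})

test_that("WHO map files union rows and skip incomplete ones with a warning", {
  one <- write_lines_tmp(c("mapKind\ticd10Code\ticd11Code",
                           "stated\tA37.9\t1C12.Z"), ext = ".tsv")
  multi <- write_lines_tmp(c("mapKind\ticd10Code\ticd11Code",
                             "stated\tA37.9\t1C12.Y",
                             "stated\tA39.8\t1C1C.Z",
                             "stated\tA39.8\t"), ext = ".tsv")
  expect_warning(xw <- load_who_icd10_to_icd11(c(one, multi)),
                 "skipped 1")
  expect_identical(map_code(xw, "A379"), c("1C12.Y", "1C12.Z"))
  expect_identical(map_code(xw, "A398"), "1C1C.Z")
  empty <- write_lines_tmp("mapKind\ticd10Code\ticd11Code", ext = ".tsv")
  expect_identical(n_pairs(load_who_icd10_to_icd11(c(empty, empty))), 0L)
})

test_that("FinalMaptype controls which Fung mappings are retained", {
  hdr <- "icd10cm,icd11_precoordinated,icd11_postcoordinated,FinalMaptype"
  path <- write_lines_tmp(c(hdr,
                            "M810,FB83.1Y,FB83.1Y&XT9T,full map by post coordination",
                            "M811,FB83.1Y,FB83.1Y&XT9T,",
                            "M812,FB83.2,,"), ext = ".csv")
  xw <- load_fung_map(path)
  # tagged row: only the postcoordinated expression is the mapping
  expect_identical(map_code(xw, "M810"), "FB83.1Y&XT9T")
  # untagged row with both columns: both are mappings
  expect_identical(map_code(xw, "M811"), c("FB83.1Y", "FB83.1Y&XT9T"))
  expect_identical(map_code(xw, "M812"), "FB83.2")
  flavors <- xw$entries$flavor[xw$entries$source == "M810"]
  expect_identical(flavors, "POSTCOORDINATED")
  bad <- write_lines_tmp(c(hdr, "M813,FB83.1Y,,full map by post coordination"),
                         ext = ".csv")
  expect_error(load_fung_map(bad), "postcoordinated")
})

test_that("merging unions pairs and keeps the highest-precedence provenance", {
  a <- toy_crosswalk(list(X123 = "T1"), "ICD9CM", "ICD10CM", "GEM")
  b <- toy_crosswalk(list(X123 = "T1", X124 = c("T1", "T2")),
                     "ICD9CM", "ICD10CM", "CONCEPT_EQUIV")
  m <- merge_crosswalks(list(a, b))
  expect_identical(n_pairs(m), 3L)
  expect_identical(m$entries$provenance[m$entries$source == "X123"], "GEM")
  expect_error(merge_crosswalks(list(a, toy_crosswalk(list(), "ICD10CM"))),
               "mismatched versions")
  # disjoint tables concatenate; overlapping 1-N sets union without duplicates
  c1 <- toy_crosswalk(list(A111 = c("U", "V")), provenance = "FUNG_MAP")
  c2 <- toy_crosswalk(list(A111 = c("V", "W"), B222 = "U"))
  mm <- merge_crosswalks(list(c1, c2))
  expect_identical(map_code(mm, "A111"), c("U", "V", "W"))
  expect_identical(n_pairs(mm), 4L)
})

test_that("manual overrides only fill gaps and conflict otherwise", {
  xw <- toy_crosswalk(list(A379 = "1C12.Z"))
  out <- apply_manual_overrides(xw, data.frame(source = "B999", target = "XX40"))
  expect_identical(map_code(out, "B999"), "XX40")
  expect_identical(out$entries$provenance[out$entries$source == "B999"],
                   "MANUAL")
  expect_identical(pair_set(apply_manual_overrides(xw, data.frame(
    source = character(), target = character()))), pair_set(xw))
  expect_error(apply_manual_overrides(xw, data.frame(source = "A37.9",
                                                     target = "XX41")),
               "already-mapped.*A379")
})

test_that("reverse engineering assigns nearest mapped ancestor mappings to a fixpoint", {
  xw <- toy_crosswalk(list(A379 = "1C12.Z"))
  out <- reverse_engineer_from_hierarchy(xw, c("A3790", "A3791"))
  expect_identical(map_code(out, "A3790"), "1C12.Z")
  expect_identical(map_code(out, "A3791"), "1C12.Z")
  expect_identical(
    unique(out$entries$provenance[out$entries$source == "A3791"]),
    "REVERSE_ENGINEERED")
  # fully mapped universe: fixpoint immediately, output = input
  expect_identical(pair_set(reverse_engineer_from_hierarchy(xw, "A379")),
                   pair_set(xw))
  # multi-level gap crossed: ancestor A37 is the only mapped code
  chain <- reverse_engineer_from_hierarchy(toy_crosswalk(list(A37 = "T")),
                                           c("A379", "A3791"))
  expect_identical(map_code(chain, "A379"), "T")
  expect_identical(map_code(chain, "A3791"), "T")
})

test_that("reverse engineering matches a brute-force fixpoint oracle on random hierarchies", {
  set.seed(41)
  for (rep in 1:25) {
    universe <- random_toy_universe(sample(10:60, 1))
    mapped <- sample(universe, max(1L, rpois(1, length(universe) / 4)))
    map <- lapply(seq_along(mapped), function(i) {
      paste0("T", sample(100:999, sample(1:3, 1)))
    })
    names(map) <- mapped
    xw <- toy_crosswalk(map)
    out <- reverse_engineer_from_hierarchy(xw, universe)
    oracle <- oracle_reverse_engineer(map, universe)
    for (code in universe) {
      expect_identical(map_code(out, code),
                       sort(unique(oracle[[code]] %||% character(0))))
    }
    # fixpoint invariant: nobody with a mapped ancestor stays unmapped
    final_mapped <- unique(out$entries$source)
    for (code in setdiff(universe, final_mapped)) {
      anc <- code
      while (nchar(anc) > 3L) {
        anc <- substr(anc, 1L, nchar(anc) - 1L)
        expect_false(anc %in% final_mapped)
      }
    }
    # monotonicity: reverse engineering never removes entries
    expect_gte(n_pairs(out), n_pairs(xw))
  }
})

test_that("composition agrees with exhaustive path enumeration", {
  ab <- toy_crosswalk(list(X111 = c("Y1", "Y2"), X222 = "Y3"),
                      "ICD9CM", "ICD10CM", "GEM")
  bc <- toy_crosswalk(list(Y1 = "Z1", Y2 = c("Z1", "Z3")))
  comp <- compose_crosswalks(ab, bc)
  expect_identical(map_code(comp, "X111"), c("Z1", "Z3"))
  expect_identical(map_code(comp, "X222"), character(0)) # Y3 unmapped
  expect_identical(comp$source_version, "ICD9CM")
  expect_identical(comp$target_version, "ICD11MMS")
  expect_error(compose_crosswalks(bc, ab), "cannot compose")

  set.seed(42)
  for (rep in 1:20) {
    s_codes <- paste0("S", 100:149)
    m_codes <- paste0("M", 100:139)
    t_codes <- paste0("T", 100:129)
    map_ab <- lapply(s_codes, function(s) sample(m_codes, sample(0:3, 1)))
    names(map_ab) <- s_codes
    map_bc <- lapply(m_codes, function(m) sample(t_codes, sample(0:2, 1)))
    names(map_bc) <- m_codes
    xab <- toy_crosswalk(map_ab[lengths(map_ab) > 0], "ICD9CM", "ICD10CM", "GEM")
    xbc <- toy_crosswalk(map_bc[lengths(map_bc) > 0])
    comp <- compose_crosswalks(xab, xbc)
    oracle <- oracle_compose(map_ab, map_bc, s_codes)
    for (s in s_codes) {
      expect_identical(map_code(comp, s), oracle[[s]] %||% character(0))
    }
  }
})

test_that("cardinality counts always partition the universe", {
  xw <- toy_crosswalk(list(A111 = "T", B222 = c("T", "U")))
  cs <- cardinality_summary(xw, c("A111", "B222", "C333"))
  expect_identical(c(cs$n_unmapped, cs$n_one, cs$n_multi), c(1L, 1L, 1L))
  expect_identical(cs$n_unmapped + cs$n_one + cs$n_multi, cs$universe_size)
  empty <- toy_crosswalk(list())
  cs0 <- cardinality_summary(empty, c("A111", "B222"))
  expect_identical(cs0$n_unmapped, 2L)
  expect_error(cardinality_summary(xw, character(0)), "empty")
})

test_that("crosswalk serialization round-trips and is byte-deterministic", {
  xw <- toy_crosswalk(list(A379 = c("1C12.Z", "1C12.Y&XT9T"), B999 = "XX40"))
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_crosswalk(xw, p1)
  back <- read_crosswalk(p1)
  expect_identical(pair_set(back), pair_set(xw))
  expect_identical(back$source_version, xw$source_version)
  expect_identical(back$entries$flavor, xw$entries$flavor)
  write_crosswalk(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("mapping through reverse-engineered entries is provenance-transparent", {
  xw <- reverse_engineer_from_hierarchy(toy_crosswalk(list(A379 = "1C12.Z")),
                                        c("A3791"))
  expect_identical(map_code(xw, "A3791"), map_code(xw, "A379"))
})
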