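#' Configuration for the synthetic study generator
#'
#' Builds and validates the configuration of the ground-truthed synthetic
#' world: a hierarchical ICD-10-CM-like code universe (with flat ICD-9-like
#' and ICD-11-like counterparts), truth crosswalks with controlled
#' 1-0/1-1/1-N cardinalities, per-category diagnosis prevalences, and
#' in-hospital mortality drawn from a logistic model in the category
#' indicators.
#'
#' Defaults emulate the study conditions: 17 comorbidity categories with
#' Charlson-original integer weights, graded prevalences giving a mean
#' index near the values reported for real ICU admissions, a mostly-1-1
#' mapping structure with a small unmapped fraction confined to
#' non-comorbidity ("noise") codes, and a mixed ICD-9/ICD-10 coding era.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical output.
#' @param n_stays number of hospital stays.
#' @param index index label attached to the synthetic category table.
#' @param n_categories number of comorbidity categories.
#' @param category_prevalence per-category prevalence in `[0, 1]`.
#' @param true_weights integer weight per category.
#' @param baseline_logit intercept of the mortality model (log-odds).
#' @param weight_scale log-odds of death per weight unit.
#' @param frac_icd9_stays fraction of stays coded in ICD-9.
#' @param cardinality_mix proportions of 1-0 / 1-1 / 1-N source codes
#'   (must sum to 1); unmapped codes are allocated to noise codes first so
#'   eligibility filtering stays independent of comorbidity status.
#' @param n_codes_per_category codes per category and version (1-9).
#' @param n_noise_codes number of non-comorbidity codes per version (<=99).
#' @param frac_child_only fraction of mapped category codes that get a
#'   child code mappable only through its parent (exercises reverse
#'   engineering).
#' @param frac_postcoordinated fraction of 1-1 category mappings whose
#'   target is a postcoordinated expression.
#' @param noise_codes_mean Poisson mean of extra noise codes per stay.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_stays = 10000L,
                             index = "CCI",
                             n_categories = 17L,
                             category_prevalence = NULL,
                             true_weights = NULL,
                             baseline_logit = -3,
                             weight_scale = 0.4,
                             frac_icd9_stays = 0.4,
                             cardinality_mix = c(unmapped = 0.03,
                                                 one = 0.85,
                                                 multi = 0.12),
                             n_codes_per_category = 8L,
                             n_noise_codes = 64L,
                             frac_child_only = 0.15,
                             frac_postcoordinated = 0.2,
                             noise_codes_mean = 2) {
  if (is.null(category_prevalence)) {
    # decreasing with category rank: the heavily weighted (severe)
    # categories are the rarer ones, as in real comorbidity profiles
    category_prevalence <- seq(0.12, 0.02, length.out = n_categories)
  }
  if (is.null(true_weights)) {
    true_weights <- if (n_categories == 17L) {
      c(rep(1L, 10L), rep(2L, 4L), 3L, 6L, 6L)  # Charlson-original pattern
    } else {
      rep_len(c(1L, 1L, 2L, 2L, 3L, 6L), n_categories)
    }
  }
  cfg <- list(seed = as.integer(seed), n_stays = as.integer(n_stays),
              index = index, n_categories = as.integer(n_categories),
              category_prevalence = category_prevalence,
              true_weights = as.integer(true_weights),
              baseline_logit = baseline_logit, weight_scale = weight_scale,
              frac_icd9_stays = frac_icd9_stays,
              cardinality_mix = cardinality_mix,
              n_codes_per_category = as.integer(n_codes_per_category),
              n_noise_codes = as.integer(n_noise_codes),
              frac_child_only = frac_child_only,
              frac_postcoordinated = frac_postcoordinated,
              noise_codes_mean = noise_codes_mean)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_categories < 1L || cfg$n_categories > 99L) {
    stop("n_categories must be in 1..99", call. = FALSE)
  }
  if (length(cfg$category_prevalence) != cfg$n_categories ||
      any(cfg$category_prevalence < 0) || any(cfg$category_prevalence > 1)) {
    stop("category_prevalence must give one value in [0, 1] per category",
         call. = FALSE)
  }
  if (length(cfg$true_weights) != cfg$n_categories) {
    stop("true_weights must give one integer per category", call. = FALSE)
  }
  mix <- cfg$cardinality_mix
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("cardinality_mix must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (mix[[2L]] + mix[[3L]] == 0 && any(cfg$category_prevalence > 0)) {
    stop("infeasible cardinality_mix: no code is mappable but category ",
         "prevalences are positive", call. = FALSE)
  }
  if (cfg$n_codes_per_category < 1L || cfg$n_codes_per_category > 9L) {
    stop("n_codes_per_category must be in 1..9", call. = FALSE)
  }
  if (cfg$n_noise_codes < 0L || cfg$n_noise_codes > 99L) {
    stop("n_noise_codes must be in 0..99", call. = FALSE)
  }
  for (f in c("frac_icd9_stays", "frac_child_only", "frac_postcoordinated")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_codes_mean < 0) stop("noise_codes_mean must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Two-letter category tag: AA, AB, ... (reserved synthetic alphabet)
cat_tag <- function(c) {
  paste0(LETTERS[(c - 1L) %/% 26L + 1L], LETTERS[(c - 1L) %% 26L + 1L])
}

# Deterministic largest-remainder allocation of N codes to the mix
allocate_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the synthetic code universe and truth crosswalks
#'
#' Creates ICD-9-like, hierarchical ICD-10-CM-like (3-7 characters, shared
#' prefixes) and ICD-11-like code lists on a reserved alphabet (leading
#' `Z9`/`Z8`, `V9`/`V8`, `X9`/`X8` blocks for category/noise codes, so
#' fixtures can never collide with the shipped real code lists), together
#' with ground-truth crosswalks whose 1-0/1-1/1-N cardinalities follow the
#' configured mix exactly (largest-remainder allocation before shuffling).
#' A configurable fraction of mapped category codes receives a child code
#' mappable only through its parent, and a fraction of targets are
#' postcoordinated expressions. Every truth pair is routed to one of the
#' mapping-source flavors (GEM / MRCONSO / WHO one-category / WHO
#' multiple-categories / Fung) so each reader is exercised by
#' [write_mapping_sources()].
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_universe`: code tables, truth category
#'   tables per version, truth crosswalks (`xw_9_10`, `xw_10_11` as emitted
#'   in the source files, `xw_10_11_full` including the child codes), and
#'   the file routing of every pair.
#' @export
generate_code_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nc <- config$n_categories
  k <- config$n_codes_per_category
  cats <- sprintf("synthcat%02d", seq_len(nc))
  tags <- vapply(seq_len(nc), cat_tag, "")

  icd10 <- data.frame(
    code = paste0(rep(paste0("Z9", tags), each = k), seq_len(k)),
    category = rep(cats, each = k), stringsAsFactors = FALSE)
  noise10 <- if (config$n_noise_codes > 0L) {
    paste0("Z8", sprintf("%02d", seq_len(config$n_noise_codes)))
  } else character()
  icd10 <- rbind(icd10,
                 data.frame(code = noise10, category = NA_character_,
                            stringsAsFactors = FALSE))

  icd9 <- data.frame(
    code = paste0(rep(paste0("V9", tags), each = k), seq_len(k)),
    category = rep(cats, each = k), stringsAsFactors = FALSE)
  noise9 <- if (config$n_noise_codes > 0L) {
    paste0("V8", sprintf("%02d", seq_len(config$n_noise_codes)))
  } else character()
  icd9 <- rbind(icd9,
                data.frame(code = noise9, category = NA_character_,
                           stringsAsFactors = FALSE))

  # --- cardinality allocation over the full ICD-10 universe ---------------
  n_universe <- nrow(icd10)
  counts <- allocate_counts(config$cardinality_mix, n_universe)
  is_noise <- is.na(icd10$category)
  # 1-0 codes: noise codes first, category codes only if noise runs out
  un_pool <- c(sample(icd10$code[is_noise]), sample(icd10$code[!is_noise]))
  unmapped <- un_pool[seq_len(counts[[1L]])]
  rest <- setdiff(icd10$code, unmapped)
  multi <- if (counts[[3L]] > 0L) sample(rest, counts[[3L]]) else character()
  single <- setdiff(rest, multi)

  # --- target construction ------------------------------------------------
  exts <- paste0("XT9", LETTERS[1:5])
  primary_target <- function(code) {
    i <- match(code, icd10$code)
    cat <- icd10$category[i]
    if (is.na(cat)) {
      paste0("X8", substr(code, 3L, 4L), ".A")
    } else {
      c_idx <- match(cat, cats)
      paste0("X9", tags[c_idx], ".", substr(code, 5L, 5L))
    }
  }
  shared_stem <- function(cat) paste0("X9", tags[match(cat, cats)], ".Z")

  rows <- list()
  routing <- list()
  # 1-1 codes
  for (code in single) {
    t1 <- primary_target(code)
    cat <- icd10$category[match(code, icd10$code)]
    if (!is.na(cat) && stats::runif(1) < config$frac_postcoordinated) {
      expr <- paste0(t1, "&", sample(exts, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        source = code, target = expr, provenance = "FUNG_MAP",
        stringsAsFactors = FALSE)
      routing[[length(routing) + 1L]] <- data.frame(
        source = code, target = expr, file = "fung_postonly", pre = t1,
        stringsAsFactors = FALSE)
    } else {
      file <- if (!is.na(cat) && stats::runif(1) < 0.3) "fung_pre" else "who_one"
      rows[[length(rows) + 1L]] <- data.frame(
        source = code, target = t1,
        provenance = if (file == "fung_pre") "FUNG_MAP" else "WHO_MAP",
        stringsAsFactors = FALSE)
      routing[[length(routing) + 1L]] <- data.frame(
        source = code, target = t1, file = file, pre = t1,
        stringsAsFactors = FALSE)
    }
  }
  # 1-N codes: two targets each
  for (code in multi) {
    t1 <- primary_target(code)
    cat <- icd10$category[match(code, icd10$code)]
    if (is.na(cat)) {
      t2 <- sub("\\.A$", ".B", t1)
      tgts <- c(t1, t2)
      file <- rep("who_multi", 2L)
      prov <- rep("WHO_MAP", 2L)
      pre <- tgts
    } else if (stats::runif(1) < 0.5) {
      tgts <- c(t1, shared_stem(cat))
      file <- rep("who_multi", 2L)
      prov <- rep("WHO_MAP", 2L)
      pre <- tgts
    } else {
      tgts <- c(t1, paste0(t1, "&", sample(exts, 1L)))
      file <- rep("fung_both", 2L)
      prov <- rep("FUNG_MAP", 2L)
      pre <- c(t1, t1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source = code, target = tgts, provenance = prov,
      stringsAsFactors = FALSE)
    routing[[length(routing) + 1L]] <- data.frame(
      source = code, target = tgts, file = file, pre = pre,
      stringsAsFactors = FALSE)
  }
  entries_10_11 <- do.call(rbind, rows)
  routing_10_11 <- do.call(rbind, routing)
  xw_10_11 <- crosswalk("ICD10CM", "ICD11MMS", entries_10_11)

  # --- child codes mappable only through their parent ---------------------
  mapped_cat_codes <- intersect(icd10$code[!is_noise], entries_10_11$source)
  n_children <- round(config$frac_child_only * length(mapped_cat_codes))
  child_parent <- if (n_children > 0L) {
    sort(sample(mapped_cat_codes, n_children))
  } else character()
  children <- data.frame(
    code = if (length(child_parent)) paste0(child_parent, "A") else character(),
    parent = child_parent,
    category = icd10$category[match(child_parent, icd10$code)],
    stringsAsFactors = FALSE)
  child_entries <- if (nrow(children)) {
    idx <- match(entries_10_11$source, children$parent)
    has <- !is.na(idx)
    data.frame(source = children$code[idx[has]],
               target = entries_10_11$target[has],
               provenance = "REVERSE_ENGINEERED", stringsAsFactors = FALSE)
  } else entries_10_11[0L, ]
  xw_10_11_full <- crosswalk("ICD10CM", "ICD11MMS",
                             rbind(entries_10_11[, c("source", "target",
                                                     "provenance")],
                                   child_entries))

  # --- 9 -> 10 truth crosswalk (1-1 by construction) ----------------------
  map9 <- data.frame(source = icd9$code, target = icd10$code,
                     stringsAsFactors = FALSE)
  gem_rows <- stats::runif(nrow(map9)) < 0.6
  map9$provenance <- ifelse(gem_rows, "GEM", "CONCEPT_EQUIV")
  map9$file <- ifelse(gem_rows, "gem", "mrconso")
  xw_9_10 <- crosswalk("ICD9CM", "ICD10CM",
                       map9[, c("source", "target", "provenance")])

  # --- truth category tables ----------------------------------------------
  cat9 <- as_category_table(data.frame(
    index = config$index, version = "ICD9CM",
    category = icd9$category[!is.na(icd9$category)],
    code = icd9$code[!is.na(icd9$category)], match = "exact",
    stringsAsFactors = FALSE))
  cat10 <- as_category_table(data.frame(
    index = config$index, version = "ICD10CM",
    category = icd10$category[!is.na(icd10$category)],
    code = icd10$code[!is.na(icd10$category)], match = "prefix",
    stringsAsFactors = FALSE))
  stems11 <- unique(data.frame(
    category = rep(cats, each = k + 1L),
    code = c(t(cbind(matrix(paste0("X9", rep(tags, each = k), ".",
                                   rep(seq_len(k), nc)),
                            nrow = nc, byrow = TRUE),
                     paste0("X9", tags, ".Z")))),
    stringsAsFactors = FALSE))
  cat11 <- as_category_table(data.frame(
    index = config$index, version = "ICD11MMS",
    category = stems11$category, code = stems11$code, match = "exact",
    stringsAsFactors = FALSE))

  categories <- data.frame(category = cats,
                           prevalence = config$category_prevalence,
                           weight = config$true_weights,
                           stringsAsFactors = FALSE)

  structure(list(config = config, categories = categories,
                 icd9 = icd9, icd10 = icd10, children = children,
                 unmapped = sort(unmapped),
                 xw_9_10 = xw_9_10, xw_10_11 = xw_10_11,
                 xw_10_11_full = xw_10_11_full,
                 routing_10_11 = routing_10_11, routing_9_10 = map9,
                 cat_table_icd9 = cat9, cat_table_icd10 = cat10,
                 cat_table_icd11 = cat11),
            class = "synthetic_universe")
}

#' Generate a MIMIC-like synthetic cohort
#'
#' Draws per-stay coding version (never mixed within a stay), category
#' indicators from the configured prevalences, a uniformly chosen code per
#' present category (ICD-10 stays may draw the parent-only child codes),
#' Poisson-distributed extra noise codes, and in-hospital death from
#' `Bernoulli(plogis(baseline_logit + weight_scale * sum(w_c x_c)))`.
#' Stays are guaranteed non-empty (a noise code is added when a stay would
#' otherwise carry no diagnosis).
#'
#' @param config a [synthetic_config()].
#' @param universe a [generate_code_universe()] result for the same config.
#' @return List of class `synthetic_cohort`: `diagnoses` and `admissions`
#'   data.frames in MIMIC layout plus `truth` (per-stay indicator matrix,
#'   version, death flag and true score).
#' @export
generate_cohort <- function(config, universe) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(universe, "synthetic_universe"))
  set.seed(config$seed + 1L)
  n <- config$n_stays
  nc <- config$n_categories
  cats <- universe$categories$category
  stay_id <- 20000000L + seq_len(n)
  subject_id <- 10000000L + seq_len(n)
  is9 <- stats::runif(n) < config$frac_icd9_stays
  version <- ifelse(is9, "ICD9CM", "ICD10CM")

  x <- matrix(stats::runif(n * nc) <
                rep(config$category_prevalence, each = n),
              nrow = n, dimnames = list(NULL, cats))
  true_score <- as.vector(x %*% config$true_weights)
  p_death <- stats::plogis(config$baseline_logit +
                             config$weight_scale * true_score)
  died <- stats::runif(n) < p_death

  pools10 <- lapply(cats, function(ct) {
    c(universe$icd10$code[universe$icd10$category %in% ct],
      universe$children$code[universe$children$category %in% ct])
  })
  pools9 <- lapply(cats, function(ct) {
    universe$icd9$code[universe$icd9$category %in% ct]
  })
  noise10 <- universe$icd10$code[is.na(universe$icd10$category)]
  noise9 <- universe$icd9$code[is.na(universe$icd9$category)]

  pieces <- list()
  for (c_idx in seq_len(nc)) {
    has <- which(x[, c_idx])
    if (length(has) == 0L) next
    h9 <- has[is9[has]]; h10 <- has[!is9[has]]
    if (length(h9)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        stay = h9, code = sample(pools9[[c_idx]], length(h9), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (length(h10)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        stay = h10, code = sample(pools10[[c_idx]], length(h10), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  n_noise <- stats::rpois(n, config$noise_codes_mean)
  covered <- sort(unique(unlist(lapply(pieces, `[[`, "stay"))))
  empty <- setdiff(which(n_noise == 0L), covered)
  n_noise[empty] <- 1L  # keep every stay non-empty
  which9 <- which(is9); which10 <- which(!is9)
  if (length(which9) && sum(n_noise[which9]) > 0 && length(noise9)) {
    pieces[[length(pieces) + 1L]] <- data.frame(
      stay = rep(which9, n_noise[which9]),
      code = sample(noise9, sum(n_noise[which9]), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (length(which10) && sum(n_noise[which10]) > 0 && length(noise10)) {
    pieces[[length(pieces) + 1L]] <- data.frame(
      stay = rep(which10, n_noise[which10]),
      code = sample(noise10, sum(n_noise[which10]), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, pieces)
  long <- long[order(long$stay), , drop = FALSE]
  seq_num <- stats::ave(seq_len(nrow(long)), long$stay, FUN = seq_along)
  diagnoses <- data.frame(subject_id = subject_id[long$stay],
                          hadm_id = stay_id[long$stay],
                          seq_num = as.integer(seq_num),
                          icd_code = long$code,
                          icd_version = ifelse(is9[long$stay], 9L, 10L),
                          stringsAsFactors = FALSE)
  admissions <- data.frame(subject_id = subject_id, hadm_id = stay_id,
                           hospital_expire_flag = as.integer(died),
                           stringsAsFactors = FALSE)
  structure(list(diagnoses = diagnoses, admissions = admissions,
                 truth = list(stay_id = stay_id, indicators = x,
                              version = version, died = died,
                              true_score = true_score,
                              true_weights = stats::setNames(
                                config$true_weights, cats))),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort in MIMIC layout
#'
#' Emits `diagnoses.csv` (subject_id, hadm_id, seq_num, icd_code,
#' icd_version) and `admissions.csv` (subject_id, hadm_id,
#' hospital_expire_flag); reading them back with [read_diagnoses()] /
#' [read_admissions()] reproduces the records.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_mimic_like <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(diagnoses = file.path(dir, "diagnoses.csv"),
             admissions = file.path(dir, "admissions.csv"))
  utils::write.csv(cohort$diagnoses, paths[["diagnoses"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$admissions, paths[["admissions"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' Write the synthetic mapping-source bundle
#'
#' Splits the truth crosswalks across the four source-file flavors so every
#' reader is exercised: a GEM-style flat file and an MRCONSO-layout
#' concept file for ICD-9 to ICD-10, WHO-style one-category and
#' multiple-categories TSVs and a Fung-style CSV (with `FinalMaptype`
#' tags for postcoordination-only rows) for ICD-10 to ICD-11. Also writes
#' the truth category tables (`category_codes_synthetic.tsv`) and a
#' `truth.json` echo of the configuration and ground truth.
#'
#' @param universe a [generate_code_universe()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_mapping_sources <- function(universe, dir) {
  stopifnot(inherits(universe, "synthetic_universe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gem = file.path(dir, "gem_icd9_icd10.txt"),
             mrconso = file.path(dir, "mrconso.rrf"),
             who_one = file.path(dir, "who_10To11MapToOneCategory.tsv"),
             who_multi = file.path(dir, "who_10To11MapToMultipleCategories.tsv"),
             fung = file.path(dir, "fung_icd10cm_icd11.csv"),
             categories = file.path(dir, "category_codes_synthetic.tsv"),
             truth = file.path(dir, "truth.json"))

  r9 <- universe$routing_9_10
  gem <- r9[r9$file == "gem", , drop = FALSE]
  writeLines(sprintf("%s %s %s", gem$source, gem$target, "00000"),
             paths[["gem"]])

  mr <- r9[r9$file == "mrconso", , drop = FALSE]
  mr_row <- function(cui, sab, code) {
    paste(cui, "ENG", "P", "L0", "PF", "S0", "Y", "A0", "", "", "", sab,
          "PT", code, "synthetic concept", "0", "N", "", sep = "|")
  }
  cuis <- sprintf("C9%06d", seq_len(nrow(mr)))
  writeLines(c(mr_row(cuis, "ICD9CM", mr$source),
               mr_row(cuis, "ICD10CM", mr$target)),
             paths[["mrconso"]])

  r10 <- universe$routing_10_11
  who_write <- function(rows, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("mapKind\ticd10Code\ticd11Code", con)
    if (nrow(rows)) {
      writeLines(paste("stated", rows$source, rows$target, sep = "\t"), con)
    }
  }
  who_write(r10[r10$file == "who_one", , drop = FALSE], paths[["who_one"]])
  who_write(r10[r10$file == "who_multi", , drop = FALSE], paths[["who_multi"]])

  fung <- r10[r10$file %in% c("fung_pre", "fung_both", "fung_postonly"), ,
              drop = FALSE]
  # fung_both rows come in (pre, post) pairs sharing a source; emit one row
  fung_rows <- list()
  for (src in unique(fung$source)) {
    rr <- fung[fung$source == src, , drop = FALSE]
    kind <- rr$file[[1L]]
    if (kind == "fung_pre") {
      fung_rows[[src]] <- data.frame(icd10cm = src,
                                     icd11_precoordinated = rr$target[[1L]],
                                     icd11_postcoordinated = "",
                                     FinalMaptype = "stated map",
                                     stringsAsFactors = FALSE)
    } else if (kind == "fung_postonly") {
      fung_rows[[src]] <- data.frame(icd10cm = src,
                                     icd11_precoordinated = rr$pre[[1L]],
                                     icd11_postcoordinated = rr$target[[1L]],
                                     FinalMaptype = "full map by post coordination",
                                     stringsAsFactors = FALSE)
    } else {
      post <- rr$target[grepl("&", rr$target, fixed = TRUE)][[1L]]
      pre <- rr$target[!grepl("&", rr$target, fixed = TRUE)][[1L]]
      fung_rows[[src]] <- data.frame(icd10cm = src,
                                     icd11_precoordinated = pre,
                                     icd11_postcoordinated = post,
                                     FinalMaptype = "map with post coordination",
                                     stringsAsFactors = FALSE)
    }
  }
  fung_df <- if (length(fung_rows)) do.call(rbind, fung_rows) else {
    data.frame(icd10cm = character(), icd11_precoordinated = character(),
               icd11_postcoordinated = character(), FinalMaptype = character())
  }
  fung_df <- fung_df[order(fung_df$icd10cm), , drop = FALSE]
  utils::write.csv(fung_df, paths[["fung"]], row.names = FALSE, quote = FALSE)

  cat_all <- rbind(universe$cat_table_icd9, universe$cat_table_icd10)
  utils::write.table(cat_all, paths[["categories"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(config = unclass(universe$config),
                categories = universe$categories,
                n_pairs_9_10 = n_pairs(universe$xw_9_10),
                n_pairs_10_11 = n_pairs(universe$xw_10_11),
                unmapped_codes = universe$unmapped,
                children = universe$children)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
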