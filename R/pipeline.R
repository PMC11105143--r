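#' Identity crosswalk over a set of codes
#'
#' Maps every code to itself across versions. Useful as a null
#' transformation: converting a population through an identity crosswalk
#' must leave every score unchanged.
#'
#' @param codes character vector of source codes.
#' @param source_version,target_version version tags.
#' @return An `icd_crosswalk` with one 1-1 entry per code (provenance
#'   `MANUAL`).
#' @export
identity_crosswalk <- function(codes, source_version = "ICD10CM",
                               target_version = "ICD11MMS") {
  codes <- unique(normalize_code(codes, source_version))
  crosswalk(source_version, target_version,
            data.frame(source = codes, target = codes, provenance = "MANUAL",
                       stringsAsFactors = FALSE))
}

#' Rank unmapped codes by stay frequency for manual review
#'
#' The manual mapping stage of the study applies to codes that remain
#' unmapped after the automated steps; this reporting filter lists the 1-0
#' codes of a universe ranked by the number of stays in which they occur,
#' for human review. The pipeline never auto-selects manual mappings.
#'
#' @param xw an `icd_crosswalk`.
#' @param diagnoses long diagnosis table (`stay_id`, `code`, `version`).
#' @param universe codes to audit (default: the diagnosis codes of the
#'   crosswalk's source version).
#' @param min_stays report only codes present in at least this many stays.
#' @return data.frame `code`, `n_stays`, sorted by decreasing frequency.
#' @export
manual_review_candidates <- function(xw, diagnoses, universe = NULL,
                                     min_stays = 0L) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  dg <- diagnoses[diagnoses$version == xw$source_version, , drop = FALSE]
  if (is.null(universe)) universe <- unique(dg$code)
  unmapped <- setdiff(unique(normalize_code(universe, xw$source_version)),
                      unique(xw$entries$source))
  if (length(unmapped) == 0L) {
    return(data.frame(code = character(), n_stays = integer()))
  }
  per <- unique(dg[, c("stay_id", "code")])
  freq <- table(factor(per$code, levels = unmapped))
  out <- data.frame(code = names(freq), n_stays = as.integer(freq),
                    stringsAsFactors = FALSE)
  out <- out[out$n_stays >= min_stays, , drop = FALSE]
  out[order(-out$n_stays, out$code), , drop = FALSE]
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

input_manifest <- function(paths) {
  paths <- paths[file.exists(paths)]
  data.frame(file = basename(unname(paths)),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Simulate the full synthetic input bundle
#'
#' Writes everything the downstream pipeline stages consume: the four
#' mapping-source files, the truth category tables, `truth.json`, and the
#' MIMIC-layout `diagnoses.csv` / `admissions.csv`. Output is fully
#' determined by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return Invisibly, a list with the `universe`, `cohort` and file paths.
#' @export
pipeline_simulate <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  universe <- generate_code_universe(config)
  cohort <- generate_cohort(config, universe)
  p1 <- write_mapping_sources(universe, dir)
  p2 <- write_mimic_like(cohort, dir)
  invisible(list(universe = universe, cohort = cohort, paths = c(p1, p2)))
}

#' Build and audit the crosswalks from a source-file directory
#'
#' Runs the mapping-table creation procedure: load the GEM and
#' concept-equivalence sources (ICD-9-CM to ICD-10-CM), load the WHO and
#' Fung-style sources (ICD-10-CM to ICD-11-MMS), merge each pair, apply
#' optional manual overrides, complete the 10-to-11 table by hierarchy
#' reverse engineering over the codes in use, and compose the 9-to-11
#' table through ICD-10-CM. Writes canonical crosswalk TSVs, a cardinality
#' report (TSV + JSON), the manual-review candidate list and an input
#' manifest.
#'
#' @param dir directory holding the source bundle (file names as written by
#'   [pipeline_simulate()]; individual paths can be overridden).
#' @param out_dir output directory (default `<dir>/crosswalk`).
#' @param paths optional named overrides for `gem`, `mrconso`, `who_one`,
#'   `who_multi`, `fung`, `diagnoses`.
#' @param overrides_9_10,overrides_10_11 optional manual-override TSVs.
#' @return Invisibly, a list with crosswalks `xw_9_10`, `xw_10_11`,
#'   `xw_9_11` and their cardinality summaries.
#' @export
pipeline_build_crosswalk <- function(dir, out_dir = file.path(dir, "crosswalk"),
                                     paths = list(),
                                     overrides_9_10 = NULL,
                                     overrides_10_11 = NULL) {
  defaults <- list(gem = file.path(dir, "gem_icd9_icd10.txt"),
                   mrconso = file.path(dir, "mrconso.rrf"),
                   who_one = file.path(dir, "who_10To11MapToOneCategory.tsv"),
                   who_multi = file.path(dir, "who_10To11MapToMultipleCategories.tsv"),
                   fung = file.path(dir, "fung_icd10cm_icd11.csv"),
                   diagnoses = file.path(dir, "diagnoses.csv"))
  paths <- utils::modifyList(defaults, paths)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("crosswalk build failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  xw_gem <- stage("load_gem", load_gem_table(paths$gem))
  xw_umls <- stage("load_concept_equivalences",
                   load_concept_equivalences(paths$mrconso, "ICD9CM", "ICD10CM"))
  xw_9_10 <- stage("merge_9_10", merge_crosswalks(list(xw_gem, xw_umls)))
  if (!is.null(overrides_9_10)) {
    xw_9_10 <- stage("manual_overrides_9_10",
                     apply_manual_overrides(xw_9_10,
                                            read_override_table(overrides_9_10)))
  }
  xw_who <- stage("load_who",
                  load_who_icd10_to_icd11(c(paths$who_one, paths$who_multi)))
  xw_fung <- stage("load_fung", load_fung_map(paths$fung))
  xw_10_11 <- stage("merge_10_11", merge_crosswalks(list(xw_fung, xw_who)))
  if (!is.null(overrides_10_11)) {
    xw_10_11 <- stage("manual_overrides_10_11",
                      apply_manual_overrides(xw_10_11,
                                             read_override_table(overrides_10_11)))
  }
  diagnoses <- stage("read_diagnoses", read_diagnoses(paths$diagnoses))
  # ICD-10-CM codes in use: present in the data or reachable from ICD-9-CM
  universe10 <- union(unique(diagnoses$code[diagnoses$version == "ICD10CM"]),
                      unique(xw_9_10$entries$target))
  xw_10_11 <- stage("reverse_engineering",
                    reverse_engineer_from_hierarchy(xw_10_11, universe10))
  xw_9_11 <- stage("compose_9_11", compose_crosswalks(xw_9_10, xw_10_11))

  universe9 <- unique(diagnoses$code[diagnoses$version == "ICD9CM"])
  summaries <- list(
    icd9_to_icd10 = if (length(universe9)) {
      cardinality_summary(xw_9_10, universe9)
    },
    icd10_to_icd11 = if (length(universe10)) {
      cardinality_summary(xw_10_11, universe10)
    },
    icd9_to_icd11 = if (length(universe9)) {
      cardinality_summary(xw_9_11, universe9)
    })
  summaries <- summaries[!vapply(summaries, is.null, TRUE)]

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_crosswalk(xw_9_10, file.path(out_dir, "xw_icd9_icd10.tsv"))
  write_crosswalk(xw_10_11, file.path(out_dir, "xw_icd10_icd11.tsv"))
  write_crosswalk(xw_9_11, file.path(out_dir, "xw_icd9_icd11.tsv"))
  card <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(mapping = nm, n_unmapped = s$n_unmapped, n_one = s$n_one,
               n_multi = s$n_multi, universe_size = s$universe_size,
               n_pairs = NA_integer_, stringsAsFactors = FALSE)
  }))
  card$n_pairs <- c(icd9_to_icd10 = n_pairs(xw_9_10),
                    icd10_to_icd11 = n_pairs(xw_10_11),
                    icd9_to_icd11 = n_pairs(xw_9_11))[card$mapping]
  utils::write.table(card, file.path(out_dir, "cardinality_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_report(card, file.path(out_dir, "cardinality_report.json"))
  review <- manual_review_candidates(xw_10_11, diagnoses,
                                     universe = universe10)
  utils::write.table(review,
                     file.path(out_dir, "manual_review_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(input_manifest(unlist(paths)),
                     file.path(out_dir, "input_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(xw_9_10 = xw_9_10, xw_10_11 = xw_10_11, xw_9_11 = xw_9_11,
                 summaries = summaries, cardinality = card))
}

#' Run the cross-coding comorbidity study
#'
#' Assembles the eligible populations (A1: ICD-10-CM, A2: ICD-9-CM),
#' derives their ICD-11-MMS counterparts (B1, B2) through the built
#' crosswalks, infers the ICD-11 category table by mapping inheritance,
#' scores every population, and compares codings: per-population mean/SD
#' summary, paired t tests, Pearson correlations with Fisher intervals,
#' backward stepwise logistic reweighting against in-hospital mortality,
#' integer weight derivation and Spearman comparison of the weight
#' vectors. All outputs are written as sorted TSV / JSON under `out_dir`.
#'
#' @param dir directory holding `diagnoses.csv`, `admissions.csv` and
#'   (optionally) `category_codes_synthetic.tsv` and `truth.json`.
#' @param crosswalk_dir directory with the canonical crosswalk TSVs
#'   (default `<dir>/crosswalk`).
#' @param out_dir output directory (default `<dir>/study`).
#' @param index index to score. The weight scheme defaults to the truth
#'   weights when `truth.json` is present, else to `CHARLSON_ORIGINAL`
#'   (CCI) / `VAN_WALRAVEN` (ECI).
#' @param category_table category table covering ICD-9-CM and ICD-10-CM;
#'   default: the bundle's synthetic table if present, else the packaged
#'   Quan table.
#' @param scheme optional [weight_scheme()] override.
#' @param stepwise_threshold Wald p elimination threshold.
#' @param confidence Pearson CI level.
#' @return Invisibly, a list with populations, score results, comparisons,
#'   reweighting results and weight comparisons.
#' @export
pipeline_run_study <- function(dir, crosswalk_dir = file.path(dir, "crosswalk"),
                               out_dir = file.path(dir, "study"),
                               index = "CCI", category_table = NULL,
                               scheme = NULL, stepwise_threshold = 0.05,
                               confidence = 0.95) {
  diagnoses <- read_diagnoses(file.path(dir, "diagnoses.csv"))
  admissions <- read_admissions(file.path(dir, "admissions.csv"))
  syn_tab <- file.path(dir, "category_codes_synthetic.tsv")
  if (is.null(category_table)) {
    category_table <- if (file.exists(syn_tab)) {
      load_category_table(syn_tab)
    } else {
      load_category_table()
    }
  }
  truth_path <- file.path(dir, "truth.json")
  if (is.null(scheme)) {
    if (file.exists(truth_path)) {
      truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
      scheme <- weight_scheme("CUSTOM",
                              stats::setNames(truth$categories$weight,
                                              truth$categories$category))
    } else {
      scheme <- weight_scheme(if (index == "ECI") "VAN_WALRAVEN"
                              else "CHARLSON_ORIGINAL")
    }
  }
  xw_10_11 <- read_crosswalk(file.path(crosswalk_dir, "xw_icd10_icd11.tsv"))
  xw_9_11 <- read_crosswalk(file.path(crosswalk_dir, "xw_icd9_icd11.tsv"))

  stays <- filter_eligible(diagnoses, admissions, xw_10_11, xw_9_11)
  if (nrow(stays) == 0L) {
    stop("no eligible stays: every stay was rejected by the filters",
         call. = FALSE)
  }
  pops <- build_source_populations(stays)
  populations <- list(A1 = pops$A1, A2 = pops$A2)
  if (nrow(pops$A1$stays)) populations$B1 <- convert_to_icd11(pops$A1, xw_10_11)
  if (nrow(pops$A2$stays)) populations$B2 <- convert_to_icd11(pops$A2, xw_9_11)

  icd11_table <- infer_icd11_category_table(category_table, xw_10_11, index)
  full_table <- as_category_table(rbind(as.data.frame(category_table),
                                        as.data.frame(icd11_table)))

  results <- list()
  for (nm in names(populations)) {
    pop <- populations[[nm]]
    if (nrow(pop$stays) == 0L) next
    results[[nm]] <- score_population(pop, index, full_table, scheme)
  }

  comparisons <- list()
  reweights <- list()
  weight_comparisons <- list()
  for (pair in list(c("A1", "B1"), c("A2", "B2"))) {
    a <- pair[[1L]]; b <- pair[[2L]]
    if (is.null(results[[a]]) || is.null(results[[b]])) next
    comparisons[[paste0(a, "_", b)]] <-
      compare_distributions(results[[a]]$scores, results[[b]]$scores,
                            index = index, confidence = confidence)
    for (nm in pair) {
      if (is.null(reweights[[nm]])) {
        reweights[[nm]] <- reweight_categories(results[[nm]]$flags,
                                               results[[nm]]$died,
                                               threshold = stepwise_threshold)
      }
    }
    wa <- reweights[[a]]$weights
    wb <- reweights[[b]]$weights
    both <- intersect(reweights[[a]]$retained, reweights[[b]]$retained)
    safe_spearman <- function(x, y) {
      # undefined when a weight vector is constant (e.g. all eliminated)
      tryCatch(spearman_rank(x, y),
               error = function(e) list(rho = NA_real_, p = NA_real_,
                                        n = length(x)))
    }
    weight_comparisons[[paste0(a, "_", b)]] <- list(
      all_categories = safe_spearman(wa, wb[names(wa)]),
      retained_in_both = if (length(both) >= 3L) {
        safe_spearman(wa[both], wb[both])
      },
      n_retained_a = length(reweights[[a]]$retained),
      n_retained_b = length(reweights[[b]]$retained))
  }

  # ---- report bundle -----------------------------------------------------
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_tab <- do.call(rbind, lapply(names(results), function(nm) {
    s <- summarize_scores(results[[nm]]$scores)
    data.frame(population = nm, index = index, n_stays = s$n,
               mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
  }))
  utils::write.table(summary_tab, file.path(out_dir, "summary_table2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(results)) {
    r <- results[[nm]]
    utils::write.table(
      data.frame(stay_id = r$stay_id, score = r$scores, died = r$died),
      file.path(out_dir, paste0("scores_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    utils::write.table(cmp$histogram_a,
                       file.path(out_dir, paste0("histogram_",
                                                 strsplit(nm, "_")[[1L]][[1L]],
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$histogram_b,
                       file.path(out_dir, paste0("histogram_",
                                                 strsplit(nm, "_")[[1L]][[2L]],
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp$histogram_a <- cmp$histogram_b <- NULL
    write_json_report(unclass(cmp),
                      file.path(out_dir, paste0("comparison_", nm, ".json")))
  }
  for (nm in names(reweights)) {
    r <- reweights[[nm]]
    utils::write.table(
      data.frame(category = names(r$coefficients),
                 coefficient = unname(r$coefficients),
                 se = unname(r$se), p_value = unname(r$p_values),
                 retained = names(r$coefficients) %in% r$retained,
                 weight = unname(r$weights[names(r$coefficients)])),
      file.path(out_dir, paste0("reweight_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(weight_comparisons)) {
    write_json_report(weight_comparisons,
                      file.path(out_dir, "weight_comparison.json"))
  }
  write_json_report(attr(stays, "audit"),
                    file.path(out_dir, "filter_audit.json"))
  write_json_report(list(index = index,
                         scheme = attr(scheme, "scheme"),
                         weights = as.list(stats::setNames(as.numeric(scheme),
                                                           names(scheme))),
                         stepwise_threshold = stepwise_threshold,
                         confidence = confidence,
                         dir = normalizePath(dir)),
                    file.path(out_dir, "config_echo.json"))
  utils::write.table(
    input_manifest(c(file.path(dir, c("diagnoses.csv", "admissions.csv")),
                     file.path(crosswalk_dir,
                               c("xw_icd9_icd10.tsv", "xw_icd10_icd11.tsv",
                                 "xw_icd9_icd11.tsv")))),
    file.path(out_dir, "input_manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(populations = populations, results = results,
                 comparisons = comparisons, reweights = reweights,
                 weight_comparisons = weight_comparisons,
                 summary = summary_tab, audit = attr(stays, "audit"),
                 icd11_table = icd11_table, scheme = scheme))
}
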