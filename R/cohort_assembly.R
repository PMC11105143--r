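#' Read a MIMIC-layout diagnosis table
#'
#' Expects a CSV with columns `subject_id`, `hadm_id`, `seq_num`,
#' `icd_code`, `icd_version` (integer 9 or 10). Codes are normalized on
#' input; the version integer is decoded into a version tag. Rows with any
#' other version value are rejected with an error reporting their count,
#' and duplicate (stay, seq_num) pairs are an error.
#'
#' @param path CSV file path.
#' @return data.frame with columns `subject_id`, `stay_id`, `seq_num`,
#'   `code`, `version`.
#' @export
read_diagnoses <- function(path) {
  if (!file.exists(path)) stop("cannot read diagnoses file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = "icd_code"))
  need <- c("subject_id", "hadm_id", "seq_num", "icd_code", "icd_version")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("diagnoses file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !(dt$icd_version %in% c(9L, 10L))
  if (any(bad)) {
    stop(sum(bad), " diagnosis row(s) with unsupported icd_version ",
         "(source data must be coded in ICD-9-CM or ICD-10-CM)",
         call. = FALSE)
  }
  if (anyDuplicated(dt[, c("hadm_id", "seq_num")])) {
    stop("duplicate (hadm_id, seq_num) pairs in diagnoses file", call. = FALSE)
  }
  version <- ifelse(dt$icd_version == 9L, "ICD9CM", "ICD10CM")
  code <- dt$icd_code
  code[version == "ICD9CM"] <- normalize_code(code[version == "ICD9CM"], "ICD9CM")
  code[version == "ICD10CM"] <- normalize_code(code[version == "ICD10CM"], "ICD10CM")
  data.frame(subject_id = dt$subject_id, stay_id = dt$hadm_id,
             seq_num = dt$seq_num, code = code, version = version,
             stringsAsFactors = FALSE)
}

#' Read a stay-level admissions table with the mortality flag
#'
#' @param path CSV with columns `hadm_id` and `hospital_expire_flag`
#'   (or `died`); `subject_id` is carried through when present.
#' @return data.frame with columns `stay_id`, `died` (logical).
#' @export
read_admissions <- function(path) {
  if (!file.exists(path)) stop("cannot read admissions file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE)
  if (!"hadm_id" %in% names(dt)) {
    stop("admissions file lacks column hadm_id", call. = FALSE)
  }
  flag_col <- intersect(c("hospital_expire_flag", "died"), names(dt))
  if (length(flag_col) == 0L) {
    stop("admissions file lacks a mortality flag column ",
         "(hospital_expire_flag or died)", call. = FALSE)
  }
  data.frame(stay_id = dt$hadm_id,
             died = as.logical(as.integer(dt[[flag_col[[1L]]]])),
             stringsAsFactors = FALSE)
}

#' Filter stays eligible for cross-version analysis
#'
#' A stay is retained iff (i) all its diagnosis records share one coding
#' version (never both ICD-9-CM and ICD-10-CM in the same stay) and
#' (ii) every one of its codes has a non-empty ICD-11-MMS target set under
#' the crosswalk for its version. Rejections are tallied by reason in the
#' `"audit"` attribute.
#'
#' @param diagnoses data.frame from [read_diagnoses()].
#' @param admissions data.frame from [read_admissions()]; stays without a
#'   mortality flag are rejected (reason `no_mortality_flag`).
#' @param xw_10_11 `ICD10CM -> ICD11MMS` crosswalk.
#' @param xw_9_11 `ICD9CM -> ICD11MMS` crosswalk (composed through
#'   ICD-10-CM).
#' @return data.frame of stays: `stay_id`, `subject_id`, `version`, `died`,
#'   and a `codes` list-column of deduplicated normalized code sets, with
#'   attribute `"audit"` (counts by rejection reason).
#' @export
filter_eligible <- function(diagnoses, admissions, xw_10_11, xw_9_11) {
  stopifnot(inherits(xw_10_11, "icd_crosswalk"), inherits(xw_9_11, "icd_crosswalk"))
  dt <- as.data.table(diagnoses)
  if (is.null(dt$subject_id)) dt[, subject_id := stay_id]
  mapped10 <- unique(xw_10_11$entries$source)
  mapped9 <- unique(xw_9_11$entries$source)
  dt[, mapped := (version == "ICD10CM" & code %in% mapped10) |
       (version == "ICD9CM" & code %in% mapped9)]
  per_stay <- dt[, .(subject_id = subject_id[[1L]],
                     n_versions = data.table::uniqueN(version),
                     version = version[[1L]],
                     all_mapped = all(mapped),
                     codes = list(sort(unique(code)))),
                 by = stay_id]
  adm <- as.data.table(admissions)[, .(stay_id, died)]
  per_stay <- merge(per_stay, adm, by = "stay_id", all.x = TRUE, sort = FALSE)
  mixed <- per_stay$n_versions > 1L
  unmapped <- !mixed & !per_stay$all_mapped
  noflag <- !mixed & !unmapped & is.na(per_stay$died)
  keep <- !(mixed | unmapped | noflag)
  audit <- list(n_total = nrow(per_stay),
                n_mixed_version = sum(mixed),
                n_unmappable = sum(unmapped),
                n_no_mortality_flag = sum(noflag),
                n_eligible = sum(keep))
  out <- as.data.frame(per_stay[keep, .(stay_id, subject_id, version, died, codes)])
  attr(out, "audit") <- audit
  out
}

#' Partition eligible stays into the native-coding populations
#'
#' Population A1 holds the stays coded in ICD-10-CM, population A2 those in
#' ICD-9-CM; input order is preserved within each population.
#'
#' @param stays data.frame from [filter_eligible()].
#' @return Named list of two `icd_population` objects, `A1` and `A2`.
#' @export
build_source_populations <- function(stays) {
  list(A1 = new_population("A1", "ICD10CM",
                           stays[stays$version == "ICD10CM", , drop = FALSE]),
       A2 = new_population("A2", "ICD9CM",
                           stays[stays$version == "ICD9CM", , drop = FALSE]))
}

new_population <- function(label, version, stays) {
  rownames(stays) <- NULL
  structure(list(label = label, version = version, stays = stays),
            class = "icd_population")
}

#' @export
print.icd_population <- function(x, ...) {
  cat("<icd_population> ", x$label, " (", x$version, "): ",
      nrow(x$stays), " stays, ", sum(x$stays$died), " deaths\n", sep = "")
  invisible(x)
}

#' Convert a population to ICD-11-MMS coding
#'
#' Replaces each stay's code set by the deduplicated union of the ICD-11
#' targets of its codes. Stay count, order, ids and mortality flags are
#' unchanged; labels follow A1 -> B1, A2 -> B2. An unmapped code (which
#' eligibility filtering should have excluded) is an integrity error.
#'
#' @param pop an `icd_population` with version `ICD9CM` or `ICD10CM`.
#' @param xw crosswalk whose source version matches `pop$version` and whose
#'   target version is `ICD11MMS`.
#' @return The converted `icd_population` (version `ICD11MMS`).
#' @export
convert_to_icd11 <- function(pop, xw) {
  stopifnot(inherits(pop, "icd_population"), inherits(xw, "icd_crosswalk"))
  if (xw$source_version != pop$version) {
    stop("crosswalk source version (", xw$source_version,
         ") does not match population coding (", pop$version, ")",
         call. = FALSE)
  }
  targets <- split(xw$entries$target, xw$entries$source)
  all_codes <- unique(unlist(pop$stays$codes, use.names = FALSE))
  missing_map <- setdiff(all_codes, names(targets))
  if (length(missing_map)) {
    stop("integrity error: unmapped code(s) in an eligible population: ",
         paste(utils::head(missing_map, 10L), collapse = ", "), call. = FALSE)
  }
  stays <- pop$stays
  stays$codes <- lapply(stays$codes, function(cs) {
    sort(unique(unlist(targets[cs], use.names = FALSE)))
  })
  label <- c(A1 = "B1", A2 = "B2")[[pop$label]]
  if (is.na(label)) label <- paste0(pop$label, "_icd11")
  new_population(label, xw$target_version, stays)
}

#' Long diagnosis view of a population
#'
#' @param pop an `icd_population`.
#' @return data.frame with columns `stay_id`, `code` (one row per stay-code).
#' @export
population_diagnoses <- function(pop) {
  stopifnot(inherits(pop, "icd_population"))
  n <- lengths(pop$stays$codes)
  data.frame(stay_id = rep(pop$stays$stay_id, n),
             code = unlist(pop$stays$codes, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Score a population
#'
#' Assigns category flags, applies the severity hierarchy and computes the
#' index score per stay.
#'
#' @param pop an `icd_population`.
#' @param index index name.
#' @param category_table a `category_table` covering `pop$version`.
#' @param scheme a [weight_scheme()].
#' @param pairs severity pairs (defaults to the packaged hierarchy for the
#'   index, none for unknown indices).
#' @return List with `flags` (logical matrix, hierarchy applied), `scores`
#'   (numeric), `stay_id`, `died`.
#' @export
score_population <- function(pop, index, category_table, scheme,
                             pairs = SEVERITY_PAIRS[[index]]) {
  stopifnot(inherits(pop, "icd_population"))
  flags <- flag_matrix(population_diagnoses(pop), pop$version, index,
                       category_table, stay_ids = pop$stays$stay_id)
  flags <- apply_severity_hierarchy(flags, index, pairs)
  list(stay_id = pop$stays$stay_id, died = pop$stays$died,
       flags = flags, scores = score_flags(flags, scheme))
}
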