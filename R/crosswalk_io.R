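#' Load a GEM flat mapping file (ICD-9-CM to ICD-10-CM)
#'
#' General Equivalence Mapping files are whitespace-delimited with three
#' fields per row: source code, target code, and a 5-digit flag string
#' (approximate, no-map, combination, scenario, choice-list). Rows whose
#' no-map flag (second digit) is 1 are excluded; every other row becomes one
#' entry, so combination scenarios contribute one entry per listed target
#' row. Provenance `GEM`.
#'
#' @param path path to the GEM file.
#' @param source_version,target_version version tags of the two columns.
#' @return An `icd_crosswalk`.
#' @export
load_gem_table <- function(path, source_version = "ICD9CM",
                           target_version = "ICD10CM") {
  if (!file.exists(path)) stop("cannot read GEM file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(crosswalk(source_version, target_version))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop("malformed GEM row(s) at line(s) ",
         paste(utils::head(which(nf != 3L), 10L), collapse = ", "),
         ": expected 3 whitespace-delimited fields", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  flags <- m[, 3L]
  bad <- !grepl("^[01]{5}$", flags)
  if (any(bad)) {
    stop("malformed GEM flag string at line(s) ",
         paste(utils::head(which(bad), 10L), collapse = ", "),
         " (expected 5 binary digits)", call. = FALSE)
  }
  keep <- substr(flags, 2L, 2L) == "0"  # drop no-map rows
  if (!any(keep)) return(crosswalk(source_version, target_version))
  crosswalk(source_version, target_version,
            data.frame(source = normalize_code(m[keep, 1L], source_version),
                       target = normalize_code(m[keep, 2L], target_version),
                       provenance = "GEM", stringsAsFactors = FALSE))
}

# Standard MRCONSO.RRF column positions (pipe-delimited, 18 fields)
MRCONSO_COLS <- c("CUI", "LAT", "TS", "LUI", "STT", "SUI", "ISPREF", "AUI",
                  "SAUI", "SCUI", "SDUI", "SAB", "TTY", "CODE", "STR",
                  "SRL", "SUPPRESS", "CVF")

#' Load concept equivalences from an MRCONSO-layout file
#'
#' Codes of two vocabularies sharing a Concept Unique Identifier (CUI)
#' denote the same concept: for every CUI, each source-vocabulary code is
#' mapped to every target-vocabulary code under that CUI (cross product).
#' Provenance `CONCEPT_EQUIV`.
#'
#' @param path pipe-delimited file in the UMLS MRCONSO column layout
#'   (CUI first field, SAB at position 12, CODE at position 14).
#' @param source_vocab,target_vocab SAB vocabulary identifiers to pair
#'   (e.g. `"ICD9CM"`, `"ICD10CM"`).
#' @param source_version,target_version ICD version tags of the two
#'   vocabularies.
#' @return An `icd_crosswalk`.
#' @export
load_concept_equivalences <- function(path, source_vocab, target_vocab,
                                      source_version = "ICD9CM",
                                      target_version = "ICD10CM") {
  if (!file.exists(path)) stop("cannot read concept file: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, sep = "|", header = FALSE, quote = "",
                      colClasses = "character", fill = TRUE),
    error = function(e) stop("cannot parse MRCONSO-layout file: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) return(crosswalk(source_version, target_version))
  if (ncol(dt) < 14L) {
    stop("MRCONSO-layout file is missing required columns (need at least ",
         "14 pipe-delimited fields; found ", ncol(dt), ")", call. = FALSE)
  }
  cui <- dt[[1L]]; sab <- dt[[12L]]; code <- dt[[14L]]
  src <- data.table(cui = cui[sab == source_vocab],
                    source = code[sab == source_vocab])
  tgt <- data.table(cui = cui[sab == target_vocab],
                    target = code[sab == target_vocab])
  if (nrow(src) == 0L || nrow(tgt) == 0L) {
    return(crosswalk(source_version, target_version))
  }
  joined <- merge(src, tgt, by = "cui", allow.cartesian = TRUE)
  if (nrow(joined) == 0L) return(crosswalk(source_version, target_version))
  crosswalk(source_version, target_version,
            data.frame(source = normalize_code(joined$source, source_version),
                       target = normalize_code(joined$target, target_version),
                       provenance = "CONCEPT_EQUIV", stringsAsFactors = FALSE))
}

#' Load WHO ICD-10 to ICD-11 map files
#'
#' Reads the WHO release map tables (the "10To11MapToOneCategory" and
#' "10To11MapToMultipleCategories" TSV files) and unions their rows.
#' Only the two code columns are read; rows missing either code are skipped
#' with a warning reporting the count. Provenance `WHO_MAP`.
#'
#' @param paths character vector of TSV file paths.
#' @param icd10_col,icd11_col names of the ICD-10 and ICD-11 code columns.
#' @param source_version version tag for the ICD-10 side (default
#'   `"ICD10CM"`, matching application of the WHO map to clinical
#'   modification codes).
#' @return An `icd_crosswalk` to `ICD11MMS`.
#' @export
load_who_icd10_to_icd11 <- function(paths, icd10_col = "icd10Code",
                                    icd11_col = "icd11Code",
                                    source_version = "ICD10CM") {
  rows <- list()
  n_skipped <- 0L
  for (path in paths) {
    if (!file.exists(path)) stop("cannot read WHO map file: ", path, call. = FALSE)
    dt <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                            colClasses = "character", fill = TRUE)
    if (nrow(dt) == 0L) next
    missing_cols <- setdiff(c(icd10_col, icd11_col), names(dt))
    if (length(missing_cols)) {
      stop("WHO map file ", path, " lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    s <- trimws(dt[[icd10_col]]); t <- trimws(dt[[icd11_col]])
    ok <- !is.na(s) & nzchar(s) & !is.na(t) & nzchar(t)
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) {
      rows[[length(rows) + 1L]] <-
        data.frame(source = normalize_code(s[ok], source_version),
                   target = vapply(t[ok], function(x) parse_expression(x)$raw, ""),
                   provenance = "WHO_MAP", stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L) {
    warning("skipped ", n_skipped, " WHO map row(s) missing a code",
            call. = FALSE)
  }
  if (length(rows) == 0L) return(crosswalk(source_version, "ICD11MMS"))
  crosswalk(source_version, "ICD11MMS", do.call(rbind, rows))
}

#' Load an ICD-10-CM to ICD-11 map table with postcoordination
#'
#' Reads a map table in the style of Fung et al.: one row per ICD-10-CM
#' code with a precoordinated ICD-11-MMS code, an optional postcoordinated
#' expression, and a `FinalMaptype` tag. When the tag reads
#' `"full map by post coordination"` only the postcoordinated expression is
#' retained as the mapping; otherwise both the precoordinated code and
#' (when present) the postcoordinated expression are retained.
#' Provenance `FUNG_MAP`.
#'
#' @param path TSV/CSV file (delimiter sniffed by [data.table::fread]).
#' @param icd10_col,pre_col,post_col,maptype_col column names.
#' @return An `icd_crosswalk` `ICD10CM -> ICD11MMS`.
#' @export
load_fung_map <- function(path, icd10_col = "icd10cm",
                          pre_col = "icd11_precoordinated",
                          post_col = "icd11_postcoordinated",
                          maptype_col = "FinalMaptype") {
  if (!file.exists(path)) stop("cannot read map file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          fill = TRUE)
  missing_cols <- setdiff(c(icd10_col, pre_col, post_col, maptype_col), names(dt))
  if (length(missing_cols)) {
    stop("map file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0L) return(crosswalk("ICD10CM", "ICD11MMS"))
  src <- trimws(dt[[icd10_col]])
  pre <- trimws(dt[[pre_col]])
  post <- trimws(dt[[post_col]])
  tag <- tolower(trimws(dt[[maptype_col]]))
  full_post <- tag == "full map by post coordination"
  bad <- full_post & (is.na(post) | !nzchar(post))
  if (any(bad)) {
    stop("row(s) ", paste(utils::head(which(bad), 10L), collapse = ", "),
         " tagged 'full map by post coordination' but the postcoordinated ",
         "expression column is empty", call. = FALSE)
  }
  rows <- list()
  keep_pre <- !full_post & !is.na(pre) & nzchar(pre)
  if (any(keep_pre)) {
    rows$pre <- data.frame(source = src[keep_pre], target = pre[keep_pre],
                           stringsAsFactors = FALSE)
  }
  keep_post <- !is.na(post) & nzchar(post)
  if (any(keep_post)) {
    rows$post <- data.frame(source = src[keep_post], target = post[keep_post],
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(crosswalk("ICD10CM", "ICD11MMS"))
  entries <- do.call(rbind, rows)
  crosswalk("ICD10CM", "ICD11MMS",
            data.frame(source = normalize_code(entries$source, "ICD10CM"),
                       target = vapply(entries$target,
                                       function(x) parse_expression(x)$raw, ""),
                       provenance = "FUNG_MAP", stringsAsFactors = FALSE))
}

#' Read a manual override table
#'
#' @param path two-column TSV with header `source`, `target`.
#' @return data.frame with columns `source`, `target`.
#' @export
read_override_table <- function(path) {
  if (!file.exists(path)) stop("cannot read override table: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", fill = TRUE)
  if (!all(c("source", "target") %in% names(dt))) {
    stop("override table needs columns source, target", call. = FALSE)
  }
  as.data.frame(dt[, c("source", "target"), with = FALSE])
}

#' Serialize a crosswalk to canonical TSV
#'
#' Writes the 4-column TSV (source, target, provenance, flavor) sorted
#' lexicographically by (source, target), making pair counts and diffs
#' auditable; identical crosswalks serialize byte-identically.
#'
#' @param xw an `icd_crosswalk`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(xw, path) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  e <- xw$entries
  e <- e[order(e$source, e$target), , drop = FALSE]
  header <- paste0("# crosswalk\t", xw$source_version, "\t", xw$target_version)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste("source", "target", "provenance", "flavor", sep = "\t"), con)
  if (nrow(e)) {
    writeLines(paste(e$source, e$target, e$provenance, e$flavor, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a crosswalk written by [write_crosswalk()]
#'
#' @param path path to a canonical crosswalk TSV.
#' @return An `icd_crosswalk`.
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) stop("cannot read crosswalk file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  parts <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || parts[[1L]] != "# crosswalk") {
    stop("not a canonical crosswalk TSV (missing version header): ", path,
         call. = FALSE)
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = "character", fill = TRUE)
  crosswalk(parts[[2L]], parts[[3L]], as.data.frame(dt))
}
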