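#' Category universe of a table for one index
#'
#' @keywords internal
table_categories <- function(category_table, index) {
  cats <- unique(category_table$category[category_table$index == index])
  if (length(cats) == 0L) {
    stop("category table has no categories for index ", index, call. = FALSE)
  }
  cats
}

# Match a vector of normalized code stems against the (index, version) slice
# of a category table. Returns a data.table (code, category), one row per
# (code, matching category). Prefix rows match any code starting with them;
# exact rows match by equality. Any match sets the flag.
match_categories <- function(codes, version, index, category_table) {
  tab <- category_table[category_table$index == index &
                          category_table$version == version, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("category table covers no codes for index ", index,
         " in version ", version, call. = FALSE)
  }
  codes <- unique(codes)
  hits <- list()
  exact <- tab[tab$match == "exact", , drop = FALSE]
  if (nrow(exact)) {
    e <- data.table(code = codes)[
      data.table(code = exact$code, category = exact$category),
      on = "code", nomatch = NULL]
    hits$exact <- e
  }
  pref <- tab[tab$match == "prefix", , drop = FALSE]
  if (nrow(pref)) {
    lens <- sort(unique(nchar(pref$code)))
    ptab <- data.table(pfx = pref$code, category = pref$category)
    expanded <- rbindlist(lapply(lens, function(k) {
      keep <- nchar(codes) >= k
      data.table(code = codes[keep], pfx = substr(codes[keep], 1L, k))
    }))
    p <- merge(expanded, ptab, by = "pfx", allow.cartesian = TRUE)
    hits$prefix <- p[, .(code, category)]
  }
  out <- rbindlist(hits, use.names = TRUE, fill = TRUE)
  if (nrow(out) == 0L) return(data.table(code = character(), category = character()))
  unique(out[, .(code, category)])
}

#' Assign comorbidity category flags to one coded stay
#'
#' A category flag is set iff any of the stay's codes matches one of the
#' category's code prefixes (or exact codes) for the stated version.
#' Postcoordinated ICD-11 expressions match through their stem; extension
#' codes never alter category membership.
#'
#' @param codes character vector of codes / postcoordinated expressions for
#'   one stay (raw or normalized).
#' @param version version tag shared by all codes.
#' @param index `"CCI"` or `"ECI"` (or the index name used by a custom
#'   table).
#' @param category_table a `category_table` (default: packaged Quan table).
#' @return Named logical vector over the index's categories.
#' @examples
#' assign_flags("E13620", "ICD10CM", "CCI")  # diabwc
#' @export
assign_flags <- function(codes, version, index,
                         category_table = load_category_table()) {
  check_version(version)
  cats <- table_categories(category_table, index)
  flags <- stats::setNames(logical(length(cats)), cats)
  if (length(codes)) {
    stems <- normalize_code(expression_stem(codes), version)
    hits <- match_categories(stems, version, index, category_table)
    flags[unique(hits$category)] <- TRUE
  }
  flags
}

#' Category flag matrix for a cohort
#'
#' Vectorized version of [assign_flags()] over a long diagnosis table.
#'
#' @param diagnoses data.frame with columns `stay_id` and `code`.
#' @param version version tag shared by all codes.
#' @inheritParams assign_flags
#' @param stay_ids optional vector fixing row order (stays absent from
#'   `diagnoses` get all-FALSE rows).
#' @return Logical matrix, one row per stay (rownames = stay ids), one
#'   column per category.
#' @export
flag_matrix <- function(diagnoses, version, index,
                        category_table = load_category_table(),
                        stay_ids = NULL) {
  check_version(version)
  cats <- table_categories(category_table, index)
  if (is.null(stay_ids)) stay_ids <- unique(diagnoses$stay_id)
  out <- matrix(FALSE, nrow = length(stay_ids), ncol = length(cats),
                dimnames = list(as.character(stay_ids), cats))
  if (nrow(diagnoses) == 0L || length(stay_ids) == 0L) return(out)
  dt <- data.table(stay_id = as.character(diagnoses$stay_id),
                   code = normalize_code(expression_stem(diagnoses$code),
                                         version))
  hits <- match_categories(dt$code, version, index, category_table)
  if (nrow(hits) == 0L) return(out)
  m <- merge(dt, hits, by = "code", allow.cartesian = TRUE)
  m <- unique(m[, .(stay_id, category)])
  m <- m[stay_id %in% rownames(out)]
  out[cbind(m$stay_id, m$category)] <- TRUE
  out
}

#' Apply the severity hierarchy to category flags
#'
#' Each comorbidity family is counted once, keeping the most severe member:
#' for every (mild, severe) pair of the index, the mild flag is cleared
#' whenever the severe flag is set (the `assign0` convention).
#'
#' @param flags named logical vector (one stay) or logical matrix
#'   (stays x categories) as returned by [assign_flags()]/[flag_matrix()].
#' @param index index name used to select the hierarchy.
#' @param pairs list of `c(mild, severe)` pairs; defaults to the packaged
#'   hierarchy for CCI/ECI and to no pairs for other index names. Pairs
#'   whose members are absent from `flags` are ignored.
#' @return `flags` with the hierarchy applied.
#' @export
apply_severity_hierarchy <- function(flags, index,
                                     pairs = SEVERITY_PAIRS[[index]]) {
  if (is.null(pairs)) pairs <- list()
  nm <- if (is.matrix(flags)) colnames(flags) else names(flags)
  for (p in pairs) {
    if (!all(p %in% nm)) next
    if (is.matrix(flags)) {
      flags[, p[1L]] <- flags[, p[1L]] & !flags[, p[2L]]
    } else {
      flags[p[1L]] <- flags[p[1L]] && !flags[p[2L]]
    }
  }
  flags
}

#' Score category flags under a weight scheme
#'
#' Computes the weighted sum of category indicators. The severity
#' hierarchy is assumed already applied. Scores may be negative under the
#' van Walraven ECI weights.
#'
#' @param flags named logical vector or logical matrix of category flags.
#' @param scheme a [weight_scheme()] (or named numeric vector) covering
#'   every category of `flags`.
#' @return Integer score (vector of scores for a matrix input).
#' @export
score_flags <- function(flags, scheme) {
  nm <- if (is.matrix(flags)) colnames(flags) else names(flags)
  missing_w <- setdiff(nm, names(scheme))
  if (length(missing_w)) {
    stop("weight scheme is missing categories: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  w <- as.numeric(scheme[nm])
  if (is.matrix(flags)) {
    as.vector(flags %*% w)
  } else {
    sum(as.numeric(flags) * w)
  }
}

#' Derive an ICD-11-MMS category table by mapping inheritance
#'
#' Every ICD-11 target of the crosswalk (the stem, for postcoordinated
#' expressions) inherits the union of the comorbidity categories of all
#' ICD-10-CM source codes that map to it. The resulting entries are
#' exact-match codes, not prefixes, because inheritance is defined per
#' mapped code. ICD-11 codes whose sources carry no category are simply
#' absent from the table.
#'
#' @param icd10_table a `category_table` covering `ICD10CM`.
#' @param xw an `icd_crosswalk` `ICD10CM -> ICD11MMS`.
#' @param index index (or indices) to derive; defaults to all indices
#'   present in `icd10_table`.
#' @return A `category_table` with `version = "ICD11MMS"`.
#' @export
infer_icd11_category_table <- function(icd10_table, xw,
                                       index = unique(icd10_table$index)) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  if (xw$source_version != "ICD10CM" || xw$target_version != "ICD11MMS") {
    stop("category inheritance requires an ICD10CM -> ICD11MMS crosswalk",
         call. = FALSE)
  }
  pairs <- unique(data.table(source = xw$entries$source,
                             stem = expression_stem(xw$entries$target)))
  rows <- lapply(index, function(ix) {
    hits <- match_categories(pairs$source, "ICD10CM", ix, icd10_table)
    if (nrow(hits) == 0L) return(NULL)
    m <- merge(pairs, hits, by.x = "source", by.y = "code",
               allow.cartesian = TRUE)
    if (nrow(m) == 0L) return(NULL)
    u <- unique(m[, .(category, stem)])
    data.frame(index = ix, version = "ICD11MMS", category = u$category,
               code = u$stem, match = "exact", stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- data.frame(index = character(), version = character(),
                      category = character(), code = character(),
                      match = character(), stringsAsFactors = FALSE)
    class(out) <- c("category_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$index, out$category, out$code), , drop = FALSE]
  rownames(out) <- NULL
  as_category_table(out)
}

#' Export a category code list with weights
#'
#' Writes the per-category code list of one index/version as a sorted TSV
#' with columns `index`, `category`, `code`, `match`, `weight` (the weight
#' of the category under the active scheme). The file round-trips through
#' [read_codelist()].
#'
#' @param category_table a `category_table`.
#' @param index,version slice to export.
#' @param scheme a [weight_scheme()] covering the index's categories.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_codelists <- function(category_table, index, version, scheme, path) {
  tab <- category_table[category_table$index == index &
                          category_table$version == version, , drop = FALSE]
  tab <- tab[order(tab$category, tab$code), , drop = FALSE]
  out <- data.frame(index = tab$index, category = tab$category,
                    code = tab$code, match = tab$match,
                    weight = as.numeric(scheme[tab$category]),
                    stringsAsFactors = FALSE)
  if (nrow(out) && anyNA(out$weight)) {
    stop("weight scheme is missing categories: ",
         paste(unique(out$category[is.na(out$weight)]), collapse = ", "),
         call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write code list to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a code list written by [export_codelists()]
#'
#' @param path TSV path.
#' @param version ICD version tag of the listed codes.
#' @return A `category_table`; the per-category weights are attached as the
#'   `"weights"` attribute.
#' @export
read_codelist <- function(path, version) {
  check_version(version)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = 1:4)))
  need <- c("index", "category", "code", "match", "weight")
  if (!all(need %in% names(dt))) {
    stop("code list needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- as_category_table(data.frame(index = dt$index, version = version,
                                      category = dt$category, code = dt$code,
                                      match = dt$match,
                                      stringsAsFactors = FALSE))
  w <- dt[!duplicated(dt$category), c("category", "weight")]
  attr(tab, "weights") <- stats::setNames(as.numeric(w$weight), w$category)
  tab
}
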