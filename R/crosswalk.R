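#' @importFrom data.table data.table as.data.table := .N .SD setorder rbindlist
NULL

PROVENANCE_LEVELS <- c("GEM", "FUNG_MAP", "WHO_MAP", "CONCEPT_EQUIV",
                       "MANUAL", "REVERSE_ENGINEERED")
MAP_FLAVORS <- c("PRECOORDINATED", "POSTCOORDINATED")

#' Construct a crosswalk
#'
#' A crosswalk is a directed multimap from codes of one ICD version to codes
#' or postcoordinated expressions of another, with per-entry provenance and
#' map flavor. Duplicate (source, target) pairs are collapsed keeping the
#' highest-precedence provenance (GEM > FUNG_MAP > WHO_MAP > CONCEPT_EQUIV >
#' MANUAL > REVERSE_ENGINEERED).
#'
#' @param source_version,target_version version tags (must differ).
#' @param entries data.frame with columns `source`, `target`, `provenance`,
#'   `flavor`. Codes are assumed already normalized. `flavor` may be omitted
#'   and is then derived from the presence of `&` in the target.
#' @return An object of class `icd_crosswalk`.
#' @export
crosswalk <- function(source_version, target_version,
                      entries = data.frame(source = character(),
                                           target = character(),
                                           provenance = character(),
                                           flavor = character())) {
  check_version(source_version)
  check_version(target_version)
  if (source_version == target_version) {
    stop("source and target versions of a crosswalk must differ", call. = FALSE)
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "provenance") %in% names(entries))) {
    stop("crosswalk entries need columns source, target, provenance",
         call. = FALSE)
  }
  if (is.null(entries$flavor)) {
    entries$flavor <- ifelse(grepl("&", entries$target, fixed = TRUE),
                             "POSTCOORDINATED", "PRECOORDINATED")
  }
  bad_prov <- setdiff(unique(entries$provenance), PROVENANCE_LEVELS)
  if (length(bad_prov)) {
    stop("unknown provenance value(s): ", paste(bad_prov, collapse = ", "),
         call. = FALSE)
  }
  bad_flav <- setdiff(unique(entries$flavor), MAP_FLAVORS)
  if (length(bad_flav)) {
    stop("unknown map flavor value(s): ", paste(bad_flav, collapse = ", "),
         call. = FALSE)
  }
  entries <- entries[, c("source", "target", "provenance", "flavor")]
  # collapse duplicate pairs, keeping the highest-precedence provenance
  if (nrow(entries)) {
    prec <- match(entries$provenance, PROVENANCE_LEVELS)
    ord <- order(entries$source, entries$target, prec)
    entries <- entries[ord, , drop = FALSE]
    dup <- duplicated(entries[, c("source", "target")])
    entries <- entries[!dup, , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(source_version = source_version,
                 target_version = target_version,
                 entries = entries),
            class = "icd_crosswalk")
}

#' @export
print.icd_crosswalk <- function(x, ...) {
  cat("<icd_crosswalk> ", x$source_version, " -> ", x$target_version, "\n",
      sep = "")
  cat("  ", nrow(x$entries), " pairs over ",
      length(unique(x$entries$source)), " source codes\n", sep = "")
  if (nrow(x$entries)) {
    tab <- table(x$entries$provenance)
    cat("  provenance: ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of distinct source-target pairs in a crosswalk
#'
#' @param xw an `icd_crosswalk`.
#' @return Integer count of distinct (source, target) pairs.
#' @export
n_pairs <- function(xw) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  nrow(unique(xw$entries[, c("source", "target")]))
}

#' Merge crosswalks sharing the same orientation
#'
#' Set-union of the (source, target) pairs of several crosswalks. When the
#' same pair arises from multiple sources the provenance of the
#' highest-precedence source is kept.
#'
#' @param crosswalks a list of `icd_crosswalk` objects with identical source
#'   and target versions.
#' @return A merged `icd_crosswalk`.
#' @export
merge_crosswalks <- function(crosswalks) {
  stopifnot(length(crosswalks) >= 1L,
            all(vapply(crosswalks, inherits, TRUE, "icd_crosswalk")))
  sv <- unique(vapply(crosswalks, `[[`, "", "source_version"))
  tv <- unique(vapply(crosswalks, `[[`, "", "target_version"))
  if (length(sv) != 1L || length(tv) != 1L) {
    stop("cannot merge crosswalks with mismatched versions (",
         paste(sv, collapse = "/"), " -> ", paste(tv, collapse = "/"), ")",
         call. = FALSE)
  }
  entries <- do.call(rbind, lapply(crosswalks, `[[`, "entries"))
  crosswalk(sv, tv, entries)
}

#' Add manually validated mappings for unmapped codes
#'
#' Override pairs stand in for the human consensus mapping step: they may
#' only fill gaps (sources with no existing mapping). An override whose
#' source is already mapped is a conflict and raises an error naming the
#' offending source codes.
#'
#' @param xw an `icd_crosswalk`.
#' @param overrides data.frame with columns `source`, `target` (raw text;
#'   normalized on entry).
#' @return The crosswalk with the override pairs added, provenance `MANUAL`.
#' @export
apply_manual_overrides <- function(xw, overrides) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  overrides <- as.data.frame(overrides, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(overrides))) {
    stop("override table needs columns source, target", call. = FALSE)
  }
  if (nrow(overrides) == 0L) return(xw)
  src <- normalize_code(overrides$source, xw$source_version)
  tgt <- normalize_code(overrides$target, xw$target_version)
  mapped <- unique(xw$entries$source)
  conflict <- unique(src[src %in% mapped])
  if (length(conflict)) {
    stop("manual override(s) for already-mapped source code(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  add <- data.frame(source = src, target = tgt,
                    provenance = "MANUAL", stringsAsFactors = FALSE)
  crosswalk(xw$source_version, xw$target_version, rbind(xw$entries[, 1:3], add))
}

#' Complete a crosswalk by hierarchy-based reverse engineering
#'
#' For every code of the universe without a mapping, the mappings of its
#' nearest mapped lexical ancestor (one-character truncations of the
#' normalized ICD-10-CM code, down to the 3-character root) are copied with
#' provenance `REVERSE_ENGINEERED`. The process iterates until no new
#' mappings can be retrieved (fixpoint); previously mapped codes are never
#' modified. Codes with no mapped ancestor remain unmapped.
#'
#' @param xw an `icd_crosswalk` with ICD-10-CM sources.
#' @param universe character vector of codes (raw or normalized) that
#'   require mappings.
#' @return The completed crosswalk.
#' @export
reverse_engineer_from_hierarchy <- function(xw, universe) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  if (xw$source_version != "ICD10CM") {
    stop("reverse engineering uses the ICD-10-CM hierarchy; crosswalk source is ",
         xw$source_version, call. = FALSE)
  }
  if (length(universe) == 0L) return(xw)
  universe <- unique(normalize_code(universe, "ICD10CM"))
  entries <- xw$entries
  repeat {
    mapped <- unique(entries$source)
    todo <- setdiff(universe, mapped)
    if (length(todo) == 0L) break
    new_rows <- vector("list", length(todo))
    k <- 0L
    for (code in todo) {
      anc <- code
      hit <- NA_character_
      while (nchar(anc) > 3L) {
        anc <- substr(anc, 1L, nchar(anc) - 1L)
        if (anc %in% mapped) { hit <- anc; break }
      }
      if (!is.na(hit)) {
        tgt <- entries[entries$source == hit, , drop = FALSE]
        k <- k + 1L
        new_rows[[k]] <- data.frame(source = code, target = tgt$target,
                                    provenance = "REVERSE_ENGINEERED",
                                    flavor = tgt$flavor,
                                    stringsAsFactors = FALSE)
      }
    }
    if (k == 0L) break
    entries <- rbind(entries, do.call(rbind, new_rows[seq_len(k)]))
  }
  crosswalk(xw$source_version, xw$target_version, entries)
}

#' Compose two crosswalks
#'
#' Chains A->B and B->C mappings: a source code maps to the union, over all
#' of its intermediate targets, of the intermediates' targets. A source is
#' unmapped in the composition iff it had no intermediate or all its
#' intermediates are unmapped. Provenance and flavor of the second leg are
#' kept (they determined the final target).
#'
#' @param xw_a_b,xw_b_c crosswalks with `xw_a_b$target_version ==
#'   xw_b_c$source_version`.
#' @return The composed `icd_crosswalk` from `xw_a_b$source_version` to
#'   `xw_b_c$target_version`.
#' @export
compose_crosswalks <- function(xw_a_b, xw_b_c) {
  stopifnot(inherits(xw_a_b, "icd_crosswalk"), inherits(xw_b_c, "icd_crosswalk"))
  if (xw_a_b$target_version != xw_b_c$source_version) {
    stop("cannot compose: intermediate versions differ (",
         xw_a_b$target_version, " vs ", xw_b_c$source_version, ")",
         call. = FALSE)
  }
  a <- as.data.table(xw_a_b$entries)[, .(source, mid = target)]
  b <- as.data.table(xw_b_c$entries)[, .(mid = source, target, provenance, flavor)]
  joined <- merge(a, b, by = "mid", allow.cartesian = TRUE)
  crosswalk(xw_a_b$source_version, xw_b_c$target_version,
            as.data.frame(joined[, .(source, target, provenance, flavor)]))
}

#' Map a code through a crosswalk
#'
#' @param xw an `icd_crosswalk`.
#' @param code a single code (raw or normalized) in the crosswalk's source
#'   version.
#' @return Character vector of targets; empty for unmapped codes (never an
#'   error).
#' @export
map_code <- function(xw, code) {
  stopifnot(inherits(xw, "icd_crosswalk"), length(code) == 1L)
  code <- normalize_code(code, xw$source_version)
  sort(unique(xw$entries$target[xw$entries$source == code]))
}

#' Cardinality summary of a crosswalk over a code universe
#'
#' Classifies every universe code as 1-0 (no mapping), 1-1 (exactly one
#' target) or 1-N (two or more targets). The three counts always partition
#' the universe.
#'
#' @param xw an `icd_crosswalk`.
#' @param universe character vector of source-version codes.
#' @return A list of class `cardinality_summary` with counts `n_unmapped`,
#'   `n_one`, `n_multi`, `universe_size`.
#' @export
cardinality_summary <- function(xw, universe) {
  stopifnot(inherits(xw, "icd_crosswalk"))
  if (length(universe) == 0L) stop("empty code universe", call. = FALSE)
  universe <- unique(normalize_code(universe, xw$source_version))
  pairs <- unique(xw$entries[, c("source", "target")])
  counts <- table(factor(pairs$source, levels = universe))
  structure(list(n_unmapped = sum(counts == 0L),
                 n_one = sum(counts == 1L),
                 n_multi = sum(counts >= 2L),
                 universe_size = length(universe)),
            class = "cardinality_summary")
}

#' @export
print.cardinality_summary <- function(x, ...) {
  cat("Mapping cardinality over", x$universe_size, "source codes\n")
  cat(sprintf("  1-0 (unmapped): %d\n  1-1: %d\n  1-N: %d\n",
              x$n_unmapped, x$n_one, x$n_multi))
  invisible(x)
}
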