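#' @title ICD code versions
#' @description Version tags recognized throughout the package.
#' @format Character vector of the three supported ICD version tags.
#' @export
ICD_VERSIONS <- c("ICD9CM", "ICD10CM", "ICD11MMS")

#' Validate an ICD version tag
#'
#' @param version a single character scalar, one of [ICD_VERSIONS].
#' @return The tag, invisibly usable; errors on unknown tags.
#' @keywords internal
check_version <- function(version) {
  if (!is.character(version) || length(version) != 1L || is.na(version) ||
      !(version %in% ICD_VERSIONS)) {
    stop("unknown ICD version tag: ", paste(format(version), collapse = ", "),
         " (expected one of ", paste(ICD_VERSIONS, collapse = ", "), ")",
         call. = FALSE)
  }
  version
}

#' Normalize an ICD code
#'
#' Canonicalizes raw code text: uppercase, whitespace stripped. For ICD-9-CM
#' and ICD-10-CM the dot separator is also removed (these codes are stored
#' undotted in GEM files and MIMIC); ICD-11-MMS codes retain their internal
#' dot because it is part of the code structure (e.g. `FB83.1Y`).
#' Postcoordinated ICD-11 expressions (tokens joined by `&`) are normalized
#' token-wise; the `&` separators are preserved.
#'
#' Normalization is idempotent and deterministic.
#'
#' @param raw character vector of code text as found in a source file.
#' @param version one of [ICD_VERSIONS].
#' @return Character vector of normalized codes, same length as `raw`.
#' @examples
#' normalize_code("A37.91", "ICD10CM")   # "A3791"
#' normalize_code("fb83.1y", "ICD11MMS") # "FB83.1Y" (dot retained)
#' @export
normalize_code <- function(raw, version) {
  check_version(version)
  out <- toupper(gsub("[[:space:]]+", "", as.character(raw)))
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    stop("empty ICD code at record(s) ", paste(which(bad), collapse = ", "),
         " (version ", version, ")", call. = FALSE)
  }
  if (version != "ICD11MMS") {
    out <- gsub(".", "", out, fixed = TRUE)
    if (any(!nzchar(out))) {
      stop("code reduced to empty string after normalization at record(s) ",
           paste(which(!nzchar(out)), collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Parse a postcoordinated ICD-11-MMS expression
#'
#' An ICD-11-MMS postcoordinated expression is a stem code optionally
#' refined by extension codes, joined with `&` (e.g. `"FB83.1Y&XT9T"`).
#' The first token is the stem; remaining tokens are extensions, in order.
#' A bare code parses to a stem with zero extensions.
#'
#' @param raw a single expression string.
#' @return An object of class `postcoord_expr`: a list with elements
#'   `stem`, `extensions` (character, possibly empty) and `raw`
#'   (the normalized serialized form).
#' @examples
#' parse_expression("FB83.1Y&XT9T")
#' parse_expression("1C12.Z")
#' @export
parse_expression <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) {
    stop("parse_expression() expects a single expression string", call. = FALSE)
  }
  norm <- normalize_code(raw, "ICD11MMS")
  tokens <- strsplit(norm, "&", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || any(!nzchar(tokens)) || grepl("&$", norm)) {
    stop("empty token in postcoordinated expression: '", raw, "'", call. = FALSE)
  }
  structure(
    list(stem = tokens[[1L]],
         extensions = tokens[-1L],
         raw = paste(tokens, collapse = "&")),
    class = "postcoord_expr")
}

#' @export
format.postcoord_expr <- function(x, ...) x$raw

#' @export
print.postcoord_expr <- function(x, ...) {
  cat("<ICD-11-MMS expression> ", x$raw, "\n", sep = "")
  if (length(x$extensions)) {
    cat("  stem: ", x$stem, "; extensions: ",
        paste(x$extensions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Stem of an ICD-11 expression
#'
#' Vectorized helper returning the stem (first `&`-token) of each
#' expression; bare codes are returned unchanged.
#'
#' @param x character vector of codes or postcoordinated expressions.
#' @return Character vector of stems.
#' @export
expression_stem <- function(x) {
  sub("&.*$", "", x)
}

#' Lexical parent of an ICD-10-CM code
#'
#' ICD-10-CM parenthood is lexical: the parent of a normalized code is
#' obtained by removing its last character, down to the three-character
#' category root, which has no parent (returned as `NA`).
#'
#' @param code character vector of normalized ICD-10-CM codes.
#' @param version version tag; only `"ICD10CM"` is supported.
#' @return Character vector of parent codes; `NA` for category roots.
#' @examples
#' parent_code("A3791") # "A379"
#' parent_code("A37")   # NA: category root
#' @export
parent_code <- function(code, version = "ICD10CM") {
  check_version(version)
  if (version != "ICD10CM") {
    stop("hierarchy navigation is only supported for ICD-10-CM codes, not ",
         version, call. = FALSE)
  }
  code <- normalize_code(code, version)
  n <- nchar(code)
  out <- ifelse(n > 3L, substr(code, 1L, n - 1L), NA_character_)
  out
}
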