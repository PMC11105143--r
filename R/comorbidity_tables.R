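# Shipped category metadata: abbreviations, display names, weight schemes
# and severity hierarchies for the Charlson (CCI) and Elixhauser (ECI)
# comorbidity indices, following the Quan coding algorithms.

CCI_CATEGORIES <- c(
  mi = "Myocardial infarction", chf = "Congestive heart failure",
  pvd = "Peripheral vascular disease", cevd = "Cerebrovascular disease",
  dementia = "Dementia", cpd = "Chronic pulmonary disease",
  rheumd = "Rheumatologic disease", pud = "Peptic ulcer disease",
  mld = "Mild liver disease", diab = "Diabetes without complications",
  diabwc = "Diabetes with complications", hp = "Hemiplegia or paraplegia",
  rend = "Renal disease", canc = "Cancer (any malignancy)",
  msld = "Moderate or severe liver disease", metacanc = "Metastatic cancer",
  aids = "AIDS/HIV")

ECI_CATEGORIES <- c(
  chf = "Congestive heart failure", carit = "Cardiac arrhythmias",
  valv = "Valvular disease", pcd = "Pulmonary circulation disorders",
  pvd = "Peripheral vascular disorders",
  hypunc = "Hypertension, uncomplicated", hypc = "Hypertension, complicated",
  para = "Paralysis", ond = "Other neurological disorders",
  cpd = "Chronic pulmonary disease", diabunc = "Diabetes, uncomplicated",
  diabc = "Diabetes, complicated", hypothy = "Hypothyroidism",
  rf = "Renal failure", ld = "Liver disease",
  pud = "Peptic ulcer disease excluding bleeding", aids = "AIDS/HIV",
  lymph = "Lymphoma", metacanc = "Metastatic cancer",
  solidtum = "Solid tumor without metastasis",
  rheumd = "Rheumatoid arthritis/collagen vascular diseases",
  coag = "Coagulopathy", obes = "Obesity", wloss = "Weight loss",
  fed = "Fluid and electrolyte disorders", blane = "Blood loss anemia",
  dane = "Deficiency anemia", alcohol = "Alcohol abuse",
  drug = "Drug abuse", psycho = "Psychoses", depre = "Depression")

WEIGHT_SCHEMES <- list(
  CHARLSON_ORIGINAL = c(
    mi = 1, chf = 1, pvd = 1, cevd = 1, dementia = 1, cpd = 1, rheumd = 1,
    pud = 1, mld = 1, diab = 1, diabwc = 2, hp = 2, rend = 2, canc = 2,
    msld = 3, metacanc = 6, aids = 6),
  QUAN_UPDATED = c(
    mi = 0, chf = 2, pvd = 0, cevd = 0, dementia = 2, cpd = 1, rheumd = 1,
    pud = 0, mld = 2, diab = 0, diabwc = 1, hp = 2, rend = 1, canc = 2,
    msld = 4, metacanc = 6, aids = 4),
  VAN_WALRAVEN = c(
    chf = 7, carit = 5, valv = -1, pcd = 4, pvd = 2, hypunc = 0, hypc = 0,
    para = 7, ond = 6, cpd = 3, diabunc = 0, diabc = 0, hypothy = 0, rf = 5,
    ld = 11, pud = 0, aids = 0, lymph = 9, metacanc = 12, solidtum = 4,
    rheumd = 0, coag = 3, obes = -4, wloss = 6, fed = 5, blane = -2,
    dane = -2, alcohol = 0, drug = -7, psycho = 0, depre = -3))

# Severity hierarchies: for each (mild, severe) pair, the mild flag is
# zeroed when the severe flag is set ("counted once, most severe disease").
SEVERITY_PAIRS <- list(
  CCI = list(c("diab", "diabwc"), c("mld", "msld"), c("canc", "metacanc")),
  ECI = list(c("diabunc", "diabc"), c("solidtum", "metacanc"),
             c("hypunc", "hypc")))

#' Category metadata for an index
#'
#' @param index `"CCI"` or `"ECI"`.
#' @return Named character vector: abbreviation -> display name.
#' @export
index_categories <- function(index = c("CCI", "ECI")) {
  index <- match.arg(index)
  if (index == "CCI") CCI_CATEGORIES else ECI_CATEGORIES
}

#' Severity hierarchy pairs for an index
#'
#' @inheritParams index_categories
#' @return List of `c(mild, severe)` abbreviation pairs.
#' @export
severity_pairs <- function(index = c("CCI", "ECI")) {
  index <- match.arg(index)
  SEVERITY_PAIRS[[index]]
}

#' Weight scheme for index scoring
#'
#' Returns the integer weight attached to each comorbidity category.
#' `CHARLSON_ORIGINAL` and `QUAN_UPDATED` apply to the CCI;
#' `VAN_WALRAVEN` to the ECI (with negative weights for protective
#' categories). `CUSTOM` requires an explicit full map covering every
#' category of the table it is used with.
#'
#' @param name scheme name.
#' @param weights named numeric vector, required when `name = "CUSTOM"`.
#' @return Named numeric vector of weights, classed `weight_scheme`.
#' @export
weight_scheme <- function(name = c("CHARLSON_ORIGINAL", "QUAN_UPDATED",
                                   "VAN_WALRAVEN", "CUSTOM"),
                          weights = NULL) {
  name <- match.arg(name)
  if (name == "CUSTOM") {
    if (is.null(weights) || is.null(names(weights)) || anyNA(weights)) {
      stop("CUSTOM weight scheme requires a complete named weight vector",
           call. = FALSE)
    }
    w <- weights
  } else {
    w <- WEIGHT_SCHEMES[[name]]
  }
  structure(w, scheme = name, class = c("weight_scheme", "numeric"))
}

#' Load a category code table
#'
#' Category tables are TSV files with columns `index`, `version`,
#' `category`, `code`, `match` (`prefix` or `exact`). Codes with
#' `match = "prefix"` flag any diagnosis whose normalized code starts with
#' them; `exact` codes match by full-string equality (used for derived
#' ICD-11-MMS tables, where inheritance is defined per mapped code).
#'
#' @param path path to a TSV; defaults to the packaged Quan coding
#'   algorithms for CCI/ECI in ICD-9-CM and ICD-10-CM.
#' @return data.frame of class `category_table`.
#' @export
load_category_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "category_codes_quan.tsv",
                        package = "icd11impact", mustWork = TRUE)
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  as_category_table(as.data.frame(dt))
}

#' Construct a category table from a data.frame
#'
#' @param df data.frame with columns `index`, `version`, `category`, `code`
#'   and optionally `match` (defaults to `"prefix"`).
#' @return The validated table with class `category_table`.
#' @export
as_category_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("index", "version", "category", "code")
  if (!all(need %in% names(df))) {
    stop("category table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$match)) df$match <- "prefix"
  bad <- setdiff(unique(df$match), c("prefix", "exact"))
  if (length(bad)) {
    stop("unknown match mode(s) in category table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_v <- setdiff(unique(df$version), ICD_VERSIONS)
  if (length(bad_v)) {
    stop("unknown version(s) in category table: ",
         paste(bad_v, collapse = ", "), call. = FALSE)
  }
  df <- unique(df[, c("index", "version", "category", "code", "match")])
  rownames(df) <- NULL
  class(df) <- c("category_table", "data.frame")
  df
}
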