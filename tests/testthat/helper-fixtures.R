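# In-code fixtures and independent oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal crosswalk from a named list (code -> character vector of targets)
toy_crosswalk <- function(map, source_version = "ICD10CM",
                          target_version = "ICD11MMS",
                          provenance = "WHO_MAP") {
  entries <- do.call(rbind, lapply(names(map), function(s) {
    if (length(map[[s]]) == 0L) return(NULL)
    data.frame(source = s, target = map[[s]], provenance = provenance,
               stringsAsFactors = FALSE)
  }))
  if (is.null(entries)) {
    entries <- data.frame(source = character(), target = character(),
                          provenance = character())
  }
  crosswalk(source_version, target_version, entries)
}

# Independent fixpoint oracle for hierarchy reverse engineering: naive
# repeated sweeps assigning the nearest mapped ancestor's target set.
oracle_reverse_engineer <- function(map, universe) {
  repeat {
    changed <- FALSE
    for (code in universe) {
      if (!is.null(map[[code]])) next
      anc <- code
      while (nchar(anc) > 3L) {
        anc <- substr(anc, 1L, nchar(anc) - 1L)
        if (!is.null(map[[anc]])) {
          map[[code]] <- map[[anc]]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(map)
  }
}

# Exhaustive two-hop path enumeration oracle for crosswalk composition.
oracle_compose <- function(map_ab, map_bc, sources) {
  out <- list()
  for (s in sources) {
    hits <- character()
    for (mid in map_ab[[s]]) hits <- c(hits, map_bc[[mid]])
    if (length(hits)) out[[s]] <- sort(unique(hits))
  }
  out
}

# Crosswalk entries as a canonical sorted pair data.frame
pair_set <- function(xw) {
  p <- unique(xw$entries[, c("source", "target")])
  p <- p[order(p$source, p$target), ]
  rownames(p) <- NULL
  p
}

# Random hierarchical toy code set over a reserved root
random_toy_universe <- function(n, root = "QQQ") {
  codes <- character(n)
  codes[1L] <- root
  for (i in seq_len(n)[-1L]) {
    parent <- codes[sample.int(i - 1L, 1L)]
    codes[i] <- paste0(parent, sample(c(LETTERS, 0:9), 1L))
  }
  unique(codes)
}

# Small synthetic config for fast tests
quick_config <- function(seed = 7L, n_stays = 500L, ...) {
  synthetic_config(seed = seed, n_stays = n_stays, ...)
}
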