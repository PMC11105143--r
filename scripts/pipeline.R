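#!/usr/bin/env Rscript
# Thin command-line wrapper over the icd11impact pipeline functions.
#
#   Rscript scripts/pipeline.R simulate        --dir DIR [--seed N] [--n-stays N]
#   Rscript scripts/pipeline.R build-crosswalk --dir DIR
#   Rscript scripts/pipeline.R run-study       --dir DIR [--index CCI|ECI]
#   Rscript scripts/pipeline.R export-codelists --dir DIR --index CCI --version ICD11MMS --out PATH

suppressPackageStartupMessages(library(icd11impact))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: pipeline.R <subcommand> [options]")
cmd <- args[[1L]]
opts <- args[-1L]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1L && i < length(opts)) opts[[i + 1L]] else default
}
dir <- get_opt("--dir")
if (is.null(dir)) stop("--dir is required")

log_msg <- function(...) message("[pipeline] ", ...)

if (cmd == "simulate") {
  cfg <- synthetic_config(seed = as.integer(get_opt("--seed", "1")),
                          n_stays = as.integer(get_opt("--n-stays", "10000")))
  pipeline_simulate(cfg, dir)
  log_msg("synthetic bundle written to ", dir)
} else if (cmd == "build-crosswalk") {
  bx <- pipeline_build_crosswalk(dir)
  log_msg("crosswalks written to ", file.path(dir, "crosswalk"))
  print(bx$cardinality)
} else if (cmd == "run-study") {
  st <- pipeline_run_study(dir, index = get_opt("--index", "CCI"))
  log_msg("study report written to ", file.path(dir, "study"))
  print(st$summary)
} else if (cmd == "export-codelists") {
  index <- get_opt("--index", "CCI")
  version <- get_opt("--version", "ICD11MMS")
  out <- get_opt("--out", file.path(dir, paste0("codelist_", index, "_",
                                                version, ".tsv")))
  xw <- read_crosswalk(file.path(dir, "crosswalk", "xw_icd10_icd11.tsv"))
  tab <- infer_icd11_category_table(load_category_table(), xw, index)
  scheme <- weight_scheme(if (index == "ECI") "VAN_WALRAVEN"
                          else "CHARLSON_ORIGINAL")
  export_codelists(tab, index, version, scheme, out)
  log_msg("code list written to ", out)
} else {
  stop("unknown subcommand: ", cmd)
}
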