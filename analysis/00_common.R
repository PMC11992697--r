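# Shared plumbing for the numbered analysis drivers: argument parsing and
# the on-disk layout. Every driver reads/writes under results/analysis/.
suppressPackageStartupMessages(library(idrbench))

argv <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default) {
  i <- match(flag, argv)
  if (is.na(i) || i == length(argv)) return(default)
  argv[i + 1L]
}
run_seed <- as.integer(arg_value("--seed", "20260101"))
root <- arg_value("--root", "results/analysis")
cohort_dir <- file.path(root, "cohort")
dir.create(root, showWarnings = FALSE, recursive = TRUE)

tool_panel <- default_tool_configs()
vep_panel <- default_vep_panel()

need_file <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path, "; run ", producer, " first",
         call. = FALSE)
  }
  path
}

read_masks <- function() {
  lapply(stats::setNames(nm = names(tool_panel)), function(t) {
    f <- need_file(file.path(root, paste0("mask_", t, ".tsv")),
                   "analysis/02_segment.R")
    m <- read_score_track(f, t)
    data.frame(protein_id = m$protein_id, tool_id = t,
               position = m$position, disordered = m$score > 0.5,
               stringsAsFactors = FALSE)
  })
}

read_segments <- function() {
  f <- need_file(file.path(root, "segments.tsv"), "analysis/02_segment.R")
  seg <- read_table_back(f)
  split(seg, seg$tool_id)
}
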