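#!/usr/bin/env Rscript
# Stage 2: per-residue disorder calls and classified IDR segments for every
# tool, plus the multi-tool agreement table. Reads the stage-1 cohort.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

proteins <- read_fasta(need_file(file.path(cohort_dir, "proteins.fasta"),
                                 "analysis/01_simulate.R"))
tracks <- lapply(stats::setNames(nm = names(tool_panel)), function(t) {
  read_score_track(need_file(file.path(cohort_dir,
                                       paste0("track_", t, ".tsv")),
                             "analysis/01_simulate.R"), t)
})

masks <- list(); all_segments <- list()
for (t in names(tool_panel)) {
  cfg <- tool_panel[[t]]
  masks[[t]] <- call_disorder(tracks[[t]], cfg)
  seg <- classify_segments(segment_idrs(masks[[t]], cfg$min_idr_length),
                           proteins)
  all_segments[[t]] <- seg
  out <- masks[[t]]
  out$score <- as.integer(out$disordered)
  write_table(out[, c("protein_id", "position", "score")],
              file.path(root, paste0("mask_", t, ".tsv")))
  frac_out <- idr_containment_fraction(masks[[t]], seg)
  cat(sprintf("%-12s disordered %5.1f%% of residues; %4.1f%% of those outside retained IDRs; %d segments\n",
              t, 100 * mean(masks[[t]]$disordered), 100 * frac_out,
              nrow(seg)))
}
segments <- do.call(rbind, all_segments)
write_table(segments, file.path(root, "segments.tsv"))
write_table(segments_to_bed(segments), file.path(root, "segments_bed.tsv"))

combos <- combination_frequencies(masks, min_frequency = 0.01)
write_table(combos, file.path(root, "tool_combination_frequencies.tsv"))
all_dis <- combos[rowSums(combos[, names(tool_panel)]) == length(tool_panel), ]
cat("Residues called disordered by every tool:",
    sprintf("%.1f%%", 100 * sum(all_dis$frequency)), "\n")

write_manifest(file.path(root, "manifest_segment.json"), "segment",
               seed = NA_integer_,
               config = lapply(tool_panel, unclass),
               inputs = file.path(cohort_dir,
                                  c("proteins.fasta",
                                    paste0("track_", names(tool_panel), ".tsv"))),
               counts = list(residues = nrow(masks[[1]]),
                             segments = nrow(segments)))
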