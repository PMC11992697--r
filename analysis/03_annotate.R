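#!/usr/bin/env Rscript
# Stage 3: join variants to their per-tool disorder context, start-Met
# attributes and second-Met distances; report the cohort composition.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

proteins <- read_fasta(need_file(file.path(cohort_dir, "proteins.fasta"),
                                 "analysis/01_simulate.R"))
score_veps <- names(Filter(function(v) v$mode == "threshold", vep_panel))
cat_veps <- names(Filter(function(v) v$mode == "categorical", vep_panel))
variants <- read_variants(need_file(file.path(cohort_dir, "variants.tsv"),
                                    "analysis/01_simulate.R"),
                          vep_cols = score_veps, category_cols = cat_veps)
masks <- read_masks()
segments <- read_segments()

annotated <- annotate_variants(variants, masks, segments, proteins)
write_table(annotated, file.path(root, "annotated_variants.tsv"))

for (t in names(tool_panel)) {
  dis <- annotated[[paste0(t, "_disordered")]]
  benign <- annotated$label == "BENIGN"
  cat(sprintf("%-12s %4.1f%% of variants disordered; %4.1f%% of those benign; %4.1f%% of pathogenic in IDRs\n",
              t, 100 * mean(dis), 100 * mean(benign[dis]),
              100 * mean(dis[!benign])))
}
nmet <- annotated$is_nmet
cat(sprintf("Start-Met variants: %d (%.2f%% of cohort; uniform baseline %.2f%% per site), %.0f%% pathogenic\n",
            sum(nmet), 100 * mean(nmet), nmet_uniform_baseline(572),
            100 * mean(annotated$label[nmet] == "PATHOGENIC")))

write_manifest(file.path(root, "manifest_annotate.json"), "annotate",
               seed = NA_integer_,
               inputs = c(file.path(cohort_dir, c("proteins.fasta",
                                                  "variants.tsv")),
                          file.path(root, "segments.tsv")),
               counts = list(variants_in = nrow(variants),
                             variants_out = nrow(annotated),
                             nmet = sum(nmet)))
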