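#!/usr/bin/env Rscript
# Stage 5: the start-methionine subset, benchmarked separately: per-VEP
# plug-in metrics and the one-sided second-Met distance comparison.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

annotated <- read_table_back(need_file(file.path(root,
                                                 "annotated_variants.tsv"),
                                       "analysis/03_annotate.R"))
nmet <- split_nmet(annotated)$nmet
if (nrow(nmet) == 0L) stop("no start-Met variants in the cohort")
nmet_cc <- complete_case_filter(nmet, vep_panel)
cat("Start-Met variants:", nrow(nmet), "(", nrow(nmet_cc),
    "with predictions from every VEP );",
    sum(nmet$label == "PATHOGENIC"), "pathogenic,",
    sum(nmet$label == "BENIGN"), "benign.\n")

cm <- call_matrix(nmet_cc, vep_panel)
met <- do.call(rbind, lapply(names(vep_panel), function(v) {
  m <- metric_set(confusion(cm[, v], nmet_cc$label))
  data.frame(vep = v, sensitivity = m[["sensitivity"]],
             specificity = m[["specificity"]], stringsAsFactors = FALSE)
}))
write_table(met, file.path(root, "nmet_metrics.tsv"))
print(met, row.names = FALSE)

smt <- second_met_test(nmet)
cat(sprintf("Second-Met distance, pathogenic (n=%d) vs benign (n=%d) hosts: one-sided p = %.3g\n",
            smt$n_pathogenic, smt$n_benign, smt$p_value))
jsonlite::write_json(smt, file.path(root, "second_met_test.json"),
                     auto_unbox = TRUE, digits = NA)

write_manifest(file.path(root, "manifest_nmet.json"), "nmet",
               inputs = file.path(root, "annotated_variants.tsv"),
               counts = list(nmet = nrow(nmet),
                             complete_case = nrow(nmet_cc)))
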