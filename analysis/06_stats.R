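#!/usr/bin/env Rscript
# Stage 6: association between IDR positional group (N-terminal, between
# domains, C-terminal, IDP) and phenotypic effect, per disorder tool:
# chi-square independence tests with adjusted standardized residuals.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

annotated <- read_table_back(need_file(file.path(root,
                                                 "annotated_variants.tsv"),
                                       "analysis/03_annotate.R"))
annotated <- split_nmet(annotated)$main  # start-Met variants excluded

reports <- list()
for (t in names(tool_panel)) {
  tab <- idr_group_table(annotated, t)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) {
    cat(t, ": fewer than two IDR groups populated; test skipped\n")
    next
  }
  res <- chisq_independence(tab)
  cat(sprintf("%-12s X2 = %7.2f (dof %d), p = %.3g\n",
              t, res$statistic, res$dof, res$p_value))
  reports[[t]] <- list(observed = res$observed,
                       statistic = res$statistic, dof = res$dof,
                       p_value = res$p_value,
                       std_residuals = res$std_residuals)
}
jsonlite::write_json(reports, file.path(root, "idr_group_chisq.json"),
                     auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

write_manifest(file.path(root, "manifest_stats.json"), "stats",
               inputs = file.path(root, "annotated_variants.tsv"),
               counts = list(variants = nrow(annotated)))
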