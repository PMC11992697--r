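#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort (proteins, five disorder
# score tracks, labelled variants with VEP scores) and write it in the
# pipeline's input dialects.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

cfg <- synthetic_config(n_proteins = 1000L, seed = run_seed)
cohort <- generate_cohort(cfg, tool_panel)
write_cohort(cohort, cohort_dir)

v <- cohort$variants
cat("Simulated cohort:", nrow(cohort$proteins), "proteins,",
    nrow(v), "variants (", sum(v$position == 1L), "at the start Met ).\n")
cat("Median protein length:", stats::median(cohort$proteins$length),
    "| latent disordered residue fraction:",
    round(mean(cohort$latent$disordered), 3), "\n")

write_manifest(file.path(cohort_dir, "manifest.json"), "simulate",
               seed = run_seed,
               config = cfg[setdiff(names(cfg), "vep_models")],
               inputs = character(0),
               counts = list(proteins = nrow(cohort$proteins),
                             variants = nrow(v)))
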