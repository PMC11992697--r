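# Shared synthetic cohorts for the end-to-end tests, generated once per
# test run. `shrunk` uses the default disorder separation shrinkage;
# `null` sets shrinkage to 0 (scores independent of disorder).
.cohort_cache <- new.env(parent = emptyenv())

get_cohort <- function(which = c("shrunk", "null")) {
  which <- match.arg(which)
  if (!is.null(.cohort_cache[[which]])) return(.cohort_cache[[which]])
  models <- if (which == "null") default_vep_models(shrinkage = 0) else
    default_vep_models()
  cfg <- synthetic_config(n_proteins = 1000L, vep_models = models,
                          seed = 20260101L)
  co <- generate_cohort(cfg)
  # run the full pipeline: masks, segments, annotation, complete cases
  tool_cfgs <- default_tool_configs()
  masks <- lapply(names(tool_cfgs), function(t) {
    call_disorder(co$tracks[[t]], tool_cfgs[[t]])
  })
  names(masks) <- names(tool_cfgs)
  segments <- lapply(names(tool_cfgs), function(t) {
    classify_segments(segment_idrs(masks[[t]],
                                   tool_cfgs[[t]]$min_idr_length),
                      co$proteins)
  })
  names(segments) <- names(tool_cfgs)
  annotated <- annotate_variants(co$variants, masks, segments, co$proteins)
  parts <- split_nmet(annotated)
  main <- complete_case_filter(parts$main, default_vep_panel())
  res <- list(cohort = co, masks = masks, segments = segments,
              annotated = annotated, nmet = parts$nmet, main = main)
  .cohort_cache[[which]] <- res
  res
}

# cached stratified bootstrap (metapredict strata, 200 x 2000) per cohort
get_bootstrap <- function(which = c("shrunk", "null")) {
  which <- match.arg(which)
  key <- paste0("boot_", which)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cc <- get_cohort(which)
  bs <- stratified_bootstrap(cc$main, default_vep_panel(), "metapredict",
                             n_reps = 200L, per_stratum = 2000L, seed = 8L)
  res <- list(replicates = bs, summary = gap_summary(bs))
  .cohort_cache[[key]] <- res
  res
}
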