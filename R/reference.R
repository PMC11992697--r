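#' Published cohort composition of the clinical benchmark
#'
#' The reported record counts of the ClinVar-derived benchmark the pipeline
#' emulates, shipped as reference metadata: the full curated set, the
#' complete-case benchmark set (variants with a prediction from every VEP),
#' and the start-methionine subsets (the complete-case start-Met set, and
#' the slightly smaller set underlying the per-VEP start-Met figure). Used
#' for internal-consistency checks and for sizing synthetic cohorts; the
#' package never downloads or re-derives these data.
#'
#' @return A `data.frame` with columns `set`, `n_pathogenic`, `n_benign`,
#'   `n_total` and `n_proteins` (`NA` where not reported).
#' @export
clinvar_reported_counts <- function() {
  data.frame(
    set = c("full", "benchmark", "nmet_all", "nmet_complete_case",
            "nmet_figure"),
    n_pathogenic = c(23234L, 17977L, NA_integer_, 334L, 331L),
    n_benign = c(38644L, 27339L, NA_integer_, 25L, 25L),
    n_total = c(61878L, 45316L, 523L, 359L, 356L),
    n_proteins = c(7459L, NA_integer_, NA_integer_, NA_integer_,
                   NA_integer_),
    stringsAsFactors = FALSE
  )
}
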