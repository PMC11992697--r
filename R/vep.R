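#' VEP calling configuration
#'
#' Describes how one variant effect predictor's output is converted into a
#' binary pathogenic/benign call: either a threshold on a continuous score
#' or a direct categorical mapping (with an ambiguous middle category that
#' is excluded from confusion counts).
#'
#' @param vep_name Predictor name; must match a column of the variant table.
#' @param mode `"threshold"` or `"categorical"`.
#' @param threshold Score cutoff (threshold mode).
#' @param direction `"ge"` (pathogenic if score >= threshold) or `"lt"`
#'   (pathogenic if score < threshold, for log-likelihood-style scores such
#'   as ESM1b's).
#' @param family `"deep_learning"` or `"machine_learning"`; metadata only.
#' @return A `vep_config` list.
#' @export
vep_config <- function(vep_name, mode = c("threshold", "categorical"),
                       threshold = NA_real_, direction = c("ge", "lt"),
                       family = c("machine_learning", "deep_learning")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  family <- match.arg(family)
  if (mode == "threshold" && !is.finite(threshold)) {
    stop("threshold mode requires a finite threshold")
  }
  structure(list(vep_name = vep_name, mode = mode, threshold = threshold,
                 direction = direction, family = family),
            class = "vep_config")
}

#' Default VEP panel
#'
#' The benchmarked predictor panel with the authors' recommended cutoffs:
#' REVEL, VEST4 and VARITY_R call pathogenic at score >= 0.5, MVP at
#' >= 0.7, ESM1b at score < -7.5, PolyPhen-2 (HVAR probability) at >= 0.5,
#' and AlphaMissense supplies its own benign/ambiguous/pathogenic
#' categories (ambiguous variants are excluded from its confusion counts).
#'
#' @return Named list of [vep_config()] objects.
#' @export
default_vep_panel <- function() {
  list(
    alphamissense = vep_config("alphamissense", "categorical",
                               family = "deep_learning"),
    revel    = vep_config("revel", "threshold", 0.5, "ge"),
    vest4    = vep_config("vest4", "threshold", 0.5, "ge"),
    varity_r = vep_config("varity_r", "threshold", 0.5, "ge"),
    mvp      = vep_config("mvp", "threshold", 0.7, "ge",
                          family = "deep_learning"),
    esm1b    = vep_config("esm1b", "threshold", -7.5, "lt",
                          family = "deep_learning"),
    polyphen2 = vep_config("polyphen2", "threshold", 0.5, "ge")
  )
}

#' Convert one VEP output into a pathogenic/benign call
#'
#' @param x A numeric score (threshold mode) or a category string
#'   (`"benign"`, `"pathogenic"`, `"ambiguous"`); `NA` for a missing
#'   prediction.
#' @param cfg A [vep_config()].
#' @return `"PATHOGENIC"`, `"BENIGN"` or `"EXCLUDED"` (missing score or
#'   ambiguous category).
#' @export
call_variant <- function(x, cfg) {
  stopifnot(inherits(cfg, "vep_config"))
  if (length(x) != 1L) stop("call_variant takes a single value")
  if (is.na(x)) return("EXCLUDED")
  if (cfg$mode == "threshold") {
    patho <- if (cfg$direction == "ge") x >= cfg$threshold else x < cfg$threshold
    return(if (patho) "PATHOGENIC" else "BENIGN")
  }
  switch(tolower(as.character(x)),
         pathogenic = "PATHOGENIC",
         benign = "BENIGN",
         ambiguous = "EXCLUDED",
         stop("unknown category '", x, "' for ", cfg$vep_name))
}

#' Call matrix for a variant table
#'
#' Vectorised [call_variant()] over every variant and every panel member.
#'
#' @param variants Variant `data.frame` containing one column per panel VEP.
#' @param panel Named list of [vep_config()]s.
#' @return Character matrix (variants x VEPs) of
#'   `"PATHOGENIC"`/`"BENIGN"`/`"EXCLUDED"`.
#' @export
call_matrix <- function(variants, panel) {
  out <- matrix(NA_character_, nrow(variants), length(panel),
                dimnames = list(NULL, vapply(panel, `[[`, "", "vep_name")))
  for (cfg in panel) {
    v <- cfg$vep_name
    if (!v %in% names(variants)) stop("no column for VEP ", v)
    x <- variants[[v]]
    if (cfg$mode == "threshold") {
      patho <- if (cfg$direction == "ge") x >= cfg$threshold else x < cfg$threshold
      call <- ifelse(patho, "PATHOGENIC", "BENIGN")
      call[is.na(x)] <- "EXCLUDED"
    } else {
      lx <- tolower(as.character(x))
      known <- lx %in% c("pathogenic", "benign", "ambiguous") | is.na(lx)
      if (!all(known)) {
        stop("unknown category '", x[!known][1L], "' for ", v)
      }
      call <- c(pathogenic = "PATHOGENIC", benign = "BENIGN",
                ambiguous = "EXCLUDED")[lx]
      call[is.na(lx)] <- "EXCLUDED"
    }
    out[, v] <- unname(call)
  }
  out
}

#' Restrict to variants with a prediction from every panel VEP
#'
#' The benchmark is run on the complete-case set: only variants for which a
#' prediction exists across all VEPs in the panel. By default an
#' ambiguous category counts as an existing prediction (it is excluded only
#' from that VEP's confusion counts); set `ambiguous_as_missing = TRUE` for
#' the stricter reading. The per-VEP missingness report is attached as the
#' `"report"` attribute, with VEPs exceeding `flag_missing_above`
#' missingness flagged for exclusion from the panel.
#'
#' @param variants Variant `data.frame`.
#' @param panel Named list of [vep_config()]s.
#' @param ambiguous_as_missing Treat ambiguous categories as missing.
#' @param flag_missing_above Missingness fraction above which a VEP is
#'   flagged (default 0.5).
#' @return The retained rows, with attribute `report` (a `data.frame`:
#'   `vep`, `n_missing`, `missing_fraction`, `flagged`).
#' @export
complete_case_filter <- function(variants, panel, ambiguous_as_missing = FALSE,
                                 flag_missing_above = 0.5) {
  stopifnot(length(panel) >= 1L)
  has <- matrix(TRUE, nrow(variants), length(panel),
                dimnames = list(NULL, vapply(panel, `[[`, "", "vep_name")))
  for (cfg in panel) {
    x <- variants[[cfg$vep_name]]
    if (is.null(x)) stop("no column for VEP ", cfg$vep_name)
    present <- !is.na(x)
    if (cfg$mode == "categorical" && ambiguous_as_missing) {
      present <- present & tolower(as.character(x)) != "ambiguous"
    }
    has[, cfg$vep_name] <- present
  }
  n <- nrow(variants)
  miss <- n - colSums(has)
  report <- data.frame(vep = colnames(has), n_missing = as.integer(miss),
                       missing_fraction = if (n > 0) miss / n else rep(0, ncol(has)),
                       stringsAsFactors = FALSE)
  report$flagged <- report$missing_fraction > flag_missing_above
  keep <- rowSums(has) == length(panel)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}
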