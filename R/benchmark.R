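#' Confusion counts for one VEP
#'
#' Tallies calls against ground-truth labels with pathogenic as the positive
#' class. `EXCLUDED` calls (missing scores, ambiguous categories) are
#' dropped before counting, so the four cells partition the non-excluded
#' variants.
#'
#' @param calls Character vector of `"PATHOGENIC"`/`"BENIGN"`/`"EXCLUDED"`.
#' @param labels Character vector of `"PATHOGENIC"`/`"BENIGN"` ground truth.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion <- function(calls, labels) {
  stopifnot(length(calls) == length(labels))
  keep <- calls != "EXCLUDED"
  calls <- calls[keep]
  labels <- labels[keep]
  c(tp = sum(calls == "PATHOGENIC" & labels == "PATHOGENIC"),
    fp = sum(calls == "PATHOGENIC" & labels == "BENIGN"),
    fn = sum(calls == "BENIGN" & labels == "PATHOGENIC"),
    tn = sum(calls == "BENIGN" & labels == "BENIGN"))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F1 = 2*precision*recall/(precision+recall). A metric whose
#' denominator is zero is `NA`.
#'
#' @param counts Named vector from [confusion()] (`tp`, `fp`, `fn`, `tn`).
#' @return Named numeric vector `c(sensitivity, specificity, precision, f1)`.
#' @export
metric_set <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney estimator with midranks for ties: the probability that a
#' randomly chosen pathogenic variant receives a more pathogenic-oriented
#' score than a randomly chosen benign one, ties counted one half. For
#' predictors where low scores mean pathogenic (direction `"lt"`) the score
#' sign is flipped before ranking.
#'
#' @param scores Numeric scores (`NA` dropped together with their labels).
#' @param labels `"PATHOGENIC"`/`"BENIGN"` ground truth.
#' @param direction `"ge"` (higher = more pathogenic) or `"lt"`.
#' @return AUC in `[0, 1]`, or `NA` when either class is absent.
#' @export
roc_auc <- function(scores, labels, direction = c("ge", "lt")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  if (direction == "lt") scores <- -scores
  pos <- labels == "PATHOGENIC"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Analytic per-site variant probability under uniformity
#'
#' If variants fell uniformly over the residues of a protein of length `L`,
#' each site would collect `100/L` percent of them; for the cohort median
#' length of 572 residues that is about 0.17% per site, the baseline against
#' which the observed excess of initiator-methionine variants is judged.
#'
#' @param protein_length Protein length in residues.
#' @return Per-site percentage (0-100 scale).
#' @export
nmet_uniform_baseline <- function(protein_length = 572) {
  stopifnot(protein_length >= 1)
  100 / protein_length
}

#' Four-stratum bootstrap of sensitivity and specificity
#'
#' The cohort's composition over phenotype x disorder is unbalanced, so
#' metrics are estimated on bootstrap samples drawn with replacement,
#' `per_stratum` variants from each of the four strata formed by
#' (pathogenic, benign) x (disordered, ordered) under the chosen disorder
#' tool. Per replicate and per VEP, sensitivity and specificity are
#' computed separately within the disordered and ordered subsets of the
#' pooled sample (each stratum is single-label, so per-class sensitivity
#' uses the pathogenic stratum of that class, and specificity the benign
#' one). Start-methionine variants must be removed beforehand.
#'
#' @param annotated Annotated, complete-case variant table (see
#'   [annotate_variants()], [complete_case_filter()]).
#' @param panel Named list of [vep_config()]s.
#' @param tool_id Disorder tool whose `<tool>_disordered` column defines the
#'   strata.
#' @param n_reps Number of bootstrap replicates (default 200).
#' @param per_stratum Variants drawn per stratum per replicate (default
#'   12540, giving a pooled sample of 50160, the scale of the cohort).
#' @param seed Integer root seed; replicate child seeds are derived from it
#'   deterministically.
#' @param allow_nmet Set `TRUE` to skip the guard against start-methionine
#'   variants still being present.
#' @return A long `data.frame`: `vep`, `tool_id`, `disorder_class`
#'   (`"DISORDERED"`/`"ORDERED"`), `replicate`, `sensitivity`,
#'   `specificity`.
#' @export
stratified_bootstrap <- function(annotated, panel, tool_id, n_reps = 200L,
                                 per_stratum = 12540L, seed = 1L,
                                 allow_nmet = FALSE) {
  stopifnot(n_reps >= 1, per_stratum >= 1)
  if (!allow_nmet && "is_nmet" %in% names(annotated) &&
      any(annotated$is_nmet)) {
    stop("start-methionine variants are still present; remove them with ",
         "split_nmet() or set allow_nmet = TRUE")
  }
  dcol <- paste0(tool_id, "_disordered")
  if (!dcol %in% names(annotated)) stop("no disorder annotation for ", tool_id)
  dis <- annotated[[dcol]]
  patho <- annotated$label == "PATHOGENIC"
  strata <- list(
    pathogenic_disordered = which(patho & dis),
    benign_disordered     = which(!patho & dis),
    pathogenic_ordered    = which(patho & !dis),
    benign_ordered        = which(!patho & !dis)
  )
  empty <- names(strata)[vapply(strata, length, 1L) == 0L]
  if (length(empty)) stop("empty bootstrap stratum: ", empty[1L])

  cm <- call_matrix(annotated, panel)
  veps <- colnames(cm)
  # integer encoding for fast tallying: 1 = PATHOGENIC, 2 = BENIGN, 3 = EXCLUDED
  ci <- matrix(match(cm, c("PATHOGENIC", "BENIGN", "EXCLUDED")), nrow(cm),
               dimnames = dimnames(cm))

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  rate <- function(idx, wanted) {
    sub <- ci[idx, , drop = FALSE]
    hit <- colSums(sub == wanted)
    valid <- nrow(sub) - colSums(sub == 3L)
    ifelse(valid > 0, hit / valid, NA_real_)
  }

  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    draw <- lapply(strata, function(s) s[sample.int(length(s), per_stratum,
                                                    replace = TRUE)])
    sens_dis <- rate(draw$pathogenic_disordered, 1L)
    spec_dis <- rate(draw$benign_disordered, 2L)
    sens_ord <- rate(draw$pathogenic_ordered, 1L)
    spec_ord <- rate(draw$benign_ordered, 2L)
    res[[r]] <- data.frame(
      vep = rep(veps, 2L), tool_id = tool_id,
      disorder_class = rep(c("DISORDERED", "ORDERED"), each = length(veps)),
      replicate = r,
      sensitivity = c(sens_dis, sens_ord),
      specificity = c(spec_dis, spec_ord),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Medians and specificity-minus-sensitivity gaps
#'
#' Summarises a bootstrap distribution to per (VEP, tool, disorder class)
#' medians and the gap `median(specificity) - median(sensitivity)`; positive
#' gaps mean the predictor is more specific than sensitive in that class.
#'
#' @param distributions Output of [stratified_bootstrap()] (several tools
#'   may be row-bound together).
#' @return A `data.frame`: `vep`, `tool_id`, `disorder_class`,
#'   `median_sensitivity`, `median_specificity`, `gap`.
#' @export
gap_summary <- function(distributions) {
  key <- interaction(distributions$vep, distributions$tool_id,
                     distributions$disorder_class, drop = TRUE)
  rows <- lapply(split(distributions, key), function(d) {
    ms <- stats::median(d$sensitivity, na.rm = TRUE)
    mp <- stats::median(d$specificity, na.rm = TRUE)
    data.frame(vep = d$vep[1L], tool_id = d$tool_id[1L],
               disorder_class = d$disorder_class[1L],
               median_sensitivity = ms, median_specificity = mp,
               gap = mp - ms, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tool_id, out$vep, out$disorder_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class plug-in metrics for every panel VEP
#'
#' Convenience summary without resampling: sensitivity, specificity and AUC
#' per VEP within the disordered and ordered subsets defined by one tool's
#' annotation (AUC from the continuous scores where available).
#'
#' @inheritParams stratified_bootstrap
#' @return A `data.frame`: `vep`, `tool_id`, `disorder_class`,
#'   `sensitivity`, `specificity`, `auc`, `n`.
#' @export
plugin_metrics <- function(annotated, panel, tool_id) {
  dcol <- paste0(tool_id, "_disordered")
  cm <- call_matrix(annotated, panel)
  rows <- list()
  for (cls in c("DISORDERED", "ORDERED")) {
    sel <- if (cls == "DISORDERED") annotated[[dcol]] else !annotated[[dcol]]
    lab <- annotated$label[sel]
    for (cfg in panel) {
      v <- cfg$vep_name
      met <- metric_set(confusion(cm[sel, v], lab))
      auc <- if (cfg$mode == "threshold") {
        roc_auc(annotated[[v]][sel], lab, cfg$direction)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        vep = v, tool_id = tool_id, disorder_class = cls,
        sensitivity = met[["sensitivity"]], specificity = met[["specificity"]],
        auc = auc, n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
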