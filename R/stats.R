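#' Chi-square test of independence with adjusted standardized residuals
#'
#' Pearson chi-square on an r x c contingency table (no continuity
#' correction), expected counts from the product of the margins, and the
#' adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - row prop) (1 - col prop))`, which localise the
#' departures from independence cell by cell.
#'
#' @param observed Integer matrix of counts; all row and column sums must be
#'   positive.
#' @return A list: `observed`, `expected`, `statistic`, `dof`, `p_value`,
#'   `std_residuals`.
#' @export
chisq_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("negative counts")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    stop("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  as_plain <- function(m) {
    matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  }
  list(observed = as_plain(observed),
       expected = as_plain(ct$expected),
       statistic = unname(ct$statistic),
       dof = unname(ct$parameter),
       p_value = ct$p.value,
       std_residuals = as_plain(ct$stdres))
}

#' IDR positional group x phenotype contingency table
#'
#' Cross-tabulates, for one disorder tool, the positional group of the
#' covering IDR (N-terminal, C-terminal, between domains, IDP) against the
#' clinical label, over variants inside retained IDRs.
#'
#' @param annotated Annotated variant table (see [annotate_variants()]).
#' @param tool_id Disorder tool name.
#' @return A counts matrix (groups x labels), suitable for
#'   [chisq_independence()].
#' @export
idr_group_table <- function(annotated, tool_id) {
  gcol <- paste0(tool_id, "_group")
  if (!gcol %in% names(annotated)) stop("no group annotation for ", tool_id)
  sub <- annotated[annotated[[gcol]] != "ORDERED", , drop = FALSE]
  if (nrow(sub) == 0L) stop("no variants inside retained IDRs for ", tool_id)
  t(table(sub$label, factor(sub[[gcol]],
                            levels = c("NTERM", "BETWEEN", "CTERM", "IDP"))))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. The p-value is
#' exact by enumeration when `length(x) * length(y) <= exact_limit` and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"greater"` (x tends larger than y), `"less"` or
#'   `"two.sided"`.
#' @param exact_limit Product `n * m` up to which the exact distribution is
#'   used (default 400).
#' @return A list: `statistic` (the Mann-Whitney U for x), `p_value`,
#'   `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("greater", "less", "two.sided"),
                              exact_limit = 400L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= exact_limit
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Second-methionine distance comparison for start-Met variant hosts
#'
#' One-sided Wilcoxon rank-sum test of whether proteins carrying pathogenic
#' start-methionine variants have their second methionine further away than
#' proteins carrying benign ones (alternative "greater"). Proteins without
#' a second methionine are excluded.
#'
#' @param nmet Annotated start-Met variant subset (see [split_nmet()]).
#' @return A list: `n_pathogenic`, `n_benign`, `statistic`, `p_value`,
#'   `exact`.
#' @export
second_met_test <- function(nmet) {
  d <- nmet$second_met_distance
  keep <- !is.na(d)
  d <- d[keep]
  lab <- nmet$label[keep]
  x <- d[lab == "PATHOGENIC"]
  y <- d[lab == "BENIGN"]
  if (length(x) == 0L || length(y) == 0L) {
    stop("need both pathogenic and benign start-Met hosts with a second Met")
  }
  res <- wilcoxon_rank_sum(x, y, alternative = "greater")
  c(list(n_pathogenic = length(x), n_benign = length(y)), res)
}
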