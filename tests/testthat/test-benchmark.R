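test_that("confusion counts partition the non-excluded variants", {
  calls <- c(rep("PATHOGENIC", 4), rep("BENIGN", 6))
  labels <- c(rep("PATHOGENIC", 4), rep("BENIGN", 6))
  expect_equal(confusion(calls, labels), c(tp = 4L, fp = 0L, fn = 0L, tn = 6L))

  calls2 <- c("PATHOGENIC", "PATHOGENIC", "BENIGN", "PATHOGENIC", "BENIGN")
  labels2 <- c(rep("PATHOGENIC", 3), rep("BENIGN", 2))
  expect_equal(confusion(calls2, labels2), c(tp = 2L, fp = 1L, fn = 1L, tn = 1L))

  set.seed(21)
  for (i in 1:20) {
    calls <- sample(c("PATHOGENIC", "BENIGN", "EXCLUDED"), 50, replace = TRUE)
    labels <- sample(c("PATHOGENIC", "BENIGN"), 50, replace = TRUE)
    got <- confusion(calls, labels)
    want <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (j in 1:50) {
      if (calls[j] == "EXCLUDED") next
      cell <- if (calls[j] == "PATHOGENIC" && labels[j] == "PATHOGENIC") "tp"
        else if (calls[j] == "PATHOGENIC") "fp"
        else if (labels[j] == "PATHOGENIC") "fn" else "tn"
      want[cell] <- want[cell] + 1L
    }
    expect_equal(got, want)
    expect_equal(sum(got), sum(calls != "EXCLUDED"))
  }
})

test_that("metrics follow the confusion-matrix formulas with NA on zero denominators", {
  m <- metric_set(c(tp = 9, fp = 16, fn = 1, tn = 84))
  expect_equal(m[["sensitivity"]], 0.9)
  expect_equal(m[["specificity"]], 0.84)
  expect_equal(m[["precision"]], 9 / 25)
  expect_equal(m[["f1"]], 2 * (9 / 25) * 0.9 / ((9 / 25) + 0.9))

  z <- metric_set(c(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(z[["sensitivity"]]))
  expect_equal(z[["specificity"]], 1)
  expect_true(is.na(z[["precision"]]))
})

test_that("rank-based AUC equals exhaustive pair counting and behaves under transforms", {
  lab8 <- c(rep("PATHOGENIC", 4), rep("BENIGN", 4))
  s8 <- c(0.9, 0.8, 0.55, 0.3, 0.6, 0.55, 0.2, 0.1)
  expect_equal(roc_auc(s8, lab8), auc_pair_oracle(s8, lab8))

  expect_equal(roc_auc(c(1, 1, 0, 0), lab8[c(1, 2, 5, 6)]), 1)
  expect_equal(roc_auc(rep(0.5, 8), lab8), 0.5)
  expect_true(is.na(roc_auc(1:4, rep("BENIGN", 4))))

  set.seed(31)
  for (i in 1:25) {
    s <- round(rnorm(20), 1)  # rounding forces ties
    lab <- sample(c("PATHOGENIC", "BENIGN"), 20, replace = TRUE,
                  prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(s, lab), auc_pair_oracle(s, lab))
    # invariant under strictly increasing transforms
    expect_equal(roc_auc(exp(s), lab), roc_auc(s, lab))
    # complement identity needs tie-free scores
    s2 <- rnorm(20)
    expect_equal(roc_auc(s2, lab) + roc_auc(-s2, lab), 1)
    # direction flip equals negation
    expect_equal(roc_auc(s, lab, "lt"), roc_auc(-s, lab, "ge"))
  }
})

test_that("AUC matches the pROC reference implementation", {
  set.seed(41)
  s <- rnorm(60)
  lab <- sample(c("PATHOGENIC", "BENIGN"), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = s, levels = c("BENIGN", "PATHOGENIC"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, lab), ref)
})

test_that("the uniform per-site baseline for the median-length protein is about 0.17%", {
  expect_equal(nmet_uniform_baseline(572), 100 / 572)
  expect_equal(sprintf("%.2f", nmet_uniform_baseline(572)), "0.17")
})

test_that("a perfect classifier scores 1/1 and an all-pathogenic caller 1/0 in every replicate", {
  coh <- make_bench_cohort()
  bs <- stratified_bootstrap(coh, bench_panel(), "toolA", n_reps = 200,
                             per_stratum = 500, seed = 7)
  orc <- bs[bs$vep == "oracle", ]
  expect_true(all(orc$sensitivity == 1))
  expect_true(all(orc$specificity == 1))
  ap <- bs[bs$vep == "allpath", ]
  expect_true(all(ap$sensitivity == 1))
  expect_true(all(ap$specificity == 0))
})

test_that("the bootstrap is reproducible, guarded, and names empty strata", {
  coh <- make_bench_cohort()
  b1 <- stratified_bootstrap(coh, bench_panel(), "toolA", n_reps = 10,
                             per_stratum = 50, seed = 99)
  b2 <- stratified_bootstrap(coh, bench_panel(), "toolA", n_reps = 10,
                             per_stratum = 50, seed = 99)
  expect_identical(b1, b2)
  b3 <- stratified_bootstrap(coh, bench_panel(), "toolA", n_reps = 10,
                             per_stratum = 50, seed = 100)
  expect_false(identical(b1$sensitivity, b3$sensitivity))

  only_ord <- coh[!coh$toolA_disordered, ]
  expect_error(stratified_bootstrap(only_ord, bench_panel(), "toolA"),
               "pathogenic_disordered")

  withmet <- coh
  withmet$is_nmet[1] <- TRUE
  expect_error(stratified_bootstrap(withmet, bench_panel(), "toolA"),
               "start-methionine")
  expect_silent(stratified_bootstrap(withmet, bench_panel(), "toolA",
                                     n_reps = 2, per_stratum = 10, seed = 1,
                                     allow_nmet = TRUE))
})

test_that("replicate means converge to the plug-in metrics of the strata", {
  set.seed(55)
  coh <- make_bench_cohort(n_per_stratum = 5L, seed = 3L)
  bs <- stratified_bootstrap(coh, bench_panel()["noisy"], "toolA",
                             n_reps = 2000, per_stratum = 5, seed = 17)
  cm <- call_matrix(coh, bench_panel()["noisy"])
  for (cls in c("DISORDERED", "ORDERED")) {
    dis <- cls == "DISORDERED"
    sel_p <- coh$label == "PATHOGENIC" & coh$toolA_disordered == dis
    plug_sens <- mean(cm[sel_p, "noisy"] == "PATHOGENIC")
    reps <- bs$sensitivity[bs$disorder_class == cls]
    se <- stats::sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - plug_sens), 3 * se + 1e-12)
  }
})

test_that("gap summary reports median specificity minus median sensitivity", {
  d <- data.frame(vep = "v", tool_id = "t",
                  disorder_class = rep(c("DISORDERED", "ORDERED"), each = 5),
                  replicate = rep(1:5, 2),
                  sensitivity = c(rep(0.85, 5), rep(0.95, 5)),
                  specificity = c(rep(0.95, 5), rep(0.95, 5)))
  g <- gap_summary(d)
  expect_equal(g$gap[g$disorder_class == "DISORDERED"], 0.10)
  expect_equal(g$gap[g$disorder_class == "ORDERED"], 0)
})
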