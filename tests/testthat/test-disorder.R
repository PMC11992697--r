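test_that("Savitzky-Golay smoothing preserves low-degree polynomials exactly", {
  expect_equal(smooth_scores(rep(0.4, 20), 9, 3), rep(0.4, 20))
  ramp <- 0.01 * (1:30)
  expect_equal(smooth_scores(ramp, 9, 3), ramp)
  cubic <- 1 + 0.2 * (1:25) - 0.01 * (1:25)^2 + 3e-4 * (1:25)^3
  expect_equal(smooth_scores(cubic, 9, 3), cubic, tolerance = 1e-10)
})

test_that("smoothing matches the per-window least-squares oracle", {
  set.seed(101)
  for (rep in 1:10) {
    x <- cumsum(rnorm(50))
    expect_equal(smooth_scores(x, 9, 3), sg_oracle(x, 9, 3),
                 tolerance = 1e-10)
    expect_equal(smooth_scores(x, 7, 2), sg_oracle(x, 7, 2),
                 tolerance = 1e-10)
  }
})

test_that("smoothing guards its preconditions and short tracks", {
  expect_error(smooth_scores(1:20, window = 8), "odd")
  expect_error(smooth_scores(1:20, window = 9, degree = 9), "degree")
  short <- c(0.9, 0.1, 0.5)
  expect_identical(smooth_scores(short, 9, 3), short)
})

test_that("disorder calling honours each threshold dialect", {
  plddt <- make_track(c(90, 70, 35), tool_id = "plddt")
  cfg <- tool_config("plddt", 70, "le")
  expect_equal(call_disorder(plddt, cfg)$disordered, c(FALSE, TRUE, TRUE))

  meta <- make_track(c(0.5, 0.51), tool_id = "metapredict")
  cfg2 <- tool_config("metapredict", 0.5, "gt")
  expect_equal(call_disorder(meta, cfg2)$disordered, c(FALSE, TRUE))

  ge <- tool_config("fldpnn", 0.3, "ge")
  expect_equal(call_disorder(make_track(c(0.3, 0.29)), ge)$disordered,
               c(TRUE, FALSE))

  inf <- tool_config("x", Inf, "gt")
  expect_false(any(call_disorder(make_track(runif(40)), inf)$disordered))
})

test_that("smoothing-enabled configs threshold the smoothed track", {
  set.seed(7)
  scores <- c(rep(0.2, 20), 0.9, rep(0.2, 20))  # lone spike
  cfg_raw <- tool_config("t", 0.5, "gt", smoothing = FALSE)
  cfg_sm <- tool_config("t", 0.5, "gt", smoothing = TRUE)
  expect_true(any(call_disorder(make_track(scores), cfg_raw)$disordered))
  # the smoothed spike falls below threshold
  expect_false(any(call_disorder(make_track(scores), cfg_sm)$disordered))
})

test_that("IDR segmentation drops short runs and matches exhaustive scanning", {
  nine <- make_mask(c(rep(FALSE, 5), rep(TRUE, 9), rep(FALSE, 5)))
  expect_equal(nrow(segment_idrs(nine, 10)), 0L)

  all25 <- make_mask(rep(TRUE, 25))
  seg <- segment_idrs(all25, 10)
  expect_equal(seg[, c("start", "end")], data.frame(start = 1L, end = 25L))

  set.seed(202)
  for (i in 1:200) {
    n <- sample(1:64, 1)
    flags <- runif(n) < 0.5
    got <- segment_idrs(make_mask(flags), 10)
    want <- runs_oracle(flags, 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(cbind(got$start, got$end), unname(want))
    }
  }
})

test_that("segmentation is idempotent and monotone in the length cutoff", {
  set.seed(303)
  for (i in 1:40) {
    flags <- runif(80) < 0.6
    seg <- segment_idrs(make_mask(flags), 10)
    # rebuild a mask from the union of returned segments
    covered <- rep(FALSE, 80)
    for (j in seq_len(nrow(seg))) covered[seg$start[j]:seg$end[j]] <- TRUE
    expect_identical(segment_idrs(make_mask(covered), 10)[, c("start", "end")],
                     seg[, c("start", "end")])
    n_prev <- Inf
    cov_prev <- Inf
    for (mlen in c(1, 5, 10, 20)) {
      s <- segment_idrs(make_mask(flags), mlen)
      covered_n <- sum(s$end - s$start + 1L)
      expect_lte(nrow(s), n_prev)
      expect_lte(covered_n, cov_prev)
      n_prev <- nrow(s); cov_prev <- covered_n
    }
  }
})

test_that("segment classification assigns exactly one positional group", {
  expect_equal(classify_segment(1, 200, 200), "IDP")
  expect_equal(classify_segment(1, 40, 200), "NTERM")
  expect_equal(classify_segment(150, 200, 200), "CTERM")
  expect_equal(classify_segment(50, 80, 200), "BETWEEN")
  expect_error(classify_segment(0, 10, 200), "outside")
  expect_error(classify_segment(190, 201, 200), "outside")
  # IDP precedence: a full-protein segment is never NTERM/CTERM
  expect_equal(classify_segment(1, 50, 50), "IDP")

  seg <- data.frame(protein_id = c("A", "A", "B"), tool_id = "t",
                    start = c(1L, 90L, 1L), end = c(20L, 100L, 30L))
  prot <- data.frame(protein_id = c("A", "B"), length = c(100L, 30L))
  got <- classify_segments(seg, prot)
  expect_equal(got$group, c("NTERM", "CTERM", "IDP"))
})

test_that("combination frequencies tally multi-tool patterns", {
  m1 <- make_mask(c(TRUE, TRUE, FALSE, FALSE), tool_id = "a")
  m2 <- make_mask(c(TRUE, TRUE, FALSE, FALSE), tool_id = "b")
  tab <- combination_frequencies(list(m1, m2))
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$frequency), 1)
  expect_setequal(paste0(tab$a, tab$b), c("11", "00"))

  set.seed(404)
  masks <- lapply(c("a", "b", "c"), function(t) {
    make_mask(runif(20) < 0.5, tool_id = t)
  })
  tab3 <- combination_frequencies(masks)
  expect_equal(sum(tab3$count), 20L)
  expect_equal(sum(tab3$frequency), 1)
  # brute-force tally of one specific pattern
  pat <- paste0(masks[[1]]$disordered * 1, masks[[2]]$disordered * 1,
                masks[[3]]$disordered * 1)
  for (k in seq_len(nrow(tab3))) {
    want <- sum(pat == paste0(tab3$a[k], tab3$b[k], tab3$c[k]))
    expect_equal(tab3$count[k], want)
  }

  short <- make_mask(c(TRUE, FALSE), tool_id = "b")
  expect_error(combination_frequencies(list(m1, short)), "different residue")
})

test_that("containment fraction counts disordered residues outside retained IDRs", {
  run12 <- make_mask(c(rep(TRUE, 12), rep(FALSE, 8)))
  expect_equal(idr_containment_fraction(run12, segment_idrs(run12, 10)), 0)

  mixed <- make_mask(c(rep(TRUE, 12), rep(FALSE, 5), rep(TRUE, 5),
                       rep(FALSE, 3)))
  expect_equal(idr_containment_fraction(mixed, segment_idrs(mixed, 10)),
               5 / 17)

  set.seed(505)
  for (i in 1:50) {
    flags <- runif(60) < 0.5
    if (!any(flags)) next
    segs <- segment_idrs(make_mask(flags), 10)
    covered <- rep(FALSE, 60)
    for (j in seq_len(nrow(segs))) covered[segs$start[j]:segs$end[j]] <- TRUE
    want <- sum(flags & !covered) / sum(flags)
    expect_equal(idr_containment_fraction(make_mask(flags), segs), want)
  }
})

test_that("BED export shifts to half-open 0-based coordinates", {
  seg <- data.frame(protein_id = "A", tool_id = "t", start = 5L, end = 20L,
                    group = "BETWEEN")
  bed <- segments_to_bed(seg)
  expect_equal(bed$start0, 4L)
  expect_equal(bed$end, 20L)
})
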