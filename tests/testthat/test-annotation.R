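make_anno_inputs <- function() {
  prot <- data.frame(
    protein_id = c("P1", "P2"),
    sequence = c(paste0("M", strrep("A", 98), "M"),    # second Met at 100
                 paste0("MM", strrep("K", 28))),       # second Met at 2
    stringsAsFactors = FALSE)
  prot$length <- nchar(prot$sequence)
  flags1 <- rep(FALSE, 100)
  flags1[1:20] <- TRUE    # retained NTERM segment
  flags1[40:44] <- TRUE   # short run: disordered but no retained segment
  flags2 <- rep(FALSE, 30)
  masks <- list(toolA = rbind(make_mask(flags1, "P1", "toolA"),
                              make_mask(flags2, "P2", "toolA")))
  segs <- segment_idrs(masks$toolA, 10)
  segs <- classify_segments(segs, prot)
  list(proteins = prot, masks = masks, segments = list(toolA = segs))
}

test_that("annotation joins disorder flags, segment groups and N-Met attributes", {
  inp <- make_anno_inputs()
  v <- data.frame(protein_id = c("P1", "P1", "P1", "P2"),
                  position = c(5L, 42L, 60L, 1L),
                  ref_aa = c("A", "A", "A", "M"),
                  alt_aa = c("V", "V", "V", "T"),
                  label = c("BENIGN", "BENIGN", "PATHOGENIC", "PATHOGENIC"),
                  stringsAsFactors = FALSE)
  a <- annotate_variants(v, inp$masks, inp$segments, inp$proteins)

  expect_true(a$toolA_disordered[1])
  expect_equal(a$toolA_group[1], "NTERM")
  # disordered residue inside a dropped (<10) run: flag TRUE, group ORDERED
  expect_true(a$toolA_disordered[2])
  expect_equal(a$toolA_group[2], "ORDERED")
  expect_false(a$toolA_disordered[3])
  expect_equal(a$toolA_group[3], "ORDERED")

  expect_equal(a$is_nmet, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(a$second_met_distance, c(99L, 99L, 99L, 1L))
})

test_that("annotation is a pure join: permuting inputs permutes outputs", {
  inp <- make_anno_inputs()
  set.seed(9)
  v <- data.frame(protein_id = "P1", position = sample(1:100, 20),
                  ref_aa = "A", alt_aa = "V", label = "BENIGN",
                  stringsAsFactors = FALSE)
  v$ref_aa <- substring(inp$proteins$sequence[1], v$position, v$position)
  v <- v[v$ref_aa != "V", ]
  a <- annotate_variants(v, inp$masks, inp$segments, inp$proteins)
  perm <- sample(nrow(v))
  a2 <- annotate_variants(v[perm, ], inp$masks, inp$segments, inp$proteins)
  rownames(a2) <- NULL
  a_perm <- a[perm, ]
  rownames(a_perm) <- NULL
  expect_equal(a2, a_perm)
})

test_that("non-ORDERED groups always have a covering segment of that group", {
  inp <- make_anno_inputs()
  set.seed(10)
  pos <- sample(1:100, 30, replace = TRUE)
  v <- data.frame(protein_id = "P1", position = pos,
                  ref_aa = substring(inp$proteins$sequence[1], pos, pos),
                  alt_aa = "W", label = "BENIGN", stringsAsFactors = FALSE)
  v <- v[v$ref_aa != "W", ]
  a <- annotate_variants(v, inp$masks, inp$segments, inp$proteins)
  segs <- inp$segments$toolA
  for (i in seq_len(nrow(a))) {
    if (a$toolA_group[i] != "ORDERED") {
      hit <- segs$start <= a$position[i] & segs$end >= a$position[i]
      expect_true(any(hit) && segs$group[hit][1] == a$toolA_group[i])
    }
  }
})

test_that("annotation validates positions and reference alleles", {
  inp <- make_anno_inputs()
  beyond <- data.frame(protein_id = "P2", position = 31L, ref_aa = "K",
                       alt_aa = "R", label = "BENIGN")
  expect_error(annotate_variants(beyond, inp$masks, inp$segments,
                                 inp$proteins), "beyond")
  mism <- data.frame(protein_id = "P1", position = 5L, ref_aa = "W",
                     alt_aa = "R", label = "BENIGN")
  expect_error(annotate_variants(mism, inp$masks, inp$segments,
                                 inp$proteins), "mismatch")
  expect_warning(annotate_variants(mism, inp$masks, inp$segments,
                                   inp$proteins, strict = FALSE), "mismatch")
})

test_that("second-Met distance follows the pos2 - 1 convention", {
  expect_equal(second_met_distance("MAM"), 2L)
  expect_equal(second_met_distance("MM"), 1L)
  expect_true(is.na(second_met_distance("MAAAA")))
  expect_error(second_met_distance(""), "empty")
  expect_warning(d <- second_met_distance("AAM"), "does not start with M")
  expect_true(is.na(d))
})

test_that("split_nmet is a lossless partition keyed on position-1 methionines", {
  a <- data.frame(protein_id = "P", position = c(1L, 1L, 1L, 2:8),
                  ref_aa = c("M", "M", "M", rep("A", 7)),
                  alt_aa = "V", label = "BENIGN", is_nmet = NA,
                  stringsAsFactors = FALSE)
  a$is_nmet <- a$position == 1L & a$ref_aa == "M"
  parts <- split_nmet(a)
  expect_equal(nrow(parts$nmet), 3L)
  expect_equal(nrow(parts$main), 7L)
  expect_equal(nrow(parts$nmet) + nrow(parts$main), nrow(a))

  # a position-1 variant whose reference is not M belongs to the main set
  b <- a
  b$ref_aa[1] <- "V"
  b$alt_aa[1] <- "I"
  b$is_nmet <- b$position == 1L & b$ref_aa == "M"
  parts2 <- split_nmet(b)
  expect_equal(nrow(parts2$nmet), 2L)
  expect_equal(nrow(parts2$main), 8L)
})
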