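# Programmatic fixtures: small files and tables built at test time.

write_track_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  # rows: data.frame(protein_id, position, score) -- written verbatim
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal PDB text: one N and one CA atom per residue (CA carries b)
write_pdb_file <- function(resno, b, path = tempfile(fileext = ".pdb"),
                           drop_ca_for = integer(0)) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(resno)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
      serial, resno[i], i * 1.0, 0, 0, 1, b[i]))
    if (!resno[i] %in% drop_ca_for) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, resno[i], i * 1.0, 1, 0, 1, b[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

make_mask <- function(flags, protein_id = "P1", tool_id = "toolA") {
  data.frame(protein_id = protein_id, tool_id = tool_id,
             position = seq_along(flags), disordered = flags,
             stringsAsFactors = FALSE)
}

make_track <- function(scores, protein_id = "P1", tool_id = "toolA") {
  data.frame(protein_id = protein_id, tool_id = tool_id,
             position = seq_along(scores), score = scores,
             stringsAsFactors = FALSE)
}

# a small hand-built annotated cohort for benchmark unit tests:
# `oracle` scores equal the label indicator, `allpath` is constant high
make_bench_cohort <- function(n_per_stratum = 30L, seed = 42L) {
  set.seed(seed)
  grid <- expand.grid(label = c("PATHOGENIC", "BENIGN"),
                      dis = c(TRUE, FALSE), stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(protein_id = "P1", position = seq_len(n_per_stratum),
               ref_aa = "A", alt_aa = "V", label = grid$label[i],
               toolA_disordered = grid$dis[i], is_nmet = FALSE,
               stringsAsFactors = FALSE)
  }))
  rows$oracle <- ifelse(rows$label == "PATHOGENIC", 1, 0)
  rows$allpath <- 1
  rows$noisy <- ifelse(rows$label == "PATHOGENIC",
                       rnorm(nrow(rows), 0.7, 0.15),
                       rnorm(nrow(rows), 0.3, 0.15))
  rows
}

bench_panel <- function() {
  list(oracle = vep_config("oracle", "threshold", 0.5, "ge"),
       allpath = vep_config("allpath", "threshold", 0.5, "ge"),
       noisy = vep_config("noisy", "threshold", 0.5, "ge"))
}
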