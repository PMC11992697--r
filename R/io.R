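#' Read a per-residue disorder score track file
#'
#' Parses the canonical three-column track dialect (protein accession,
#' 1-based residue position, score) as emitted by disorder predictors after
#' post-processing. The file must be tab-separated with a header row; the
#' first three columns are used regardless of their names.
#'
#' @param path Path to a tab-separated file.
#' @param tool_id Identifier of the tool that produced the scores (e.g.
#'   `"metapredict"`); recorded in the returned table.
#' @return A `data.frame` with columns `protein_id`, `tool_id`, `position`,
#'   `score`, ordered by protein id then position. Positions within each
#'   protein are validated to be exactly `1..length` with finite scores.
#' @export
read_score_track <- function(path, tool_id) {
  stopifnot(is.character(path), length(path) == 1L)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) < 3L) {
    stop("score track file must have at least 3 columns: ", path)
  }
  raw <- raw[, 1:3]
  names(raw) <- c("protein_id", "position", "score")
  pos <- suppressWarnings(as.numeric(raw$position))
  if (anyNA(pos) || any(pos != as.integer(pos)) || any(pos < 1)) {
    bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)[1L]
    stop("invalid residue position at data line ", bad, " of ", path)
  }
  score <- suppressWarnings(as.numeric(raw$score))
  if (anyNA(score) || any(!is.finite(score))) {
    bad <- which(is.na(score) | !is.finite(score))[1L]
    stop("non-numeric or non-finite score at data line ", bad, " of ", path)
  }
  df <- data.frame(protein_id = raw$protein_id, tool_id = tool_id,
                   position = as.integer(pos), score = score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein_id, df$position), , drop = FALSE]
  rownames(df) <- NULL
  validate_score_track(df)
  df
}

#' Validate a score track table
#'
#' Checks the track invariants: within every protein x tool the positions
#' form exactly `1..length` with no gaps or duplicates, and all scores are
#' finite.
#'
#' @param track A track `data.frame` (see [read_score_track()]).
#' @return The input, invisibly, on success.
#' @export
validate_score_track <- function(track) {
  stopifnot(all(c("protein_id", "tool_id", "position", "score") %in%
                  names(track)))
  if (any(!is.finite(track$score))) stop("score track contains non-finite scores")
  key <- paste(track$protein_id, track$tool_id, sep = "\r")
  for (k in unique(key)) {
    pos <- sort(track$position[key == k])
    expect <- seq_len(length(pos))
    if (!identical(as.integer(pos), as.integer(expect))) {
      miss <- setdiff(expect, pos)
      id <- sub("\r.*$", "", k)
      if (length(miss)) {
        stop("protein ", id, ": missing position ", miss[1L])
      }
      stop("protein ", id, ": duplicated or out-of-range positions")
    }
  }
  invisible(track)
}

#' Extract per-residue pLDDT from AlphaFold PDB files
#'
#' AlphaFold stores its per-residue confidence (pLDDT, 0-100) in the
#' B-factor field of its PDB outputs. This reads one or more PDB fragment
#' files for the same protein, takes the B-factor of each CA atom, and
#' assembles a single score track indexed by residue number. Long proteins
#' are distributed as several overlapping fragment models; fragments may
#' repeat a residue only if they agree on its value.
#'
#' @param paths Character vector of PDB file paths (one or more fragments).
#' @param protein_id Protein identifier for the resulting track.
#' @return A track `data.frame` (`protein_id`, `tool_id = "plddt"`,
#'   `position`, `score`).
#' @export
extract_plddt <- function(paths, protein_id) {
  stopifnot(length(paths) >= 1L)
  resno <- integer(0)
  bval <- numeric(0)
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, verbose = FALSE)
    atoms <- pdb$atom
    all_res <- unique(atoms$resno)
    ca <- atoms[atoms$elety == "CA", , drop = FALSE]
    no_ca <- setdiff(all_res, ca$resno)
    if (length(no_ca)) {
      stop("residue ", no_ca[1L], " in ", p, " has no CA atom")
    }
    if (anyDuplicated(ca$resno)) stop("duplicated CA records in ", p)
    resno <- c(resno, ca$resno)
    bval <- c(bval, ca$b)
  }
  if (anyDuplicated(resno)) {
    for (r in unique(resno[duplicated(resno)])) {
      v <- unique(bval[resno == r])
      if (length(v) > 1L) {
        stop("residue ", r, " appears in multiple fragments with ",
             "conflicting pLDDT values (", paste(v, collapse = ", "), ")")
      }
    }
    keep <- !duplicated(resno)
    resno <- resno[keep]
    bval <- bval[keep]
  }
  o <- order(resno)
  df <- data.frame(protein_id = protein_id, tool_id = "plddt",
                   position = as.integer(resno[o]), score = bval[o],
                   stringsAsFactors = FALSE)
  validate_score_track(df)
  df
}

# 20 standard amino acids; X allowed for unknown residues
.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A `data.frame` with columns `protein_id` (first whitespace-
#'   delimited token of the header), `sequence` and `length`. Duplicate ids
#'   or characters outside the 20 standard amino acids plus X are errors.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate protein id in FASTA: ", ids[duplicated(ids)][1L])
  }
  seqs <- as.character(ss)
  ok <- grepl(paste0("^[", paste(c(.aa_alphabet, "X"), collapse = ""), "]+$"),
              seqs)
  if (!all(ok)) {
    stop("sequence for ", ids[!ok][1L],
         " contains characters outside the amino-acid alphabet")
  }
  data.frame(protein_id = ids, sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Read a variant table
#'
#' Reads a simplified dbNSFP-style TSV of missense variants: one row per
#' variant with protein id, 1-based residue position, reference and
#' alternate amino acid, a clinical label, and one column per VEP. Score
#' columns are numeric; categorical VEP columns (e.g. an
#' AlphaMissense-style benign/ambiguous/pathogenic call) are character.
#' Empty cells and `"."` are read as missing.
#'
#' @param path Path to a tab-separated variant file with header.
#' @param vep_cols Character vector of numeric VEP score column names
#'   expected in the file.
#' @param category_cols Character vector of categorical VEP column names
#'   (default none).
#' @param strict If `TRUE` (default), a `vep_cols`/`category_cols` entry
#'   absent from the file is an error.
#' @return A `data.frame` with columns `protein_id`, `position`, `ref_aa`,
#'   `alt_aa`, `label` (`"PATHOGENIC"`/`"BENIGN"`) plus the declared VEP
#'   columns. Rows with `ref_aa == alt_aa` are rejected.
#' @export
read_variants <- function(path, vep_cols = character(0),
                          category_cols = character(0), strict = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           na.strings = c("", "."), check.names = FALSE)
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "label")
  if (!all(need %in% names(raw))) {
    stop("variant table must contain columns: ", paste(need, collapse = ", "))
  }
  missing_cols <- setdiff(c(vep_cols, category_cols), names(raw))
  if (length(missing_cols) && strict) {
    stop("declared VEP column not in file: ", missing_cols[1L])
  }
  df <- data.frame(protein_id = raw$protein_id,
                   position = as.integer(raw$position),
                   ref_aa = raw$ref_aa, alt_aa = raw$alt_aa,
                   label = toupper(raw$label), stringsAsFactors = FALSE)
  if (anyNA(df$position) || any(df$position < 1)) {
    stop("invalid variant position (must be a 1-based integer)")
  }
  if (!all(df$label %in% c("PATHOGENIC", "BENIGN"))) {
    stop("variant labels must be PATHOGENIC or BENIGN")
  }
  if (any(df$ref_aa == df$alt_aa)) {
    bad <- which(df$ref_aa == df$alt_aa)[1L]
    stop("variant row ", bad, ": ref_aa equals alt_aa")
  }
  for (v in intersect(vep_cols, names(raw))) {
    df[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
    bad_num <- !is.na(raw[[v]]) & is.na(df[[v]])
    if (any(bad_num)) {
      stop("non-numeric score in column ", v, " at row ", which(bad_num)[1L])
    }
  }
  for (v in intersect(category_cols, names(raw))) df[[v]] <- raw[[v]]
  df
}

#' Write a result table as TSV
#'
#' All writers in the package emit tab-separated UTF-8 with a header row and
#' the column order of the input; missing values are written as empty cells.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path Path to the file.
#' @return A `data.frame` with empty cells as `NA`.
#' @export
read_table_back <- function(path) {
  utils::read.delim(path, header = TRUE, na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
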