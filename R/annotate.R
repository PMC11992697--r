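#' Distance from the initiator methionine to the second methionine
#'
#' For a sequence starting with M, returns the 1-based position of the next
#' methionine minus one (so `"MAM"` gives 2 and `"MM"` gives 1); `NA` when
#' the sequence has no methionine after position 1. The distance is a proxy
#' for rescue of start-loss variants by alternative initiation at a
#' downstream AUG.
#'
#' @param sequence Amino-acid string.
#' @return Positive integer distance, or `NA_integer_`.
#' @export
second_met_distance <- function(sequence) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  if (substr(sequence, 1L, 1L) != "M") {
    warning("sequence does not start with M; second-Met distance undefined")
    return(NA_integer_)
  }
  rest <- substring(sequence, 2L)
  hit <- regexpr("M", rest, fixed = TRUE)
  if (hit < 0L) return(NA_integer_)
  as.integer(hit)  # position in `rest` = (1-based pos in full seq) - 1
}

#' Annotate variants with disorder context and start-Met attributes
#'
#' Joins each variant to, per disorder tool, the per-residue disordered flag
#' at its position and the positional group of the covering retained IDR
#' segment (`"ORDERED"` when no retained segment covers the position -- note
#' a residue can be disordered per-residue yet `ORDERED`-group when its run
#' is shorter than the minimum IDR length). Adds `is_nmet` (position 1 with
#' reference M) and the protein's `second_met_distance`.
#'
#' @param variants Variant `data.frame` (see [read_variants()]).
#' @param masks Named list of mask `data.frame`s (one per tool), or a single
#'   combined mask table.
#' @param segments Named list (or combined table) of *classified* segments,
#'   same tools as `masks`.
#' @param proteins Protein `data.frame` with `protein_id`, `sequence`,
#'   `length`; used for bounds/reference checks and second-Met distances.
#' @param strict If `TRUE`, a reference amino acid that contradicts the
#'   sequence is an error; otherwise a warning.
#' @return The variant table with, per tool, `<tool>_disordered` and
#'   `<tool>_group` columns, plus `is_nmet` and `second_met_distance`.
#' @export
annotate_variants <- function(variants, masks, segments, proteins,
                              strict = TRUE) {
  if (is.data.frame(masks)) masks <- split(masks, masks$tool_id)
  if (is.data.frame(segments)) {
    segments <- split(segments, segments$tool_id)
  }
  plen <- stats::setNames(proteins$length, proteins$protein_id)
  pseq <- stats::setNames(proteins$sequence, proteins$protein_id)
  unknown <- setdiff(unique(variants$protein_id), names(plen))
  if (length(unknown)) stop("variant protein not in cohort: ", unknown[1L])
  over <- variants$position > plen[variants$protein_id]
  if (any(over)) {
    stop("variant at position ", variants$position[which(over)[1L]],
         " beyond length of protein ", variants$protein_id[which(over)[1L]])
  }
  seq_aa <- substr(pseq[variants$protein_id], variants$position,
                   variants$position)
  mism <- seq_aa != variants$ref_aa & seq_aa != "X"
  if (any(mism)) {
    msg <- paste0("reference mismatch for ",
                  variants$protein_id[which(mism)[1L]], " position ",
                  variants$position[which(mism)[1L]])
    if (strict) stop(msg) else warning(msg)
  }

  out <- variants
  vkey <- paste(variants$protein_id, variants$position, sep = "\r")
  for (tool in names(masks)) {
    m <- masks[[tool]]
    mkey <- paste(m$protein_id, m$position, sep = "\r")
    hit <- match(vkey, mkey)
    if (anyNA(hit)) {
      stop("no ", tool, " track value for variant at ",
           variants$protein_id[which(is.na(hit))[1L]], ":",
           variants$position[which(is.na(hit))[1L]])
    }
    out[[paste0(tool, "_disordered")]] <- m$disordered[hit]
    seg <- segments[[tool]]
    grp <- rep("ORDERED", nrow(out))
    if (!is.null(seg) && nrow(seg)) {
      for (i in seq_len(nrow(seg))) {
        sel <- variants$protein_id == seg$protein_id[i] &
          variants$position >= seg$start[i] & variants$position <= seg$end[i]
        grp[sel] <- seg$group[i]
      }
    }
    out[[paste0(tool, "_group")]] <- grp
  }
  out$is_nmet <- variants$position == 1L & variants$ref_aa == "M"
  smd <- vapply(pseq, second_met_distance, integer(1))
  out$second_met_distance <- unname(smd[variants$protein_id])
  out
}

#' Split annotated variants into start-Met and main benchmark sets
#'
#' Variants at the initiator methionine are benchmarked separately from all
#' other variants; this partitions an annotated table by `is_nmet`.
#'
#' @param annotated Output of [annotate_variants()].
#' @return A list with elements `nmet` and `main`; a disjoint partition of
#'   the input rows.
#' @export
split_nmet <- function(annotated) {
  stopifnot("is_nmet" %in% names(annotated))
  list(nmet = annotated[annotated$is_nmet, , drop = FALSE],
       main = annotated[!annotated$is_nmet, , drop = FALSE])
}
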