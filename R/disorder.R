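#' Per-tool disorder calling configuration
#'
#' Bundles the threshold dialect and smoothing settings used to turn one
#' tool's raw per-residue scores into disorder calls.
#'
#' @param tool_id Tool identifier.
#' @param threshold Score threshold on the tool's native scale.
#' @param direction One of `"gt"` (disordered if score > threshold),
#'   `"ge"` (>=) or `"le"` (<=, for inverted scales such as pLDDT).
#' @param smoothing Logical; apply Savitzky-Golay smoothing before
#'   thresholding.
#' @param smoothing_window Odd window width in residues (default 9).
#' @param smoothing_degree Polynomial degree (default 3; must be <
#'   `smoothing_window`).
#' @param min_idr_length Minimum segment length retained by
#'   [segment_idrs()] (default 10).
#' @return A `tool_config` list.
#' @export
tool_config <- function(tool_id, threshold, direction = c("gt", "ge", "le"),
                        smoothing = FALSE, smoothing_window = 9L,
                        smoothing_degree = 3L, min_idr_length = 10L) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            smoothing_window %% 2 == 1, smoothing_window > 0,
            smoothing_degree >= 0, smoothing_degree < smoothing_window,
            min_idr_length >= 1)
  structure(list(tool_id = tool_id, threshold = threshold,
                 direction = direction, smoothing = smoothing,
                 smoothing_window = as.integer(smoothing_window),
                 smoothing_degree = as.integer(smoothing_degree),
                 min_idr_length = as.integer(min_idr_length)),
            class = "tool_config")
}

#' Default disorder-tool panel
#'
#' The five-tool panel with each tool's recommended threshold on its native
#' scale: AIUPred and metapredict call a residue disordered above 0.5,
#' AlphaFold2 pLDDT at or below 70, AlphaFold2-RSA at or above 0.581 and
#' flDPnn at or above 0.3. Savitzky-Golay smoothing (window 9, degree 3) is
#' applied before thresholding for AIUPred and flDPnn only; the other tools
#' threshold raw scores.
#'
#' @return Named list of [tool_config()] objects.
#' @export
default_tool_configs <- function() {
  list(
    aiupred     = tool_config("aiupred", 0.5, "gt", smoothing = TRUE),
    plddt       = tool_config("plddt", 70, "le"),
    metapredict = tool_config("metapredict", 0.5, "gt"),
    af2rsa      = tool_config("af2rsa", 0.581, "ge"),
    fldpnn      = tool_config("fldpnn", 0.3, "ge", smoothing = TRUE)
  )
}

#' Savitzky-Golay smoothing of a score vector
#'
#' Least-squares polynomial smoothing: each interior value is replaced by the
#' centre of a degree-`degree` polynomial fit over the surrounding window.
#' At the edges the first/last full window's polynomial is evaluated at the
#' edge positions, so any signal that is itself a polynomial of degree
#' <= `degree` is reproduced exactly, edges included. Vectors shorter than
#' the window are returned unchanged.
#'
#' @param scores Numeric vector.
#' @param window Odd window width (default 9).
#' @param degree Polynomial degree (default 3), must be < `window`.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_scores <- function(scores, window = 9L, degree = 3L) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (degree >= window) stop("smoothing degree must be smaller than the window")
  if (length(scores) < window) return(scores)
  as.numeric(signal::sgolayfilt(scores, p = degree, n = window))
}

#' Smooth every protein of a score track table
#'
#' @param track Track `data.frame` (see [read_score_track()]).
#' @param window,degree Savitzky-Golay parameters, as in [smooth_scores()].
#' @return The track with smoothed `score` values.
#' @export
smooth_track <- function(track, window = 9L, degree = 3L) {
  track <- track[order(track$protein_id, track$position), , drop = FALSE]
  track$score <- stats::ave(track$score, track$protein_id,
                            FUN = function(s) smooth_scores(s, window, degree))
  rownames(track) <- NULL
  track
}

#' Call per-residue disorder from a score track
#'
#' Applies the tool's threshold (to the smoothed track when the
#' configuration enables smoothing, else to the raw scores) and returns a
#' per-residue disorder mask.
#'
#' @param track Track `data.frame` for one tool.
#' @param cfg A [tool_config()].
#' @return A mask `data.frame`: `protein_id`, `tool_id`, `position`,
#'   `disordered` (logical).
#' @export
call_disorder <- function(track, cfg) {
  stopifnot(inherits(cfg, "tool_config"))
  if (cfg$smoothing) {
    track <- smooth_track(track, cfg$smoothing_window, cfg$smoothing_degree)
  }
  flag <- switch(cfg$direction,
                 gt = track$score > cfg$threshold,
                 ge = track$score >= cfg$threshold,
                 le = track$score <= cfg$threshold)
  data.frame(protein_id = track$protein_id, tool_id = cfg$tool_id,
             position = track$position, disordered = flag,
             stringsAsFactors = FALSE)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end)
.runs_of <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Segment a disorder mask into IDRs
#'
#' Concatenates maximal runs of consecutive disordered residues into
#' segments and drops segments shorter than `min_idr_length` residues
#' (default 10, the conventional minimum IDR length).
#'
#' @param mask Mask `data.frame` from [call_disorder()].
#' @param min_idr_length Minimum retained segment length.
#' @return A `data.frame` (`protein_id`, `tool_id`, `start`, `end`), 1-based
#'   inclusive coordinates, sorted by protein then start.
#' @export
segment_idrs <- function(mask, min_idr_length = 10L) {
  stopifnot(min_idr_length >= 1)
  mask <- mask[order(mask$protein_id, mask$position), , drop = FALSE]
  out <- lapply(split(mask, mask$protein_id), function(m) {
    seg <- .runs_of(m$disordered)
    seg <- seg[seg$end - seg$start + 1L >= min_idr_length, , drop = FALSE]
    if (nrow(seg) == 0L) return(NULL)
    data.frame(protein_id = m$protein_id[1L], tool_id = m$tool_id[1L],
               start = seg$start, end = seg$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), tool_id = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Classify an IDR segment by its position in the protein
#'
#' A segment covering the whole protein marks an intrinsically disordered
#' protein (IDP); otherwise a segment starting at residue 1 is N-terminal,
#' one ending at the last residue is C-terminal, and anything else lies
#' between domains. IDP takes precedence over the terminal labels.
#'
#' @param start,end 1-based inclusive segment coordinates.
#' @param protein_length Protein length in residues.
#' @return One of `"IDP"`, `"NTERM"`, `"CTERM"`, `"BETWEEN"`.
#' @export
classify_segment <- function(start, end, protein_length) {
  if (start < 1 || end > protein_length || start > end) {
    stop("segment [", start, ",", end, "] outside protein of length ",
         protein_length)
  }
  if (start == 1 && end == protein_length) return("IDP")
  if (start == 1) return("NTERM")
  if (end == protein_length) return("CTERM")
  "BETWEEN"
}

#' Classify all segments of a segment table
#'
#' @param segments Segment `data.frame` from [segment_idrs()].
#' @param proteins Protein `data.frame` with `protein_id` and `length`
#'   (see [read_fasta()]), or a track/mask table from which per-protein
#'   lengths can be taken.
#' @return `segments` with an added `group` column.
#' @export
classify_segments <- function(segments, proteins) {
  len <- stats::setNames(proteins$length, proteins$protein_id)
  missing <- setdiff(unique(segments$protein_id), names(len))
  if (length(missing)) stop("no protein length for ", missing[1L])
  segments$group <- vapply(seq_len(nrow(segments)), function(i) {
    classify_segment(segments$start[i], segments$end[i],
                     len[[segments$protein_id[i]]])
  }, character(1))
  segments
}

#' Frequencies of multi-tool disorder call combinations
#'
#' Tabulates, over all residues covered by every tool, the frequency of each
#' ordered/disordered pattern across tools (for k tools, up to 2^k
#' patterns).
#'
#' @param masks A list of mask `data.frame`s (one per tool) or a single
#'   combined mask table; all tools must cover identical (protein,
#'   position) sets.
#' @param min_frequency Patterns below this fraction are dropped from the
#'   output (default 0, keep all).
#' @return A `data.frame` with one 0/1 column per tool, a `count` and a
#'   `frequency` column (fractions summing to 1 before filtering), sorted by
#'   decreasing frequency.
#' @export
combination_frequencies <- function(masks, min_frequency = 0) {
  if (is.data.frame(masks)) masks <- split(masks, masks$tool_id)
  tools <- vapply(masks, function(m) m$tool_id[1L], character(1))
  key <- function(m) paste(m$protein_id, m$position, sep = "\r")
  ref <- sort(key(masks[[1L]]))
  for (m in masks[-1L]) {
    if (!identical(sort(key(m)), ref)) {
      stop("tools cover different residue sets; cannot tabulate combinations")
    }
  }
  flags <- vapply(masks, function(m) {
    m <- m[order(m$protein_id, m$position), ]
    m$disordered
  }, logical(length(ref)))
  colnames(flags) <- tools
  pattern <- apply(flags, 1L, function(x) paste(as.integer(x), collapse = ""))
  tab <- table(pattern)
  pat_mat <- t(vapply(names(tab),
                      function(p) as.integer(strsplit(p, "")[[1L]]),
                      integer(length(tools))))
  colnames(pat_mat) <- tools
  out <- data.frame(pat_mat, count = as.integer(tab),
                    frequency = as.integer(tab) / length(pattern),
                    check.names = FALSE)
  out <- out[order(-out$frequency), , drop = FALSE]
  rownames(out) <- NULL
  out[out$frequency >= min_frequency, , drop = FALSE]
}

#' Fraction of disordered residues outside retained IDRs
#'
#' The two disorder notions of the pipeline -- a per-residue disordered flag
#' and membership in a retained (>= minimum length) IDR segment -- almost
#' coincide in practice; this computes the fraction of disordered residues
#' that fall outside every retained segment, the quantity on which that
#' near-equivalence is judged.
#'
#' @param mask Mask `data.frame` for one tool.
#' @param segments Retained segments for the same tool (from
#'   [segment_idrs()]).
#' @return A fraction in `[0, 1]`; `NaN` when the mask has no disordered
#'   residue.
#' @export
idr_containment_fraction <- function(mask, segments) {
  dis <- mask[mask$disordered, , drop = FALSE]
  if (nrow(dis) == 0L) return(NaN)
  inside <- logical(nrow(dis))
  for (pid in unique(dis$protein_id)) {
    seg <- segments[segments$protein_id == pid, , drop = FALSE]
    sel <- dis$protein_id == pid
    if (nrow(seg) == 0L) next
    pos <- dis$position[sel]
    inside[sel] <- vapply(pos, function(p) any(p >= seg$start & p <= seg$end),
                          logical(1))
  }
  mean(!inside)
}

#' Export IDR segments as BED-like records
#'
#' The only place the package leaves 1-based inclusive coordinates: the
#' exported table uses half-open 0-based `start`/`end` in the BED
#' convention, which is stated in the column names.
#'
#' @param segments Classified segment table (see [classify_segments()]).
#' @return A `data.frame` with `protein_id`, `start0` (0-based),
#'   `end` (exclusive), `group`, `tool_id`.
#' @export
segments_to_bed <- function(segments) {
  data.frame(protein_id = segments$protein_id,
             start0 = segments$start - 1L, end = segments$end,
             group = segments$group, tool_id = segments$tool_id,
             stringsAsFactors = FALSE)
}
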