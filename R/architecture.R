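# Group geometry: nt strictly between the -10 hexamer and the downstream
# DnaA box (g_down) and the upstream box (g_up). The three promoter-bearing
# architectures differ only in how the promoter sits between the two boxes;
# the box-to-box distance (g_up + 6 + g_down = 24 nt) is invariant.
GROUP_GAPS <- list(I = c(g_down = 16L, g_up = 2L),
                   II = c(g_down = 14L, g_up = 4L),
                   III = c(g_down = 11L, g_up = 7L))

# search windows for a flanking box, in nt strictly between box edge and
# the -10; wide enough to contain every defined group with margin
UP_GAP_MAX <- 12L
DOWN_GAP_MAX <- 20L

#' Measure the gaps between a promoter's -10 and its flanking DnaA boxes
#'
#' Looks for the upstream box (on the -35 side of the -10, i.e. within
#' the spacer region, nearest edge 0-12 nt from the -10) and the
#' downstream box (on the opposite side, nearest edge 0-20 nt away).
#' On each side the highest-similarity box wins; similarity ties break
#' toward the box nearest the -10, then toward `"+"` orientation. Box
#' orientation is otherwise ignored: the conserved quantity is spacing,
#' not orientation.
#'
#' @param promoter one promoter candidate — a single row of the data
#'   frame returned by [scan_promoters()] (or any list with `m10_start`).
#' @param boxes DnaA-box hits from [find_dnaa_boxes()] on the same region.
#' @return `NULL` when either flank lacks a qualifying box; otherwise a
#'   list with `g_up`, `g_down`, `interbox_gap` (nt strictly between the
#'   facing edges of the two boxes) and the selected `upstream_box` /
#'   `downstream_box` rows.
#' @examples
#' p <- scan_params()
#' seq <- paste0(strrep("G", 20), "TACACA", "GCTAG", p$box_consensus,
#'               "CC", "TATAAT", strrep("C", 16), p$box_consensus,
#'               strrep("G", 20))
#' cand <- scan_promoters(seq, p)
#' measure_gaps(cand[1, ], find_dnaa_boxes(seq, p))[c("g_up", "g_down",
#'                                                    "interbox_gap")]
#' @export
measure_gaps <- function(promoter, boxes) {
  m10s <- as.integer(promoter$m10_start)
  m10e <- m10s + 6L
  if (is.null(boxes) || nrow(boxes) == 0L) return(NULL)
  up <- boxes[boxes$end <= m10s & m10s - boxes$end <= UP_GAP_MAX, , drop = FALSE]
  dn <- boxes[boxes$start >= m10e & boxes$start - m10e <= DOWN_GAP_MAX, , drop = FALSE]
  if (nrow(up) == 0L || nrow(dn) == 0L) return(NULL)
  pick <- function(side, gap) {
    side <- side[order(-side$matches, gap, side$orientation), , drop = FALSE]
    side[1L, , drop = FALSE]
  }
  up <- pick(up, m10s - up$end)
  dn <- pick(dn, dn$start - m10e)
  list(g_up = m10s - up$end,
       g_down = dn$start - m10e,
       interbox_gap = dn$start - up$end,
       upstream_box = up,
       downstream_box = dn)
}

#' Classify a locus into the Group I-IV promoter/DnaA-box architectures
#'
#' Walks the promoter candidates in their sorted order and fixes the call
#' on the first candidate with a 16-nt spacer whose measured gaps to the
#' flanking boxes match a group pattern: (g_down, g_up) of (16, 2) for
#' Group I, (14, 4) for Group II, (11, 7) for Group III. Loci with at
#' least one candidate but no matching geometry are `unclassified` (the
#' top candidate and its best-effort gaps are recorded); loci with no
#' candidate at all are Group IV, the promoterless architecture.
#'
#' @param promoters output of [scan_promoters()] on one region.
#' @param boxes output of [find_dnaa_boxes()] on the same region with the
#'   same parameters.
#' @param genome_id identifier carried into the call (optional).
#' @param gap_tolerance permitted deviation (nt) of each measured gap
#'   from a group's pattern. Default 0: a 2-bp shift distinguishes Groups
#'   I and II, so any tolerance merges defined groups — non-zero values
#'   are for exploratory scans only.
#' @return An object of class `arch_call`: a list with `genome_id`,
#'   `group` (`"I"`, `"II"`, `"III"`, `"IV"` or `"unclassified"`),
#'   `promoter`, `upstream_box`, `downstream_box`, `g_up`, `g_down` and
#'   `interbox_gap` (the latter `NA` where not measurable).
#' @export
classify_locus <- function(promoters, boxes, genome_id = NA_character_,
                           gap_tolerance = 0L) {
  gap_tolerance <- as.integer(gap_tolerance)
  blank <- structure(
    list(genome_id = genome_id, group = "IV", promoter = NULL,
         upstream_box = NULL, downstream_box = NULL,
         g_up = NA_integer_, g_down = NA_integer_,
         interbox_gap = NA_integer_),
    class = "arch_call")
  if (is.null(promoters) || nrow(promoters) == 0L) {
    return(blank)
  }
  for (i in seq_len(nrow(promoters))) {
    cand <- promoters[i, , drop = FALSE]
    if (cand$spacer != 16L) next
    gaps <- measure_gaps(cand, boxes)
    if (is.null(gaps)) next
    for (grp in names(GROUP_GAPS)) {
      pat <- GROUP_GAPS[[grp]]
      if (abs(gaps$g_down - pat["g_down"]) <= gap_tolerance &&
          abs(gaps$g_up - pat["g_up"]) <= gap_tolerance) {
        return(structure(
          list(genome_id = genome_id, group = grp, promoter = cand,
               upstream_box = gaps$upstream_box,
               downstream_box = gaps$downstream_box,
               g_up = gaps$g_up, g_down = gaps$g_down,
               interbox_gap = gaps$interbox_gap),
          class = "arch_call"))
      }
    }
  }
  # promoter-bearing but no defined geometry: record the top candidate
  # and whatever gaps are measurable
  top <- promoters[1L, , drop = FALSE]
  gaps <- measure_gaps(top, boxes)
  out <- blank
  out$group <- "unclassified"
  out$promoter <- top
  if (!is.null(gaps)) {
    out$upstream_box <- gaps$upstream_box
    out$downstream_box <- gaps$downstream_box
    out$g_up <- gaps$g_up
    out$g_down <- gaps$g_down
    out$interbox_gap <- gaps$interbox_gap
  }
  out
}

#' @export
print.arch_call <- function(x, ...) {
  cat(sprintf("<arch_call> %s: Group %s\n",
              ifelse(is.na(x$genome_id), "(unnamed)", x$genome_id), x$group))
  if (!is.null(x$promoter)) {
    cat(sprintf("  promoter: -35 %s (%d mm) ..%d nt.. -10 %s (%d mm)\n",
                x$promoter$m35_seq, x$promoter$mm35, x$promoter$spacer,
                x$promoter$m10_seq, x$promoter$mm10))
  }
  if (!is.na(x$interbox_gap)) {
    cat(sprintf("  gaps: %d nt to upstream box, %d nt to downstream box, %d nt between boxes\n",
                x$g_up, x$g_down, x$interbox_gap))
  }
  invisible(x)
}

#' @rdname classify_locus
#' @param x an `arch_call`.
#' @param ... unused.
#' @param row.names,optional passed through to the data frame method
#'   contract (unused).
#' @export
as.data.frame.arch_call <- function(x, row.names = NULL, optional = FALSE, ...) {
  p <- x$promoter
  ub <- x$upstream_box
  db <- x$downstream_box
  data.frame(
    genome_id = x$genome_id,
    group = x$group,
    m10_start = if (is.null(p)) NA_integer_ else p$m10_start,
    m10_seq = if (is.null(p)) NA_character_ else p$m10_seq,
    mm10 = if (is.null(p)) NA_integer_ else p$mm10,
    m35_start = if (is.null(p)) NA_integer_ else p$m35_start,
    m35_seq = if (is.null(p)) NA_character_ else p$m35_seq,
    mm35 = if (is.null(p)) NA_integer_ else p$mm35,
    spacer = if (is.null(p)) NA_integer_ else p$spacer,
    predicted_tss = if (is.null(p)) NA_integer_ else p$predicted_tss,
    up_box_start = if (is.null(ub)) NA_integer_ else ub$start,
    up_box_seq = if (is.null(ub)) NA_character_ else ub$seq,
    up_box_matches = if (is.null(ub)) NA_integer_ else ub$matches,
    down_box_start = if (is.null(db)) NA_integer_ else db$start,
    down_box_seq = if (is.null(db)) NA_character_ else db$seq,
    down_box_matches = if (is.null(db)) NA_integer_ else db$matches,
    g_up = x$g_up,
    g_down = x$g_down,
    interbox_gap = x$interbox_gap,
    stringsAsFactors = FALSE)
}
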