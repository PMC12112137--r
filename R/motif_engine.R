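#' Count Hamming mismatches between two equal-length sequences
#'
#' Position-wise mismatch count against a consensus. `N` counts as a
#' mismatch at its position regardless of the other character, so masked
#' bases can never help a candidate.
#'
#' @param observed,consensus equal-length nucleotide strings over
#'   `{A,C,G,T,N}` (case-insensitive).
#' @return Non-negative integer mismatch count.
#' @examples
#' count_mismatches("TATAGT", "TATAAT")  # 1
#' count_mismatches("TACACA", "TTGACA")  # 2
#' @export
count_mismatches <- function(observed, consensus) {
  observed <- .check_dna(observed, "observed")
  consensus <- .check_dna(consensus, "consensus")
  if (nchar(observed) != nchar(consensus)) {
    stop(sprintf("sequences differ in length (%d vs %d)",
                 nchar(observed), nchar(consensus)), call. = FALSE)
  }
  o <- strsplit(observed, "", fixed = TRUE)[[1]]
  k <- strsplit(consensus, "", fixed = TRUE)[[1]]
  sum(!.match_vec(o, k))
}

.region_seq <- function(region) {
  if (inherits(region, "target_region")) region$sequence
  else .check_dna(region, "region")
}

#' Find DnaA-box matches on both orientations of a region
#'
#' Slides a window the width of the box consensus over the region and
#' reports every placement, on either orientation, whose match count to
#' the consensus reaches `min_box_matches`. Similarity is the fraction of
#' matching positions; overlapping hits are all kept. Orientation `"+"`
#' means the consensus matched the region's own strand, `"-"` that it
#' matched the reverse complement of the window.
#'
#' @param region a `target_region` or plain nucleotide string.
#' @param params a [scan_params()] object.
#' @return A data frame with one row per hit — columns `start`, `end`
#'   (0-based half-open region offsets), `orientation`, `seq` (the window
#'   as written on the region strand), `matches` and `similarity` —
#'   sorted by `start`, then orientation (`"+"` first). Regions shorter
#'   than the box return zero rows.
#' @examples
#' p <- scan_params()
#' hits <- find_dnaa_boxes(paste0(strrep("G", 10), p$box_consensus,
#'                                strrep("G", 10)), p)
#' hits[, c("start", "orientation", "matches")]
#' @export
find_dnaa_boxes <- function(region, params = scan_params()) {
  seq <- .region_seq(region)
  w <- params$box_length
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- data.frame(start = integer(0), end = integer(0),
                      orientation = character(0), seq = character(0),
                      matches = integer(0), similarity = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  cons <- strsplit(params$box_consensus, "", fixed = TRUE)[[1]]
  rc_cons <- strsplit(.revcomp(params$box_consensus), "", fixed = TRUE)[[1]]
  fwd <- .window_matches(chars, cons)
  # revcomp(window) vs consensus == window vs revcomp(consensus)
  rev <- .window_matches(chars, rc_cons)
  starts <- 0:(n - w)
  keep_f <- fwd >= params$min_box_matches
  keep_r <- rev >= params$min_box_matches
  hits <- rbind(
    data.frame(start = starts[keep_f], orientation = rep("+", sum(keep_f)),
               matches = fwd[keep_f], stringsAsFactors = FALSE),
    data.frame(start = starts[keep_r], orientation = rep("-", sum(keep_r)),
               matches = rev[keep_r], stringsAsFactors = FALSE))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$start, hits$orientation), , drop = FALSE]
  hits$end <- hits$start + w
  hits$seq <- substring(seq, hits$start + 1L, hits$end)
  hits$similarity <- hits$matches / w
  rownames(hits) <- NULL
  hits[, c("start", "end", "orientation", "seq", "matches", "similarity")]
}

#' Scan a region for -35/-10 promoter element pairs
#'
#' Exhaustive enumeration of hexamer pairs on the region's own strand
#' (the strand the antisense promoter fires from) under the mismatch
#' budgets and spacer constraint in `params`. Candidates are ordered by
#' total mismatches ascending, then by distance of the spacer from 16 nt
#' (the spacing every accepted *Bacillus* antisense promoter shows), then
#' by leftmost -10 and leftmost -35; the ordering is deterministic and
#' contractual.
#'
#' @param region a `target_region` or plain nucleotide string.
#' @param params a [scan_params()] object.
#' @return A data frame with one candidate per row: `m10_start`,
#'   `m10_seq`, `mm10`, `m35_start`, `m35_seq`, `mm35`, `spacer` (nt
#'   strictly between the 3' end of the -35 and the 5' end of the -10)
#'   and `predicted_tss` (region offset). Zero rows when nothing
#'   qualifies.
#' @examples
#' seq <- paste0(strrep("G", 20), "TACACA", strrep("G", 16), "TATAAT",
#'               strrep("G", 20))
#' scan_promoters(seq)[, c("mm10", "mm35", "spacer")]
#' @export
scan_promoters <- function(region, params = scan_params()) {
  seq <- .region_seq(region)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- data.frame(m10_start = integer(0), m10_seq = character(0),
                      mm10 = integer(0), m35_start = integer(0),
                      m35_seq = character(0), mm35 = integer(0),
                      spacer = integer(0), predicted_tss = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 6L + params$spacer_range[1] + 6L) return(empty)
  mm10 <- 6L - .window_matches(chars, strsplit(params$consensus_m10, "", fixed = TRUE)[[1]])
  mm35 <- 6L - .window_matches(chars, strsplit(params$consensus_m35, "", fixed = TRUE)[[1]])
  m35_ok <- which(mm35 <= params$max_mm35) - 1L   # 0-based starts
  m10_ok <- which(mm10 <= params$max_mm10) - 1L
  if (length(m35_ok) == 0L || length(m10_ok) == 0L) return(empty)
  rows <- list()
  for (s in params$spacer_range[1]:params$spacer_range[2]) {
    m10_at <- m35_ok + 6L + s
    valid <- m10_at %in% m10_ok
    if (!any(valid)) next
    rows[[length(rows) + 1L]] <- data.frame(
      m10_start = m10_at[valid], m35_start = m35_ok[valid],
      spacer = s, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  cand <- do.call(rbind, rows)
  cand$mm10 <- mm10[cand$m10_start + 1L]
  cand$mm35 <- mm35[cand$m35_start + 1L]
  cand$m10_seq <- substring(seq, cand$m10_start + 1L, cand$m10_start + 6L)
  cand$m35_seq <- substring(seq, cand$m35_start + 1L, cand$m35_start + 6L)
  cand$predicted_tss <- cand$m10_start + 6L + params$tss_offset - 1L
  cand <- cand[order(cand$mm10 + cand$mm35, abs(cand$spacer - 16L),
                     cand$m10_start, cand$m35_start), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("m10_start", "m10_seq", "mm10", "m35_start", "m35_seq", "mm35",
           "spacer", "predicted_tss")]
}
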