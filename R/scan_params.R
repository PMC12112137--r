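#' Scan parameters for promoter and DnaA-box detection
#'
#' Bundles the consensus elements, mismatch budgets and geometric
#' constraints used by [scan_promoters()] and [find_dnaa_boxes()].
#' Defaults describe the SigA-type housekeeping promoter (consensus
#' `TATAAT` / `TTGACA`) with the loosest budgets exhibited by accepted
#' antisense-promoter candidates in *Bacillus* (-10 up to 1 mismatch,
#' -35 up to 2), a 15-18 nt spacer bracket, and the *B. subtilis* DnaA-box
#' consensus `TTATCCACA` scored by fraction of matching positions with a
#' 7-of-9 reporting floor. The box consensus is a configurable convention,
#' not a trained model.
#'
#' @param consensus_m10 -10 hexamer consensus (default `TATAAT`).
#' @param consensus_m35 -35 hexamer consensus (default `TTGACA`).
#' @param max_mm10 maximum mismatches tolerated in the -10 (default 1).
#' @param max_mm35 maximum mismatches tolerated in the -35 (default 2).
#' @param spacer_range inclusive bounds on the spacer, the number of
#'   nucleotides strictly between the 3' end of the -35 and the 5' end of
#'   the -10 (default `c(15, 18)`).
#' @param box_consensus DnaA-box consensus (default `TTATCCACA`, 9-mer).
#' @param min_box_matches minimum matching positions for a reported box
#'   hit (default 7).
#' @param tss_offset nucleotides from the 3' end of the -10 to the
#'   predicted transcription start (default 7). Affects only the reported
#'   predicted TSS, never classification.
#' @return An object of class `scan_params`.
#' @examples
#' p <- scan_params(max_mm35 = 3)
#' p$max_mm35
#' @export
scan_params <- function(consensus_m10 = "TATAAT",
                        consensus_m35 = "TTGACA",
                        max_mm10 = 1L,
                        max_mm35 = 2L,
                        spacer_range = c(15L, 18L),
                        box_consensus = "TTATCCACA",
                        min_box_matches = 7L,
                        tss_offset = 7L) {
  consensus_m10 <- .check_dna(consensus_m10, "-10 consensus")
  consensus_m35 <- .check_dna(consensus_m35, "-35 consensus")
  box_consensus <- .check_dna(box_consensus, "box consensus")
  if (nchar(consensus_m10) != 6L || nchar(consensus_m35) != 6L) {
    stop("promoter consensus elements must be hexamers", call. = FALSE)
  }
  max_mm10 <- as.integer(max_mm10)
  max_mm35 <- as.integer(max_mm35)
  if (max_mm10 < 0L || max_mm10 > 6L || max_mm35 < 0L || max_mm35 > 6L) {
    stop("mismatch budgets must lie in [0, 6]", call. = FALSE)
  }
  spacer_range <- as.integer(spacer_range)
  if (length(spacer_range) != 2L || spacer_range[1] > spacer_range[2] ||
      spacer_range[1] < 0L) {
    stop("spacer_range must be a non-empty non-negative interval", call. = FALSE)
  }
  box_length <- nchar(box_consensus)
  min_box_matches <- as.integer(min_box_matches)
  if (min_box_matches < 0L || min_box_matches > box_length) {
    stop("min_box_matches must lie in [0, box length]", call. = FALSE)
  }
  tss_offset <- as.integer(tss_offset)
  if (tss_offset < 1L) stop("tss_offset must be positive", call. = FALSE)
  structure(
    list(consensus_m10 = consensus_m10,
         consensus_m35 = consensus_m35,
         max_mm10 = max_mm10,
         max_mm35 = max_mm35,
         spacer_range = spacer_range,
         box_consensus = box_consensus,
         box_length = box_length,
         min_box_matches = min_box_matches,
         tss_offset = tss_offset),
    class = "scan_params"
  )
}

#' @export
print.scan_params <- function(x, ...) {
  cat("Promoter/DnaA-box scan parameters\n")
  cat(sprintf("  -10 consensus : %s (<= %d mismatches)\n",
              x$consensus_m10, x$max_mm10))
  cat(sprintf("  -35 consensus : %s (<= %d mismatches)\n",
              x$consensus_m35, x$max_mm35))
  cat(sprintf("  spacer        : %d-%d nt\n",
              x$spacer_range[1], x$spacer_range[2]))
  cat(sprintf("  DnaA box      : %s (>= %d/%d matches)\n",
              x$box_consensus, x$min_box_matches, x$box_length))
  cat(sprintf("  TSS offset    : %d nt past the -10\n", x$tss_offset))
  invisible(x)
}
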