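#' Describe a transcription template
#'
#' A linear template interval, a transcription start site and direction,
#' plus optional intrinsic terminators. The terminator coordinate is the
#' last transcribed base of the terminated product; `readthrough = TRUE`
#' marks a terminator that polymerase partially reads through, so longer
#' products remain possible past it.
#'
#' @param template_start,template_end template interval, 0-based half-open.
#' @param tss transcription start site coordinate (first transcribed base).
#' @param direction `"+"` (rightward) or `"-"` (leftward).
#' @param terminators `NULL`, or a data frame with columns `coord` (last
#'   transcribed base) and `readthrough` (logical), ordered by increasing
#'   distance from the TSS.
#' @return An object of class `transcription_layout`.
#' @examples
#' transcription_layout(0, 262, tss = 10, direction = "+")
#' @export
transcription_layout <- function(template_start, template_end, tss,
                                 direction = c("+", "-"),
                                 terminators = NULL) {
  direction <- match.arg(direction)
  template_start <- as.integer(template_start)
  template_end <- as.integer(template_end)
  tss <- as.integer(tss)
  if (template_start >= template_end) {
    stop("template interval must be non-empty", call. = FALSE)
  }
  if (tss < template_start || tss >= template_end) {
    stop(sprintf("tss %d outside template [%d,%d)", tss, template_start,
                 template_end), call. = FALSE)
  }
  if (!is.null(terminators)) {
    terminators <- as.data.frame(terminators, stringsAsFactors = FALSE)
    stopifnot(all(c("coord", "readthrough") %in% names(terminators)))
    terminators$coord <- as.integer(terminators$coord)
    terminators$readthrough <- as.logical(terminators$readthrough)
    downstream <- if (direction == "+") terminators$coord >= tss
                  else terminators$coord <= tss
    if (!all(downstream)) {
      stop("terminators must lie downstream of the tss in the direction of transcription",
           call. = FALSE)
    }
  }
  structure(
    list(template_start = template_start, template_end = template_end,
         tss = tss, direction = direction, terminators = terminators),
    class = "transcription_layout")
}

.isoform <- function(length, end_kind, terminator_index = NA_integer_) {
  data.frame(length = as.integer(length), end_kind = end_kind,
             terminator_index = as.integer(terminator_index),
             stringsAsFactors = FALSE)
}

#' Run-off transcript length
#'
#' Length of the product made on a linear template when polymerase runs
#' to the template edge: the number of template positions from the TSS to
#' the edge, counting both. A 262-bp template with the start 10 positions
#' in yields the 252-nt product expected of the *dnaA* promoter on its
#' run-off template.
#'
#' @param layout a [transcription_layout()] with no terminators between
#'   the TSS and the template edge.
#' @return A one-row data frame (`length`, `end_kind = "runoff"`,
#'   `terminator_index = NA`).
#' @examples
#' runoff_length(transcription_layout(0, 262, tss = 10, direction = "+"))
#' @export
runoff_length <- function(layout) {
  stopifnot(inherits(layout, "transcription_layout"))
  if (!is.null(layout$terminators) && nrow(layout$terminators) > 0L) {
    stop("template carries terminators between tss and edge; use isoform_lengths()",
         call. = FALSE)
  }
  len <- if (layout$direction == "+") layout$template_end - layout$tss
         else layout$tss - layout$template_start + 1L
  .isoform(len, "runoff")
}

#' Transcript isoform lengths on a terminator-bearing template
#'
#' One terminated isoform per terminator — its length the inclusive
#' TSS-to-terminator distance — plus a final run-off isoform only when
#' every terminator permits readthrough. A hard (non-readthrough)
#' terminator ends the enumeration: nothing longer can be made. This is
#' the arithmetic behind a promoter producing, e.g., 270- and 667-nt
#' species from one start site via a leaky terminator between them.
#'
#' @param layout a [transcription_layout()]; terminators must be sorted
#'   by increasing distance from the TSS.
#' @return A data frame of isoforms (`length`, `end_kind`,
#'   `terminator_index`), in increasing length order.
#' @examples
#' lay <- transcription_layout(0, 700, tss = 0, direction = "+",
#'   terminators = data.frame(coord = c(269, 666),
#'                            readthrough = c(TRUE, FALSE)))
#' isoform_lengths(lay)$length  # 270 667
#' @export
isoform_lengths <- function(layout) {
  stopifnot(inherits(layout, "transcription_layout"))
  term <- layout$terminators
  if (is.null(term) || nrow(term) == 0L) {
    return(runoff_length(layout))
  }
  dist <- if (layout$direction == "+") term$coord - layout$tss
          else layout$tss - term$coord
  if (is.unsorted(dist, strictly = TRUE)) {
    stop("terminators must be sorted by increasing distance from the tss",
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(term))) {
    out[[length(out) + 1L]] <- .isoform(dist[i] + 1L, "terminated", i)
    if (!term$readthrough[i]) {
      return(do.call(rbind, out))
    }
  }
  # every terminator was readthrough-permissive: the run-off species exists
  runoff <- if (layout$direction == "+") layout$template_end - layout$tss
            else layout$tss - layout$template_start + 1L
  out[[length(out) + 1L]] <- .isoform(runoff, "runoff")
  do.call(rbind, out)
}
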