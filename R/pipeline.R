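#' Scan a set of genomes for the antisense-promoter architecture
#'
#' Runs extraction, DnaA-box detection, promoter scanning and Group I-IV
#' classification over every input locus. Inputs may be a directory of
#' genome files, a vector of file paths, a list of [genome_record()]
#' objects, or a [generate_panel()] result. Multi-record GenBank files
#' contribute one locus per record. Per-genome failures (e.g. a missing
#' anchor gene) become `skipped` rows, never a fatal error; zero
#' parseable inputs is fatal. Runs are deterministic: fixed sort orders,
#' no timestamps in any data output.
#'
#' @param input directory, file paths, list of `genome_record`s, or a
#'   `synthetic_panel`.
#' @param format `"genbank"` or `"fasta+gff3"` (for file input; with
#'   `fasta+gff3`, each FASTA must sit next to an equally-named `.gff3`
#'   file, or pass `gff` explicitly for a single file).
#' @param params a [scan_params()] object.
#' @param gap_tolerance forwarded to [classify_locus()].
#' @param gff companion GFF3 path(s) for `fasta+gff3` input.
#' @param out_dir if non-`NULL`, write `calls.tsv`, `summary.tsv`,
#'   `elements.bed` (genome-frame 6-column BED) and `regions.fasta`
#'   there.
#' @return An object of class `arra_scan`: list with `calls` (one row
#'   per locus), `summary` (group tally), `regions` (the extracted
#'   `target_region`s), `elements` (genome-frame BED data frame) and
#'   `skipped`.
#' @examples
#' panel <- generate_panel(c(I = 2, IV = 1), base_seed = 3)
#' res <- scan_genomes(panel)
#' res$summary
#' @export
scan_genomes <- function(input, format = c("genbank", "fasta+gff3"),
                         params = scan_params(), gap_tolerance = 0L,
                         gff = NULL, out_dir = NULL) {
  format <- match.arg(format)
  genomes <- .collect_genomes(input, format, gff)
  if (length(genomes) == 0L) {
    stop("no parseable input genomes; supply a directory, files or records",
         call. = FALSE)
  }
  rows <- list()
  regions <- list()
  elements <- list()
  skipped <- character(0)
  for (g in genomes) {
    res <- tryCatch({
      region <- extract_target_region(g)
      boxes <- find_dnaa_boxes(region, params)
      proms <- scan_promoters(region, params)
      call <- classify_locus(proms, boxes, genome_id = g$id,
                             gap_tolerance = gap_tolerance)
      list(region = region, call = call, boxes = boxes)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- c(skipped, sprintf("%s: %s", g$id, res))
      row <- as.data.frame(structure(
        list(genome_id = g$id, group = NA_character_, promoter = NULL,
             upstream_box = NULL, downstream_box = NULL,
             g_up = NA_integer_, g_down = NA_integer_,
             interbox_gap = NA_integer_), class = "arch_call"))
      row$status <- sprintf("skipped: %s", res)
      rows[[length(rows) + 1L]] <- row
      next
    }
    row <- as.data.frame(res$call)
    row$status <- "ok"
    rows[[length(rows) + 1L]] <- row
    regions[[g$id]] <- res$region
    elements[[length(elements) + 1L]] <-
      .element_bed(res$region, res$call, res$boxes)
  }
  calls <- do.call(rbind, rows)
  calls <- calls[, c("genome_id", "status",
                     setdiff(names(calls), c("genome_id", "status")))]
  calls <- calls[order(calls$genome_id), , drop = FALSE]
  rownames(calls) <- NULL
  ok <- calls$status == "ok"
  summary <- data.frame(
    group = c("I", "II", "III", "IV", "unclassified"),
    stringsAsFactors = FALSE)
  summary$n <- vapply(summary$group,
                      function(g) sum(ok & calls$group == g, na.rm = TRUE),
                      integer(1))
  bed <- if (length(elements) > 0L) do.call(rbind, elements) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))
  bed <- bed[order(bed$chrom, bed$start, bed$name), , drop = FALSE]
  rownames(bed) <- NULL
  out <- structure(
    list(calls = calls, summary = summary,
         regions = regions[order(names(regions))],
         elements = bed, skipped = skipped, params = params),
    class = "arra_scan")
  if (!is.null(out_dir)) write_scan(out, out_dir)
  out
}

.collect_genomes <- function(input, format, gff) {
  if (inherits(input, "synthetic_panel")) return(input$genomes)
  if (inherits(input, "genome_record")) return(list(input))
  if (is.list(input)) {
    stopifnot(all(vapply(input, inherits, logical(1), "genome_record")))
    return(input)
  }
  stopifnot(is.character(input))
  paths <- input
  if (length(input) == 1L && dir.exists(input)) {
    ext <- if (format == "genbank") "\\.(gb|gbk|gbff|genbank)$" else "\\.(fa|fasta|fna)$"
    paths <- sort(list.files(input, pattern = ext, full.names = TRUE))
    if (length(paths) == 0L) {
      stop(sprintf("no %s files found in %s", format, input), call. = FALSE)
    }
  }
  recs <- list()
  for (p in paths) {
    g <- if (format == "genbank") NULL else
      if (!is.null(gff)) gff else paste0(tools::file_path_sans_ext(p), ".gff3")
    recs <- c(recs, read_genome_set(p, format = format, gff = g))
  }
  recs
}

# genome-frame BED rows for the called elements of one locus; elements
# wrapping the origin are split into two rows sharing a name
.element_bed <- function(region, call, boxes) {
  rows <- list()
  add <- function(r_start, r_end, name, score) {
    m <- region_to_genome(region, r_start, r_end)
    L <- region$genome_length
    if (m$end <= L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = region$genome_id, start = m$start, end = m$end,
        name = name, score = score, strand = m$strand,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = region$genome_id,
        start = c(m$start, 0L), end = c(L, m$end - L),
        name = name, score = score, strand = m$strand,
        stringsAsFactors = FALSE)
    }
  }
  p <- call$promoter
  if (!is.null(p)) {
    add(p$m10_start, p$m10_start + 6L, "minus10", p$mm10)
    add(p$m35_start, p$m35_start + 6L, "minus35", p$mm35)
  }
  if (nrow(boxes) > 0L) {
    for (i in seq_len(nrow(boxes))) {
      add(boxes$start[i], boxes$end[i],
          sprintf("dnaA_box_%d%s", boxes$start[i], boxes$orientation[i]),
          boxes$matches[i])
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Write the artifacts of a scan to a directory
#'
#' Emits `calls.tsv` (one row per locus), `summary.tsv` (group tally),
#' `elements.bed` (called elements in genome coordinates, 6-column BED)
#' and `regions.fasta` (extracted regions with provenance headers).
#' Output is byte-deterministic for identical inputs.
#'
#' @param x an `arra_scan` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scan <- function(x, out_dir) {
  stopifnot(inherits(x, "arra_scan"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  write_tsv(x$calls, "calls.tsv")
  write_tsv(x$summary, "summary.tsv")
  utils::write.table(x$elements, file.path(out_dir, "elements.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_region_fasta(unname(x$regions), file.path(out_dir, "regions.fasta"))
  invisible(out_dir)
}

#' @export
print.arra_scan <- function(x, ...) {
  n <- nrow(x$calls)
  cat(sprintf("<arra_scan> %d locus/loci (%d skipped)\n", n,
              length(x$skipped)))
  tally <- x$summary[x$summary$n > 0L, , drop = FALSE]
  if (nrow(tally) > 0L) {
    cat("  groups:",
        paste(sprintf("%s=%d", tally$group, tally$n), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.arra_scan <- function(object, ...) {
  cat("Antisense-promoter architecture scan\n")
  print(object$summary, row.names = FALSE)
  if (length(object$skipped) > 0L) {
    cat("skipped:\n")
    for (s in object$skipped) cat("  -", s, "\n")
  }
  invisible(object$summary)
}

#' Align extracted regions on the conserved downstream DnaA box
#'
#' Left-pads each region so every locus's downstream (anchor) DnaA box
#' begins in the same column, then right-pads to a rectangle — the
#' display convention for comparing the promoter architecture across
#' species, anchored on the box every promoter-bearing group shares.
#' Rows whose call lacks a downstream box are excluded and reported via
#' a message.
#'
#' @param regions list of `target_region`s (as in an `arra_scan`).
#' @param calls list of `arch_call`s, or an `arra_scan` calls data frame.
#' @return An object of class `aligned_block`: list with `ids`, `rows`
#'   (equal-length padded strings, gap character `-`) and
#'   `anchor_column` (0-based column of the anchor box start).
#' @export
anchor_align <- function(regions, calls) {
  if (inherits(calls, "data.frame")) {
    call_ids <- as.character(calls$genome_id)
    call_anchors <- calls$down_box_start
  } else {
    if (inherits(calls, "arch_call")) calls <- list(calls)
    call_ids <- vapply(calls, function(c) as.character(c$genome_id), character(1))
    call_anchors <- vapply(calls, function(c)
      if (is.null(c$downstream_box)) NA_integer_ else
        as.integer(c$downstream_box$start), integer(1))
  }
  if (inherits(regions, "target_region")) regions <- list(regions)
  ids <- vapply(regions, function(r)
    if (inherits(r, "target_region")) r$genome_id else NA_character_,
    character(1))
  seqs <- vapply(regions, function(r)
    if (inherits(r, "target_region")) r$sequence else as.character(r),
    character(1))
  if (anyNA(ids)) {  # bare strings: pair positionally
    stopifnot(length(seqs) == length(call_ids))
    ids <- call_ids
  }
  anchors <- call_anchors[match(ids, call_ids)]
  keep <- !is.na(anchors)
  if (any(!keep)) {
    message("anchor_align: excluding ", sum(!keep),
            " row(s) without a downstream DnaA box: ",
            paste(ids[!keep], collapse = ", "))
  }
  if (!any(keep)) {
    warning("no alignable rows (no call carries a downstream DnaA box)")
    return(structure(list(ids = character(0), rows = character(0),
                          anchor_column = NA_integer_),
                     class = "aligned_block"))
  }
  anchors <- anchors[keep]
  seqs <- seqs[keep]
  ids <- ids[keep]
  anchor_col <- max(anchors)
  padded <- vapply(seq_along(seqs), function(i) {
    paste0(strrep("-", anchor_col - anchors[i]), seqs[i])
  }, character(1))
  width <- max(nchar(padded))
  padded <- vapply(padded, function(s)
    paste0(s, strrep("-", width - nchar(s))), character(1), USE.NAMES = FALSE)
  structure(list(ids = ids, rows = padded, anchor_column = anchor_col),
            class = "aligned_block")
}

#' @export
print.aligned_block <- function(x, width = 80L, ...) {
  cat(sprintf("<aligned_block> %d row(s), anchor column %d\n",
              length(x$rows), x$anchor_column))
  if (length(x$rows) > 0L) {
    w <- max(nchar(x$ids))
    for (i in seq_along(x$rows)) {
      row <- x$rows[i]
      if (nchar(row) > width) row <- paste0(substr(row, 1, width - 3), "...")
      cat(sprintf("  %-*s %s\n", w, x$ids[i], row))
    }
  }
  invisible(x)
}

#' Write an aligned block as padded FASTA
#'
#' @param block an `aligned_block`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(block, path) {
  stopifnot(inherits(block, "aligned_block"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(block$rows)) {
    writeLines(c(paste0(">", block$ids[i]), block$rows[i]), con)
  }
  invisible(path)
}
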