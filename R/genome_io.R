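#' Construct an annotated genome record
#'
#' The in-memory unit of input: a nucleotide sequence with an identifier,
#' a circularity flag, and gene annotations. All coordinates are 0-based,
#' half-open on the forward strand.
#'
#' @param id record identifier (non-empty string).
#' @param sequence nucleotide string over `{A,C,G,T,N}` (case-insensitive,
#'   stored uppercase).
#' @param annotations data frame with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), and optionally `feature` (default `"gene"`)
#'   and `product` (default `NA`).
#' @param circular logical; whether the molecule is circular (origin wrap
#'   permitted in downstream extraction).
#' @return An object of class `genome_record`.
#' @examples
#' g <- genome_record("toy", "ACGTACGTACGTACGTACGTACGTACGTAC",
#'   data.frame(name = c("rpmH", "dnaA"), start = c(0, 19), end = c(9, 28),
#'              strand = "+"))
#' g
#' @export
genome_record <- function(id, sequence, annotations = NULL, circular = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a non-empty string", call. = FALSE)
  }
  sequence <- .check_dna(sequence, sprintf("sequence of '%s'", id))
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  annotations <- .normalize_annotations(annotations, nchar(sequence))
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         annotations = annotations),
    class = "genome_record"
  )
}

.normalize_annotations <- function(ann, genome_len) {
  if (is.null(ann) || nrow(as.data.frame(ann)) == 0L) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      feature = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  }
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (is.null(ann$feature)) ann$feature <- "gene"
  if (is.null(ann$product)) ann$product <- NA_character_
  needed <- c("name", "start", "end", "strand", "feature", "product")
  missing <- setdiff(needed, names(ann))
  if (length(missing) > 0L) {
    stop("annotations lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[, needed]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  bad <- ann$start < 0L | ann$start >= ann$end | ann$end > genome_len
  if (any(bad)) {
    stop("annotation coordinates out of range (need 0 <= start < end <= genome length)",
         call. = FALSE)
  }
  if (any(!nzchar(ann$name) | is.na(ann$name))) {
    stop("annotation names must be non-empty", call. = FALSE)
  }
  if (any(!ann$strand %in% c("+", "-"))) {
    stop("annotation strands must be '+' or '-'", call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d annotation(s)\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              nrow(x$annotations)))
  if (nrow(x$annotations) > 0L) {
    print(x$annotations, row.names = FALSE)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# GenBank flat-file reading/writing.
#
# Minimal GBFF subset: LOCUS topology, gene/CDS features with gene,
# locus_tag and product qualifiers (plain and complement()/join()
# locations), ORIGIN sequence blocks, multi-record files split on "//".

.parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  bounds <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", p))[[1]]
    if (length(m) == 0L) {
      m <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      if (length(m) == 0L) return(NULL)
      return(c(as.integer(m[2]), as.integer(m[2])))
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  if (any(vapply(bounds, is.null, logical(1)))) return(NULL)
  lo <- min(vapply(bounds, `[`, integer(1), 1L))
  hi <- max(vapply(bounds, `[`, integer(1), 2L))
  # 1-based inclusive -> 0-based half-open
  list(start = lo - 1L, end = hi, strand = strand)
}

.parse_genbank_record <- function(lines) {
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0L) {
    stop("GenBank record lacks a LOCUS line", call. = FALSE)
  }
  toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
  id <- if (length(toks) >= 2L) toks[2] else stop("unnamed LOCUS", call. = FALSE)
  circular <- any(grepl("\\bcircular\\b", locus_line[1], ignore.case = TRUE))

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) {
    stop("GenBank record has no ORIGIN sequence block", call. = FALSE)
  }
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    stop("GenBank record has an empty ORIGIN block", call. = FALSE)
  }

  ann <- NULL
  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) > 0L) {
    feat_lines <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    ann <- .parse_gb_features(feat_lines)
  }
  genome_record(id, sequence, ann, circular = circular)
}

.parse_gb_features <- function(feat_lines) {
  rows <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (!cur$key %in% c("gene", "CDS")) return(NULL)
    loc <- .parse_gb_location(cur$loc)
    if (is.null(loc)) return(NULL)
    name <- cur$qual[["gene"]]
    if (is.null(name)) name <- cur$qual[["locus_tag"]]
    if (is.null(name)) return(NULL)
    product <- cur$qual[["product"]]
    data.frame(name = name, start = loc$start, end = loc$end,
               strand = loc$strand, feature = cur$key,
               product = if (is.null(product)) NA_character_ else product,
               stringsAsFactors = FALSE)
  }
  for (line in feat_lines) {
    if (grepl("^ {5}\\S", line)) {
      r <- flush(cur)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      cur <- list(key = toks[1],
                  loc = if (length(toks) >= 2L) paste(toks[-1], collapse = "") else "",
                  qual = list(), in_qual = NA_character_)
    } else if (!is.null(cur)) {
      body <- trimws(line)
      if (startsWith(body, "/")) {
        m <- regmatches(body, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', body))[[1]]
        if (length(m) > 0L) {
          cur$qual[[m[2]]] <- m[3]
          cur$in_qual <- m[2]
        }
      } else if (!is.na(cur$in_qual) && nzchar(body)) {
        cur$qual[[cur$in_qual]] <- paste(cur$qual[[cur$in_qual]], body)
      } else if (nzchar(body) && is.na(cur$in_qual)) {
        cur$loc <- paste0(cur$loc, body)  # continued location
      }
    }
  }
  r <- flush(cur)
  if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Read all records of an annotated genome file
#'
#' @param path for `format = "genbank"`, a GenBank flat file (single- or
#'   multi-record); for `format = "fasta+gff3"`, a FASTA file.
#' @param format `"genbank"` or `"fasta+gff3"`.
#' @param gff GFF3 annotation file (required when `format = "fasta+gff3"`).
#' @return A list of [genome_record()] objects, one per sequence record.
#' @seealso [read_genome()] for the single-record convenience wrapper.
#' @export
read_genome_set <- function(path, format = c("genbank", "fasta+gff3"),
                            gff = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("input file does not exist: %s", path), call. = FALSE)
  }
  if (format == "genbank") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
      stop(sprintf("not a GenBank file (empty): %s", path), call. = FALSE)
    }
    ends <- grep("^//", lines)
    if (length(ends) == 0L) ends <- length(lines)
    starts <- c(1L, head(ends, -1L) + 1L)
    recs <- list()
    for (i in seq_along(ends)) {
      chunk <- lines[starts[i]:ends[i]]
      if (all(!nzchar(trimws(chunk)))) next
      recs[[length(recs) + 1L]] <- .parse_genbank_record(chunk)
    }
    if (length(recs) == 0L) {
      stop(sprintf("no sequence records in %s", path), call. = FALSE)
    }
    return(recs)
  }
  # fasta + gff3
  if (is.null(gff)) {
    stop("format 'fasta+gff3' requires the gff argument", call. = FALSE)
  }
  if (!file.exists(gff)) {
    stop(sprintf("input file does not exist: %s", gff), call. = FALSE)
  }
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop(sprintf(
                     "cannot parse FASTA %s: %s", path, conditionMessage(e)),
                     call. = FALSE))
  if (length(seqs) == 0L) {
    stop(sprintf("no sequence records in %s", path), call. = FALSE)
  }
  gr <- rtracklayer::import(gff, format = "gff3")
  circular_ids <- character(0)
  gff_lines <- readLines(gff, warn = FALSE)
  circ <- grep("^##species-circular\\s", gff_lines, value = TRUE)
  if (length(circ) > 0L) {
    circular_ids <- unlist(lapply(circ, function(l) strsplit(trimws(l), "\\s+")[[1]][-1]))
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(seqs), function(i) {
    id <- ids[i]
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == id &
                as.character(gr$type) %in% c("gene", "CDS")]
    ann <- NULL
    if (length(sel) > 0L) {
      nm <- sel$gene
      if (is.null(nm)) nm <- sel$Name
      if (is.null(nm)) nm <- sel$ID
      prod <- if (!is.null(sel$product)) as.character(sel$product) else NA_character_
      ann <- data.frame(
        name = as.character(nm),
        start = GenomicRanges::start(sel) - 1L,  # GFF3 is 1-based inclusive
        end = GenomicRanges::end(sel),
        strand = as.character(GenomicRanges::strand(sel)),
        feature = as.character(sel$type),
        product = prod,
        stringsAsFactors = FALSE)
      ann <- ann[!is.na(ann$name) & ann$strand %in% c("+", "-"), , drop = FALSE]
    }
    genome_record(id, as.character(seqs[[i]]), ann,
                  circular = id %in% circular_ids)
  })
}

#' Read a single annotated genome
#'
#' Convenience wrapper around [read_genome_set()] for files holding one
#' sequence record; multi-record files are an error here (the pipeline
#' treats each record of a multi-record file as an independent locus).
#'
#' @inheritParams read_genome_set
#' @return A [genome_record()].
#' @examples
#' gl <- generate_locus("I", seed = 1)
#' f <- tempfile(fileext = ".gb")
#' write_genbank(gl$genome, f)
#' g <- read_genome(f)
#' g$id
#' @export
read_genome <- function(path, format = c("genbank", "fasta+gff3"), gff = NULL) {
  recs <- read_genome_set(path, format = format, gff = gff)
  if (length(recs) > 1L) {
    stop(sprintf("%s holds %d records; use read_genome_set()", path,
                 length(recs)), call. = FALSE)
  }
  recs[[1L]]
}

#' Write a genome record as a GenBank flat file
#'
#' @param genome a [genome_record()] (or list of them, written as a
#'   multi-record file).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  if (inherits(genome, "genome_record")) genome <- list(genome)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genome) {
    topo <- if (g$circular) "circular" else "linear"
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s BCT 01-JAN-2000",
                       g$id, nchar(g$sequence), topo), con)
    writeLines(sprintf("DEFINITION  %s.", g$id), con)
    writeLines(sprintf("ACCESSION   %s", g$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(g$sequence)), con)
    ann <- g$annotations
    if (nrow(ann) > 0L) {
      for (i in seq_len(nrow(ann))) {
        loc <- sprintf("%d..%d", ann$start[i] + 1L, ann$end[i])
        if (ann$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     %-15s %s", ann$feature[i], loc), con)
        writeLines(sprintf('                     /gene="%s"', ann$name[i]), con)
        if (!is.na(ann$product[i])) {
          writeLines(sprintf('                     /product="%s"', ann$product[i]), con)
        }
      }
    }
    writeLines("ORIGIN", con)
    s <- tolower(g$sequence)
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome record as FASTA plus GFF3
#'
#' The GFF3 carries gene features with `gene` and `product` attributes;
#' circular topology is recorded in a `##species-circular` pragma read
#' back by [read_genome_set()].
#'
#' @param genome a [genome_record()].
#' @param fasta_path,gff_path output files.
#' @return `c(fasta_path, gff_path)`, invisibly.
#' @export
write_fasta_gff3 <- function(genome, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- genome$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome$id, nrow(ann)),
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$type <- ann$feature
  gr$gene <- ann$name
  gr$Name <- ann$name
  gr$product <- ann$product
  rtracklayer::export(gr, gff_path, format = "gff3")
  lines <- readLines(gff_path, warn = FALSE)
  extra <- sprintf("##sequence-region %s 1 %d", genome$id, nchar(genome$sequence))
  if (genome$circular) {
    extra <- c(extra, sprintf("##species-circular %s", genome$id))
  }
  writeLines(c(lines[1], extra, lines[-1]), gff_path)
  invisible(c(fasta_path, gff_path))
}

# ---------------------------------------------------------------------------
# Target-region extraction

# locate exactly one annotation for a gene symbol; gene features are
# preferred over CDS, and RefSeq product text is a fallback because gene
# symbols vary across annotations
.match_anchor <- function(genome, symbol) {
  ann <- genome$annotations
  hit <- ann[tolower(ann$name) == tolower(symbol), , drop = FALSE]
  if (nrow(hit) == 0L) {
    pat <- switch(tolower(symbol),
                  "dnaa" = "chromosomal replication initiat|\\bDnaA\\b",
                  "rpmh" = "\\bL34\\b",
                  NULL)
    if (!is.null(pat)) {
      hit <- ann[!is.na(ann$product) & grepl(pat, ann$product), , drop = FALSE]
    }
  }
  if (nrow(hit) == 0L) {
    stop(sprintf("anchor gene absent: %s (in %s)", symbol, genome$id),
         call. = FALSE)
  }
  if (nrow(hit) > 1L) {
    if (sum(hit$feature == "gene") == 1L) {
      hit <- hit[hit$feature == "gene", , drop = FALSE]
    } else if (nrow(unique(hit[, c("start", "end", "strand")])) == 1L) {
      hit <- hit[1L, , drop = FALSE]  # gene + CDS over the same extent
    } else {
      stop(sprintf("ambiguous matches for %s in %s at: %s", symbol, genome$id,
                   paste(sprintf("[%d,%d)%s", hit$start, hit$end, hit$strand),
                         collapse = ", ")), call. = FALSE)
    }
  }
  hit
}

#' Extract the intergenic region antisense to dnaA
#'
#' Locates the two anchor genes (case-insensitive symbol match, product
#' text as fallback) and returns the intergenic sequence re-oriented so
#' it reads 5' to 3' on the strand antisense to *dnaA* — the strand the
#' antisense promoter fires from — starting at the *dnaA*-proximal end.
#' On circular molecules the interval may wrap the origin (represented
#' with `source_end` exceeding the genome length).
#'
#' @param genome a [genome_record()].
#' @param gene_a,gene_b anchor gene symbols (defaults `"dnaA"`, `"rpmH"`).
#' @return An object of class `target_region` with fields `genome_id`,
#'   `sequence`, `source_start`, `source_end` (0-based half-open, genome
#'   frame), `source_strand` (the genome strand the returned sequence was
#'   read from), `length`, `genome_length` and `circular`.
#' @examples
#' g <- genome_record("toy", "GGGGGGGGGACGTACGTACGGGGGGGGGGG",
#'   data.frame(name = c("rpmH", "dnaA"), start = c(0, 19), end = c(9, 28),
#'              strand = "+"))
#' extract_target_region(g)$sequence  # "GTACGTACGT"
#' @export
extract_target_region <- function(genome, gene_a = "dnaA", gene_b = "rpmH") {
  stopifnot(inherits(genome, "genome_record"))
  a <- .match_anchor(genome, gene_a)   # dnaA
  b <- .match_anchor(genome, gene_b)   # rpmH
  L <- nchar(genome$sequence)
  if (a$start < b$end && b$start < a$end) {
    stop(sprintf("anchor genes overlap in %s: %s [%d,%d) vs %s [%d,%d)",
                 genome$id, gene_a, a$start, a$end, gene_b, b$start, b$end),
         call. = FALSE)
  }
  if (genome$circular) {
    # the arc immediately 5' of dnaA on dnaA's strand, ending at the
    # other anchor; wraps the origin when the locus straddles it
    if (a$strand == "+") { from <- b$end; to <- a$start }
    else { from <- a$end; to <- b$start }
    if (from <= to) {
      start <- from; end <- to
    } else {
      start <- from; end <- to + L
    }
  } else {
    start <- min(a$end, b$end)
    end <- max(a$start, b$start)
    if (start > end) {
      stop(sprintf("no intergenic interval between %s and %s in %s",
                   gene_a, gene_b, genome$id), call. = FALSE)
    }
  }
  raw <- .slice_wrap(genome$sequence, start, end, genome$circular)
  if (a$strand == "+") {
    seq <- .revcomp(raw)
    src_strand <- "-"
  } else {
    seq <- raw
    src_strand <- "+"
  }
  structure(
    list(genome_id = genome$id, sequence = seq,
         source_start = start, source_end = end,
         source_strand = src_strand,
         length = nchar(seq), genome_length = L,
         circular = genome$circular),
    class = "target_region"
  )
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region> %s: %d nt from [%d,%d)%s%s\n", x$genome_id,
              x$length, x$source_start, x$source_end, x$source_strand,
              if (x$source_end > x$genome_length) " (origin wrap)" else ""))
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' Re-slice a genome by a target region's provenance coordinates
#'
#' Reproduces `region$sequence` from the genome it came from — the
#' round-trip guarantee behind all coordinate book-keeping.
#'
#' @param genome the originating [genome_record()].
#' @param region a `target_region` (or a list with `source_start`,
#'   `source_end`, `source_strand`).
#' @return The region sequence reconstructed from the genome.
#' @export
genome_slice <- function(genome, region) {
  raw <- .slice_wrap(genome$sequence, region$source_start, region$source_end,
                     genome$circular)
  if (region$source_strand == "-") .revcomp(raw) else raw
}

#' Map a region-frame interval back to genome coordinates
#'
#' Elements (promoter hexamers, DnaA boxes) are reported in region
#' offsets; this maps a 0-based half-open region interval to the genome
#' frame, returning the genome interval, the genome strand an element on
#' the region's own strand lies on, and whether the mapped interval wraps
#' the origin.
#'
#' @param region a `target_region`.
#' @param start,end 0-based half-open offsets into the region sequence.
#' @return A list with `start`, `end` (0-based half-open, `end` may
#'   exceed the genome length when the element wraps), and `strand`.
#' @export
region_to_genome <- function(region, start, end) {
  stopifnot(start >= 0L, end > start, end <= region$length)
  L <- region$genome_length
  if (region$source_strand == "+") {
    gs <- region$source_start + start
    ge <- region$source_start + end
    strand <- "+"
  } else {
    gs <- region$source_end - end
    ge <- region$source_end - start
    strand <- "-"
  }
  # normalise so start lies in [0, L)
  if (gs >= L) { gs <- gs - L; ge <- ge - L }
  list(start = gs, end = ge, strand = strand)
}

#' Write extracted target regions as FASTA
#'
#' Headers carry provenance as `genome_id|start-end|strand` in 0-based
#' half-open genome coordinates.
#'
#' @param regions a list of `target_region` objects.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(regions, path) {
  if (inherits(regions, "target_region")) regions <- list(regions)
  seqs <- Biostrings::DNAStringSet(vapply(regions, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(regions, function(r) {
    sprintf("%s|%d-%d|%s", r$genome_id, r$source_start, r$source_end,
            r$source_strand)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
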