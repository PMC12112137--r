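test_that("a minimal GenBank record parses to one annotated genome", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(minimal_genbank_text(), f)
  g <- read_genome(f)
  expect_s3_class(g, "genome_record")
  expect_equal(g$id, "TESTREC")
  expect_equal(nchar(g$sequence), 60L)
  expect_false(g$circular)
  expect_equal(nrow(g$annotations), 1L)
  expect_equal(g$annotations$name, "dnaA")
  # 1-based inclusive 5..34 -> 0-based half-open [4, 34)
  expect_equal(g$annotations$start, 4L)
  expect_equal(g$annotations$end, 34L)
})

test_that("degenerate inputs raise input/format errors", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(character(0), f)
  expect_error(read_genome(f), "empty")
  expect_error(read_genome(file.path(tempdir(), "no-such-file.gb")),
               "does not exist")
  f2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X  10 bp", "ORIGIN", "//"), f2)
  expect_error(read_genome(f2), "empty ORIGIN")
})

test_that("GenBank and FASTA+GFF3 serializations parse to equal loci", {
  for (grp in c("I", "IV")) {
    gl <- generate_locus(grp, seed = 11, strand = "-", circular_wrap = (grp == "I"))
    gb <- withr::local_tempfile(fileext = ".gb")
    fa <- withr::local_tempfile(fileext = ".fa")
    gf <- withr::local_tempfile(fileext = ".gff3")
    write_genbank(gl$genome, gb)
    write_fasta_gff3(gl$genome, fa, gf)
    g1 <- read_genome(gb)
    g2 <- read_genome(fa, format = "fasta+gff3", gff = gf)
    expect_identical(g1$sequence, g2$sequence)
    expect_identical(g1$circular, g2$circular)
    expect_identical(g1$annotations[, c("name", "start", "end", "strand")],
                     g2$annotations[, c("name", "start", "end", "strand")])
    r1 <- extract_target_region(g1)
    r2 <- extract_target_region(g2)
    expect_identical(r1$sequence, r2$sequence)
    expect_identical(r1$source_start, r2$source_start)
    expect_identical(r1$source_strand, r2$source_strand)
  }
})

test_that("extraction reverse-complements the intergenic interval by hand", {
  g <- toy_genome("ACGTACGTAC")
  r <- extract_target_region(g)
  expect_equal(r$sequence, "GTACGTACGT")   # revcomp of ACGTACGTAC
  expect_equal(r$length, 10L)
  expect_equal(r$source_start, 9L)
  expect_equal(r$source_end, 19L)
  expect_equal(r$source_strand, "-")
})

test_that("extraction is strand-symmetric", {
  set.seed(101)
  for (i in 1:10) {
    ig <- random_seq(sample(40:120, 1))
    flank <- function() random_seq(30)
    seq <- paste0(flank(), "ATGAAATAG", ig, "ATGCCCTAG", flank())
    s1 <- 30L; e1 <- 39L
    s2 <- 39L + nchar(ig); e2 <- s2 + 9L
    g <- genome_record("s", seq, data.frame(
      name = c("rpmH", "dnaA"), start = c(s1, s2), end = c(e1, e2),
      strand = "+", stringsAsFactors = FALSE))
    r_fwd <- extract_target_region(g)
    r_rev <- extract_target_region(flip_genome(g))
    expect_identical(r_fwd$sequence, r_rev$sequence)
  }
})

test_that("circular genomes support origin-wrapping intergenic intervals", {
  # dnaA begins at 40, rpmH ends at 4900, genome 5000 -> wrap, 140 nt
  set.seed(7)
  seq <- random_seq(5000)
  g <- genome_record("circ", seq, data.frame(
    name = c("rpmH", "dnaA"), start = c(4700, 40), end = c(4900, 400),
    strand = "+", stringsAsFactors = FALSE), circular = TRUE)
  r <- extract_target_region(g)
  expect_equal(r$length, 140L)
  expect_equal(r$source_start, 4900L)
  expect_equal(r$source_end, 5040L)   # end past L encodes the wrap
  # modular-arithmetic oracle: splice the two arcs by hand
  manual <- paste0(substr(seq, 4901, 5000), substr(seq, 1, 40))
  expect_identical(r$sequence, rc_oracle(manual))
  # on a linear record the same layout cannot wrap: the extracted
  # interval is the one strictly between the gene bodies instead
  g_lin <- genome_record("lin", seq, g$annotations, circular = FALSE)
  r_lin <- extract_target_region(g_lin)
  expect_equal(r_lin$source_start, 400L)
  expect_equal(r_lin$source_end, 4700L)
})

test_that("re-slicing by provenance reproduces the region byte-for-byte", {
  i <- 0L
  for (grp in c("I", "II", "III", "IV")) {
    for (wrap in c(FALSE, TRUE)) {
      i <- i + 1L
      gl <- generate_locus(grp, seed = 200 + i,
                           strand = if (i %% 2L == 0L) "+" else "-",
                           circular_wrap = wrap)
      r <- extract_target_region(gl$genome)
      expect_identical(genome_slice(gl$genome, r), r$sequence)
    }
  }
})

test_that("element intervals map back to the genome frame consistently", {
  for (wrap in c(FALSE, TRUE)) {
    gl <- generate_locus("II", seed = 31, strand = "-", circular_wrap = wrap)
    r <- extract_target_region(gl$genome)
    boxes <- find_dnaa_boxes(r)
    for (i in seq_len(nrow(boxes))) {
      m <- region_to_genome(r, boxes$start[i], boxes$end[i])
      raw <- arrascan:::.slice_wrap(gl$genome$sequence, m$start, m$end,
                                    gl$genome$circular)
      oriented <- if (m$strand == "-") rc_oracle(raw) else raw
      expect_identical(oriented, boxes$seq[i])
    }
  }
})

test_that("anchor-gene lookup errors are specific", {
  g <- toy_genome()
  g_no <- genome_record("x", g$sequence,
                        g$annotations[g$annotations$name != "dnaA", ])
  expect_error(extract_target_region(g_no), "anchor gene absent: dnaA")
  ann_dup <- rbind(g$annotations,
                   data.frame(name = "dnaA", start = 21, end = 27,
                              strand = "+", feature = "gene",
                              product = NA_character_))
  expect_error(
    extract_target_region(genome_record("x", g$sequence, ann_dup)),
    "ambiguous")
  ann_ovl <- g$annotations
  ann_ovl$start <- c(0L, 5L)
  ann_ovl$end <- c(9L, 28L)
  expect_error(
    extract_target_region(genome_record("x", g$sequence, ann_ovl)),
    "overlap")
  # product-text fallback when the symbol is missing
  ann_prod <- g$annotations
  ann_prod$name <- c("rpmH", "BSU00001")
  ann_prod$product <- c(NA, "chromosomal replication initiator protein DnaA")
  g_prod <- genome_record("x", g$sequence, ann_prod)
  expect_identical(extract_target_region(g_prod)$sequence,
                   extract_target_region(g)$sequence)
})
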