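# Independent brute-force oracles and fixture builders. The oracles share
# no scanning code with the package: windows are compared character by
# character, and the opposite orientation is handled by reverse-
# complementing the window itself (the package transforms the consensus).

rc_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

hamming_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# every box window on both orientations, enumerated one window at a time
oracle_boxes <- function(seq, params = scan_params()) {
  w <- params$box_length
  n <- nchar(seq)
  rows <- list()
  if (n >= w) {
    for (s in 0:(n - w)) {
      win <- substr(seq, s + 1, s + w)
      for (ori in c("+", "-")) {
        probe <- if (ori == "+") win else rc_oracle(win)
        m <- w - hamming_oracle(probe, params$box_consensus)
        if (m >= params$min_box_matches) {
          rows[[length(rows) + 1]] <- data.frame(
            start = s, end = s + w, orientation = ori, seq = win,
            matches = m, similarity = m / w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      orientation = character(0), seq = character(0),
                      matches = integer(0), similarity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$orientation), ]
  rownames(out) <- NULL
  out
}

# every -35/-10 hexamer pair under the budgets, enumerated pairwise
oracle_promoters <- function(seq, params = scan_params()) {
  n <- nchar(seq)
  rows <- list()
  for (m35 in 0:(n - 6)) {
    s35 <- substr(seq, m35 + 1, m35 + 6)
    mm35 <- hamming_oracle(s35, params$consensus_m35)
    if (mm35 > params$max_mm35) next
    for (sp in params$spacer_range[1]:params$spacer_range[2]) {
      m10 <- m35 + 6 + sp
      if (m10 + 6 > n) next
      s10 <- substr(seq, m10 + 1, m10 + 6)
      mm10 <- hamming_oracle(s10, params$consensus_m10)
      if (mm10 > params$max_mm10) next
      rows[[length(rows) + 1]] <- data.frame(
        m10_start = m10, m10_seq = s10, mm10 = mm10,
        m35_start = m35, m35_seq = s35, mm35 = mm35,
        spacer = sp,
        predicted_tss = m10 + 6 + params$tss_offset - 1,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(m10_start = integer(0), m10_seq = character(0),
                      mm10 = integer(0), m35_start = integer(0),
                      m35_seq = character(0), mm35 = integer(0),
                      spacer = integer(0), predicted_tss = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mm10 + out$mm35, abs(out$spacer - 16),
                   out$m10_start, out$m35_start), ]
  rownames(out) <- NULL
  out
}

random_seq <- function(n, gc = 0.44) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# reverse-complement a genome record, flipping annotation coordinates and
# strands: the mirror fixture for strand-symmetry checks
flip_genome <- function(g) {
  L <- nchar(g$sequence)
  ann <- g$annotations
  new_start <- L - ann$end
  ann$end <- L - ann$start
  ann$start <- new_start
  ann$strand <- ifelse(ann$strand == "+", "-", "+")
  genome_record(g$id, rc_oracle(g$sequence), ann, circular = g$circular)
}

# a 30-nt toy locus with known intergenic content, dnaA on "+"
toy_genome <- function(intergenic = "ACGTACGTAC") {
  genome_record(
    "toy",
    paste0("ATGGCAATG", intergenic, "ATGGCAATGAC"),
    data.frame(name = c("rpmH", "dnaA"), start = c(0, 19), end = c(9, 28),
               strand = "+", stringsAsFactors = FALSE))
}

# hand-written GenBank text (independent of write_genbank)
minimal_genbank_text <- function() {
  c("LOCUS       TESTREC                 60 bp    DNA     linear BCT 01-JAN-2000",
    "DEFINITION  minimal test record.",
    "ACCESSION   TESTREC",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             5..34",
    '                     /gene="dnaA"',
    '                     /product="chromosomal replication initiator protein DnaA"',
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//")
}
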