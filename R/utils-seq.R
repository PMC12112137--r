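# Internal sequence helpers. All coordinates in this package are 0-based,
# half-open; 1-based inclusive appears only at GenBank parse/serialize
# boundaries.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# position-wise match indicator against a consensus; N never matches
.match_vec <- function(obs, cons) {
  obs == cons & obs != "N" & cons != "N"
}

# match counts of every width-w window of `chars` against `cons_chars`
# (both character vectors); returns integer vector indexed by 0-based
# window start + 1
.window_matches <- function(chars, cons_chars) {
  n <- length(chars)
  w <- length(cons_chars)
  if (n < w) return(integer(0))
  acc <- integer(n - w + 1L)
  for (k in seq_len(w)) {
    acc <- acc + as.integer(.match_vec(chars[k:(n - w + k)], cons_chars[k]))
  }
  acc
}

# seeded i.i.d. background at a given GC fraction
.random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# slice a linear string by a 0-based half-open interval that may run past
# the end (origin wrap on a circular molecule)
.slice_wrap <- function(seq, start, end, circular) {
  L <- nchar(seq)
  if (end <= L) {
    return(substr(seq, start + 1L, end))
  }
  if (!circular) {
    stop("interval crosses the sequence end but the record is not circular",
         call. = FALSE)
  }
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
}
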