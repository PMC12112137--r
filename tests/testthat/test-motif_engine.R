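test_that("mismatch counting reproduces the worked promoter comparisons", {
  expect_identical(count_mismatches("TATAGT", "TATAAT"), 1L)
  expect_identical(count_mismatches("ATGAAA", "TTGACA"), 2L)
  expect_identical(count_mismatches("TACACA", "TTGACA"), 2L)
  expect_identical(count_mismatches("TATAAT", "TATAAT"), 0L)
  # the promoter-ablating -10 substitution differs at every position
  expect_identical(count_mismatches("GGGGGG", "TATAAT"), 6L)
})

test_that("mismatch counting is symmetric, bounded, and treats N as mismatch", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    a <- random_seq(n)
    b <- random_seq(n)
    m <- count_mismatches(a, b)
    expect_identical(m, count_mismatches(b, a))
    expect_gte(m, 0L)
    expect_lte(m, n)
    expect_identical(m == 0L, a == b)
    expect_identical(m, hamming_oracle(a, b))
  }
  expect_identical(count_mismatches("TANAAT", "TATAAT"), 1L)
  expect_identical(count_mismatches("NNNNNN", "NNNNNN"), 6L)
  expect_error(count_mismatches("TATAAT", "TATAATA"), "length")
  expect_error(count_mismatches("TATXAT", "TATAAT"), "outside")
})

test_that("planted boxes are found on the stated strand and position", {
  p <- scan_params()
  bg <- strrep("G", 100)  # no G-run window reaches 7/9 on either strand
  planted <- paste0(substr(bg, 1, 10), p$box_consensus, substr(bg, 20, 100))
  hits <- find_dnaa_boxes(planted, p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  expect_equal(hits$orientation, "+")
  expect_equal(hits$matches, 9L)
  expect_equal(hits$similarity, 1)
  planted_rc <- paste0(substr(bg, 1, 10), rc_oracle(p$box_consensus),
                       substr(bg, 20, 100))
  hits_rc <- find_dnaa_boxes(planted_rc, p)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$orientation, "-")
  expect_equal(hits_rc$start, 10L)
  # region shorter than the box: empty, not an error
  expect_equal(nrow(find_dnaa_boxes("ACGT", p)), 0L)
})

test_that("box scanning equals brute-force enumeration", {
  set.seed(11)
  p <- scan_params()
  lax <- scan_params(min_box_matches = 5)  # force plenty of hits
  for (n in c(9, 25, 120, 400)) {
    s <- random_seq(n)
    expect_equal(find_dnaa_boxes(s, p), oracle_boxes(s, p))
    expect_equal(find_dnaa_boxes(s, lax), oracle_boxes(s, lax))
  }
})

test_that("box hits on the reverse complement are the mirrored, flipped hits", {
  set.seed(12)
  p <- scan_params(min_box_matches = 6)
  for (i in 1:8) {
    s <- random_seq(sample(50:300, 1))
    fwd <- find_dnaa_boxes(s, p)
    rev <- find_dnaa_boxes(rc_oracle(s), p)
    n <- nchar(s)
    mirrored <- data.frame(start = n - fwd$end, orientation =
                             ifelse(fwd$orientation == "+", "-", "+"),
                           matches = fwd$matches)
    mirrored <- mirrored[order(mirrored$start, mirrored$orientation), ]
    expect_equal(rev$start, mirrored$start)
    expect_equal(rev$orientation, mirrored$orientation)
    expect_equal(rev$matches, mirrored$matches)
  }
})

test_that("raising the box threshold never adds hits", {
  set.seed(13)
  s <- random_seq(500)
  prev <- NULL
  for (thr in 5:9) {
    hits <- find_dnaa_boxes(s, scan_params(min_box_matches = thr))
    if (!is.null(prev)) {
      expect_true(all(paste(hits$start, hits$orientation) %in%
                        paste(prev$start, prev$orientation)))
    }
    expect_true(all(hits$matches >= thr))
    prev <- hits
  }
})

test_that("a planted promoter pair is recovered with its composition", {
  bg <- strrep("G", 30)
  s <- paste0(bg, "TACACA", strrep("G", 16), "TATAAT", bg)
  cand <- scan_promoters(s)
  expect_gte(nrow(cand), 1L)
  top <- cand[1, ]
  expect_equal(top$mm10, 0L)
  expect_equal(top$mm35, 2L)
  expect_equal(top$spacer, 16L)
  expect_equal(top$m35_seq, "TACACA")
  expect_equal(top$m10_seq, "TATAAT")
  expect_equal(top$predicted_tss, top$m10_start + 6L + 7L - 1L)
  # ablating the -10 to GGGGGG removes the candidate at default budgets
  s_mut <- sub("TATAAT", "GGGGGG", s, fixed = TRUE)
  expect_equal(nrow(scan_promoters(s_mut)), 0L)
})

test_that("promoter scanning equals brute-force pair enumeration", {
  set.seed(21)
  strict <- scan_params()
  lax <- scan_params(max_mm10 = 2, max_mm35 = 3, spacer_range = c(14, 19))
  for (n in c(27, 80, 300, 1000, 2000)) {
    s <- random_seq(n)
    expect_equal(scan_promoters(s, strict), oracle_promoters(s, strict))
    expect_equal(scan_promoters(s, lax), oracle_promoters(s, lax))
  }
  # too short for any pair: empty
  expect_equal(nrow(scan_promoters(random_seq(20))), 0L)
})

test_that("tightening promoter budgets never adds candidates", {
  set.seed(22)
  s <- random_seq(800)
  loose <- scan_promoters(s, scan_params(max_mm10 = 2, max_mm35 = 3))
  tight <- scan_promoters(s, scan_params(max_mm10 = 1, max_mm35 = 2))
  key <- function(d) paste(d$m10_start, d$m35_start)
  expect_true(all(key(tight) %in% key(loose)))
})
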