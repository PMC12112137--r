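# helper: a box-hit row in the schema of find_dnaa_boxes()
box_row <- function(start, matches = 9L, orientation = "+") {
  data.frame(start = start, end = start + 9L, orientation = orientation,
             seq = strrep("N", 9), matches = matches,
             similarity = matches / 9, stringsAsFactors = FALSE)
}

prom_row <- function(m10_start, spacer = 16L) {
  data.frame(m10_start = m10_start, m10_seq = "TATAAT", mm10 = 0L,
             m35_start = m10_start - 6L - spacer, m35_seq = "TACACA",
             mm35 = 2L, spacer = spacer,
             predicted_tss = m10_start + 12L, stringsAsFactors = FALSE)
}

test_that("gap measurement recovers the defined group geometries", {
  p <- prom_row(100)
  # boxes ending 2 nt before the -10 and starting 16 nt after it
  g1 <- measure_gaps(p, rbind(box_row(100 - 2 - 9), box_row(106 + 16)))
  expect_equal(g1$g_up, 2L)
  expect_equal(g1$g_down, 16L)
  expect_equal(g1$interbox_gap, 24L)
  # gaps of (7, 11): the same 24 nt between facing edges
  g3 <- measure_gaps(p, rbind(box_row(100 - 7 - 9), box_row(106 + 11)))
  expect_equal(g3$g_up, 7L)
  expect_equal(g3$g_down, 11L)
  expect_equal(g3$interbox_gap, 24L)
  # one flank only -> no measurement
  expect_null(measure_gaps(p, box_row(100 - 2 - 9)))
  expect_null(measure_gaps(p, box_row(106 + 16)))
  expect_null(measure_gaps(p, box_row(50)[0, ]))
})

test_that("the higher-similarity flanking box wins; ties break nearest", {
  p <- prom_row(100)
  dn <- box_row(106 + 16)
  far_strong <- box_row(100 - 10 - 9, matches = 9L)
  near_weak <- box_row(100 - 2 - 9, matches = 7L)
  g <- measure_gaps(p, rbind(far_strong, near_weak, dn))
  expect_equal(g$g_up, 10L)   # similarity beats proximity
  near_strong <- box_row(100 - 2 - 9, matches = 9L)
  g2 <- measure_gaps(p, rbind(far_strong, near_strong, dn))
  expect_equal(g2$g_up, 2L)   # equal similarity: nearest edge wins
  # boxes outside the flank windows do not qualify
  expect_null(measure_gaps(p, rbind(box_row(100 - 13 - 9), dn)))
  expect_null(measure_gaps(p, rbind(box_row(100 - 2 - 9), box_row(106 + 21))))
})

test_that("gap patterns classify into Groups I/II/III and the fallbacks", {
  cases <- list(list(up = 2L, down = 16L, group = "I"),
                list(up = 4L, down = 14L, group = "II"),
                list(up = 7L, down = 11L, group = "III"),
                list(up = 3L, down = 15L, group = "unclassified"))
  for (cs in cases) {
    p <- prom_row(100)
    boxes <- rbind(box_row(100 - cs$up - 9), box_row(106 + cs$down))
    call <- classify_locus(p, boxes, genome_id = "x")
    expect_equal(call$group, cs$group)
    if (cs$group != "unclassified") {
      expect_equal(call$interbox_gap, 24L)
      expect_equal(call$g_up + 6L + call$g_down, call$interbox_gap)
    }
  }
  # no surviving promoter: the promoterless architecture (Group IV)
  call_iv <- classify_locus(prom_row(100)[0, ], box_row(50), genome_id = "x")
  expect_equal(call_iv$group, "IV")
  expect_null(call_iv$promoter)
  # promoter with non-16 spacer never fixes a group call
  call_sp <- classify_locus(prom_row(100, spacer = 17L),
                            rbind(box_row(89), box_row(122)))
  expect_equal(call_sp$group, "unclassified")
})

test_that("classification ignores box order and is deterministic", {
  p <- prom_row(100)
  boxes <- rbind(box_row(89), box_row(122), box_row(30), box_row(200))
  ref <- classify_locus(p, boxes)
  set.seed(3)
  for (i in 1:5) {
    perm <- boxes[sample(nrow(boxes)), ]
    expect_equal(classify_locus(p, perm), ref)
  }
})

test_that("a gap tolerance admits near-miss geometries, default does not", {
  p <- prom_row(100)
  boxes <- rbind(box_row(100 - 3 - 9), box_row(106 + 15))
  expect_equal(classify_locus(p, boxes)$group, "unclassified")
  expect_equal(classify_locus(p, boxes, gap_tolerance = 1L)$group, "I")
})

test_that("every synthetic group call satisfies the 24-bp conservation law", {
  for (grp in c("I", "II", "III")) {
    for (seed in 301:305) {
      gl <- generate_locus(grp, seed = seed)
      reg <- extract_target_region(gl$genome)
      call <- classify_locus(scan_promoters(reg), find_dnaa_boxes(reg))
      expect_equal(call$group, grp)
      expect_equal(call$interbox_gap, 24L)
      expect_equal(call$g_up + 6L + call$g_down, 24L)
    }
  }
})

test_that("tightening budgets moves calls toward IV/unclassified only", {
  tight <- scan_params(max_mm10 = 0, max_mm35 = 1)
  for (seed in 311:316) {
    gl <- generate_locus("I", seed = seed)
    reg <- extract_target_region(gl$genome)
    call <- classify_locus(scan_promoters(reg, tight),
                           find_dnaa_boxes(reg, tight))
    # the planted -35 carries exactly 2 mismatches, over the tight budget
    expect_true(call$group %in% c("IV", "unclassified"))
  }
})
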