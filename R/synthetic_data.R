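# Seeded generator of synthetic rpmH-dnaA loci: the download-free test
# substrate. A locus is built outward from the arrA-sense region string
# (the strand antisense to dnaA), so planted element offsets are stated
# in the same frame every scanner reports in.

# run expr under a private, restored RNG stream; generator kinds pinned
# so identical seeds give identical records across platforms
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

.mutate_positions <- function(chars, k) {
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  chars
}

.random_gene <- function(n, gc) {
  body <- .random_dna(n - 6L, gc)
  paste0("ATG", body, "TAA")
}

#' Generate one synthetic rpmH-dnaA locus with a planted architecture
#'
#' Builds an annotated, GenBank-serializable genome whose intergenic
#' region carries, on the strand antisense to *dnaA*: a consensus -10
#' (`TATAAT`), a -35 with exactly two seed-chosen mismatches from
#' `TTGACA` at a 16-nt spacer, and two exact consensus DnaA boxes at the
#' requested group's gap geometry (Group I: 16 nt to the downstream box
#' and 2 nt to the upstream box; Group II: 14/4; Group III: 11/7). Group
#' IV loci carry the two boxes at their conserved 24-nt separation but no
#' promoter. The background is i.i.d. at the requested GC fraction and is
#' rejection-sampled until no spurious window or element pair satisfies
#' the default budgets, so recovered calls are attributable to the
#' planted architecture alone; exhaustion of the redraw budget is a loud
#' error naming the seed.
#'
#' @param group planted architecture: `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param seed integer seed; equal arguments give byte-identical records.
#' @param region_length intergenic length in nt (default 300).
#' @param gc background GC fraction (default 0.44, typical of
#'   *B. subtilis*).
#' @param strand genome strand carrying *dnaA* (default `"+"`).
#' @param circular_wrap if `TRUE`, the molecule is circular and rotated
#'   so the intergenic region straddles the origin.
#' @param params [scan_params()] the masking is performed against.
#' @param max_redraws redraw budget for the spurious-hit masking
#'   (default 1000).
#' @return A list with `genome` (a [genome_record()]) and `truth` (a
#'   one-row data frame recording the seed, group, and planted element
#'   offsets in the region frame).
#' @examples
#' gl <- generate_locus("I", seed = 1)
#' reg <- extract_target_region(gl$genome)
#' classify_locus(scan_promoters(reg), find_dnaa_boxes(reg))$group  # "I"
#' @export
generate_locus <- function(group = c("I", "II", "III", "IV"), seed,
                           region_length = 300L, gc = 0.44,
                           strand = c("+", "-"), circular_wrap = FALSE,
                           params = scan_params(), max_redraws = 1000L) {
  group <- match.arg(group)
  strand <- match.arg(strand)
  region_length <- as.integer(region_length)
  seed <- as.integer(seed)
  .with_seed(seed, {
    margin <- 20L
    if (group == "IV") {
      footprint <- 2L * params$box_length + 24L
    } else {
      gd <- unname(GROUP_GAPS[[group]]["g_down"])
      gu <- unname(GROUP_GAPS[[group]]["g_up"])
      footprint <- 6L + 16L + 6L + gd + params$box_length
    }
    if (region_length < footprint + 2L * margin) {
      stop(sprintf("region_length %d too short for a group %s architecture (need >= %d)",
                   region_length, group, footprint + 2L * margin), call. = FALSE)
    }
    arch_start <- sample(seq.int(margin, region_length - margin - footprint), 1L)

    fixed <- rep(NA_character_, region_length)
    put <- function(at, s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      fixed[at + seq_along(ch)] <<- ch  # `at` is 0-based
    }
    if (group == "IV") {
      up_box_start <- arch_start
      down_box_start <- arch_start + params$box_length + 24L
      m10_start <- NA_integer_
      m35_start <- NA_integer_
      put(up_box_start, params$box_consensus)
      put(down_box_start, params$box_consensus)
    } else {
      m35_start <- arch_start
      m10_start <- arch_start + 6L + 16L
      up_box_start <- m10_start - gu - params$box_length
      down_box_start <- m10_start + 6L + gd
      m35 <- .mutate_positions(strsplit(params$consensus_m35, "", fixed = TRUE)[[1]], 2L)
      put(m35_start, paste(m35, collapse = ""))
      put(up_box_start, params$box_consensus)
      put(m10_start, params$consensus_m10)
      put(down_box_start, params$box_consensus)
    }

    region <- NULL
    free <- which(is.na(fixed))
    for (try in seq_len(max_redraws)) {
      draw <- fixed
      draw[free] <- strsplit(.random_dna(length(free), gc), "", fixed = TRUE)[[1]]
      cand_region <- paste(draw, collapse = "")
      boxes <- find_dnaa_boxes(cand_region, params)
      boxes_ok <- nrow(boxes) == 2L &&
        all(boxes$orientation == "+") &&
        setequal(boxes$start, c(up_box_start, down_box_start))
      if (!boxes_ok) next
      proms <- scan_promoters(cand_region, params)
      proms_ok <- if (group == "IV") nrow(proms) == 0L else {
        nrow(proms) == 1L && proms$m10_start == m10_start &&
          proms$m35_start == m35_start
      }
      if (!proms_ok) next
      region <- cand_region
      break
    }
    if (is.null(region)) {
      stop(sprintf("spurious-hit masking failed after %d redraws (group %s, seed %d)",
                   max_redraws, group, seed), call. = FALSE)
    }

    # embed: flank | rpmH > | intergenic | dnaA > | flank, dnaA on "+";
    # the region string is the "-" strand of the intergenic read 3'->5'
    # in genome frame, i.e. the intergenic forward slice is its revcomp
    flank <- 25L
    rpmH_len <- 45L
    dnaA_len <- 60L
    seq <- paste0(.random_dna(flank, gc),
                  .random_gene(rpmH_len, gc),
                  .revcomp(region),
                  .random_gene(dnaA_len, gc),
                  .random_dna(flank, gc))
    L <- nchar(seq)
    ann <- data.frame(
      name = c("rpmH", "dnaA"),
      start = c(flank, flank + rpmH_len + region_length),
      end = c(flank + rpmH_len, flank + rpmH_len + region_length + dnaA_len),
      strand = "+",
      feature = "gene",
      product = c("50S ribosomal protein L34",
                  "chromosomal replication initiator protein DnaA"),
      stringsAsFactors = FALSE)
    ig <- c(flank + rpmH_len, flank + rpmH_len + region_length)

    if (strand == "-") {
      seq <- .revcomp(seq)
      new_start <- L - ann$end
      ann$end <- L - ann$start
      ann$start <- new_start
      ann$strand <- "-"
      ig <- c(L - ig[2], L - ig[1])
    }
    if (circular_wrap) {
      cut <- ig[1] + region_length %/% 2L
      seq <- paste0(substr(seq, cut + 1L, L), substr(seq, 1L, cut))
      ann$start <- (ann$start - cut) %% L
      ann$end <- ((ann$end - 1L - cut) %% L) + 1L
    }
    id <- sprintf("syn%s_s%d", group, seed)
    genome <- genome_record(id, seq, ann, circular = circular_wrap)
    truth <- data.frame(
      genome_id = id, group = group, seed = seed,
      region_length = region_length, gc = gc,
      m10_start = m10_start, m35_start = m35_start,
      up_box_start = up_box_start, down_box_start = down_box_start,
      dnaA_strand = strand, circular_wrap = circular_wrap,
      stringsAsFactors = FALSE)
    list(genome = genome, truth = truth)
  })
}

#' Generate a deterministic panel of synthetic loci
#'
#' Per-locus seeds are `base_seed + index` over the panel in canonical
#' group order (I, II, III, IV — insertion order of `counts` is
#' irrelevant); the *dnaA* strand alternates and every third locus is a
#' circular, origin-wrapped molecule, so a panel exercises all
#' extraction paths.
#'
#' @param counts named vector/list of per-group locus counts, names among
#'   `I`, `II`, `III`, `IV`; missing groups default to 0.
#' @param base_seed integer panel seed.
#' @param ... passed on to [generate_locus()] (e.g. `region_length`,
#'   `gc`, `params`).
#' @return An object of class `synthetic_panel`: list with `genomes` (a
#'   list of [genome_record()]s) and `truth` (one row per locus).
#' @examples
#' panel <- generate_panel(c(I = 2, IV = 1), base_seed = 7)
#' panel$truth$group
#' @export
generate_panel <- function(counts, base_seed, ...) {
  counts <- unlist(counts)
  bad <- setdiff(names(counts), c("I", "II", "III", "IV"))
  if (length(bad) > 0L || is.null(names(counts))) {
    stop("counts must be named with groups among I, II, III, IV", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  groups <- rep(c("I", "II", "III", "IV"),
                times = vapply(c("I", "II", "III", "IV"),
                               function(g) as.integer(counts[g] %||% 0L),
                               integer(1)))
  genomes <- vector("list", length(groups))
  truth <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    gl <- generate_locus(groups[i], seed = base_seed + i,
                         strand = if (i %% 2L == 1L) "+" else "-",
                         circular_wrap = (i %% 3L == 0L), ...)
    genomes[[i]] <- gl$genome
    truth[[i]] <- gl$truth
  }
  structure(
    list(genomes = genomes,
         truth = if (length(truth) > 0L) do.call(rbind, truth)
                 else data.frame()),
    class = "synthetic_panel")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d loci\n", length(x$genomes)))
  if (nrow(x$truth) > 0L) print(table(planted = x$truth$group))
  invisible(x)
}

#' Compare planted truth with pipeline calls
#'
#' Joins a panel's truth table to the calls table of [scan_genomes()]
#' by genome identifier and tabulates planted versus called groups.
#'
#' @param truth truth data frame (from a [generate_panel()] object or a
#'   truth TSV).
#' @param calls calls data frame (from [scan_genomes()] or a calls TSV).
#' @return A list with `confusion` (planted x called table), `n`, and
#'   `recovery` (fraction of loci whose call equals the planted group).
#' @export
evaluate_panel <- function(truth, calls) {
  merged <- merge(truth[, c("genome_id", "group")],
                  calls[, c("genome_id", "group")],
                  by = "genome_id", suffixes = c("_planted", "_called"))
  confusion <- table(planted = merged$group_planted,
                     called = merged$group_called)
  structure(
    list(confusion = confusion, n = nrow(merged),
         recovery = mean(merged$group_planted == merged$group_called)),
    class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("<panel_evaluation> %d loci, recovery %.1f%%\n",
              x$n, 100 * x$recovery))
  print(x$confusion)
  invisible(x)
}
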