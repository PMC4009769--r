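## Evidence extraction from paired alignments.

aln_row <- function(read_name, chrom, pos, strand = "+", mapq = 60L,
                    end = pos + 99L, individual_id = "s1") {
  tibble::tibble(individual_id = individual_id, read_name = read_name,
                 chrom = chrom, pos = as.integer(pos), end = as.integer(end),
                 strand = strand, mapq = as.integer(mapq))
}

test_that("only one-end-in-TE pairs with a good anchor yield evidence", {
  ann <- tiny_annotation()
  params <- calling_params()
  ## qualifying pair: anchor at chr9:50,000 (no TE), mate inside Copia copy
  pairs <- dplyr::bind_rows(
    aln_row("q1", "chr9", 50000),
    aln_row("q1", "chr9", 2000100, strand = "-", mapq = 0L),
    ## concordant pair entirely outside TEs
    aln_row("q2", "chr9", 10000),
    aln_row("q2", "chr9", 10300, strand = "-"),
    ## both ends inside TEs
    aln_row("q3", "chr9", 1000100),
    aln_row("q3", "chr9", 1000500, strand = "-"),
    ## low-MAPQ anchor
    aln_row("q4", "chr9", 60000, mapq = 0L),
    aln_row("q4", "chr9", 2000200, strand = "-")
  )
  ev <- extract_te_evidence(pairs, ann, params)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$item, "Copia")
  expect_equal(ev$anchor_pos, 50000L)
  expect_equal(ev$te_id, "TE_COP1")
  expect_equal(ev$te_mate_strand, "-")

  expect_equal(nrow(extract_te_evidence(pairs[0, ], ann, params)), 0)
})

test_that("a 1 bp overlap disqualifies the anchor but qualifies the mate", {
  ann <- tiny_annotation()
  params <- calling_params()
  ## a read whose last base touches the MuDR copy start (1,000,000) counts
  ## as inside: it cannot anchor, but it qualifies as the TE-side mate
  touching <- dplyr::bind_rows(
    aln_row("q1", "chr9", 999901, end = 1000000L),
    aln_row("q1", "chr9", 50000, strand = "-"))
  ev_t <- extract_te_evidence(touching, ann, params)
  expect_equal(ev_t$anchor_pos, 50000L)
  expect_equal(ev_t$item, "MuDR")
  ## ... and paired with a mate inside another TE the pair is two-in -> nothing
  two_in <- dplyr::bind_rows(
    aln_row("q3", "chr9", 999901, end = 1000000L),
    aln_row("q3", "chr9", 2000100, strand = "-"))
  expect_equal(nrow(extract_te_evidence(two_in, ann, params)), 0)
  ## mate's last base touches the copy -> inside
  mate_edge <- dplyr::bind_rows(
    aln_row("q2", "chr9", 50000),
    aln_row("q2", "chr9", 999901, end = 1000000L, strand = "-"))
  ev <- extract_te_evidence(mate_edge, ann, params)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$item, "MuDR")
})

test_that("mate overlapping several records collapses to one row per item", {
  recs <- tiny_records()
  recs$chrom <- "chr9"
  recs$start[recs$te_id == "TE_COP2"] <- 2000500L
  recs$end[recs$te_id == "TE_COP2"] <- 2001500L  # overlaps TE_COP1
  ann <- te_annotation(recs)
  params <- calling_params()
  pairs <- dplyr::bind_rows(
    aln_row("q1", "chr9", 50000),
    aln_row("q1", "chr9", 2000600, strand = "-"))
  ev <- extract_te_evidence(pairs, ann, params)
  expect_equal(nrow(ev), 1)              # both hits are Copia
  ev_el <- extract_te_evidence(pairs, ann, calling_params(level = "element"))
  expect_equal(sort(ev_el$item), c("TE_COP1", "TE_COP2"))
})

test_that("evidence is invariant under shuffling and anchors avoid all TEs", {
  set.seed(5)
  ann <- tiny_annotation()
  params <- calling_params()
  rows <- list()
  for (k in 1:40) {
    anchor_at <- sample(c(50000, 300000, 1200000, 4500000), 1)
    mate_at <- sample(c(1000100, 2000100, 5000100, 70000), 1)
    rows[[2 * k - 1]] <- aln_row(paste0("r", k), "chr9", anchor_at,
                                 mapq = sample(c(0L, 60L), 1))
    rows[[2 * k]] <- aln_row(paste0("r", k), "chr9", mate_at, strand = "-")
  }
  pairs <- dplyr::bind_rows(rows)
  ev1 <- extract_te_evidence(pairs, ann, params)
  ev2 <- extract_te_evidence(pairs[sample(nrow(pairs)), ], ann, params)
  expect_identical(ev1, ev2)
  ## no anchor overlaps any TE interval
  if (nrow(ev1) > 0) {
    hit <- te_overlaps(ann, ev1$anchor_chrom, ev1$anchor_pos,
                       ev1$anchor_pos + 99L)
    expect_equal(nrow(hit), 0)
  }
})

test_that("virtual reference style treats contig reads as inside their TE", {
  ann <- tiny_annotation()
  params <- calling_params()
  pairs <- dplyr::bind_rows(
    aln_row("q1", "chrom_A", 5000),
    aln_row("q1", "TE_GYP1", 100, strand = "-"))
  ev <- extract_te_evidence(pairs, ann, params, reference_style = "virtual")
  expect_equal(ev$item, "Gypsy")
  expect_equal(ev$anchor_chrom, "chrom_A")
})

test_that("SAM input round-trips through Rsamtools and requires mate info", {
  sam <- write_tiny_sam(list(
    c("p1", "99", "chr9", "50000", "60", "4M", "=", "2000100"),
    c("p1", "147", "chr9", "2000100", "0", "4M", "=", "50000")),
    seqlengths = c(chr9 = 7000000))
  aln <- read_pair_alignments(sam, individual_id = "x")
  expect_equal(nrow(aln), 2)
  expect_equal(aln$individual_id, c("x", "x"))
  expect_equal(sort(aln$pos), c(50000L, 2000100L))
  expect_equal(aln$end - aln$pos + 1L, c(4L, 4L))
  ev <- extract_te_evidence(aln, tiny_annotation(), calling_params())
  expect_equal(ev$item, "Copia")

  unpaired <- write_tiny_sam(list(
    c("u1", "0", "chr9", "100", "60", "4M", "*", "0")),
    seqlengths = c(chr9 = 7000000))
  expect_error(read_pair_alignments(unpaired), "mate information")
})

test_that("alignments on sequences unknown to the genome are skipped with a warning", {
  recs <- tiny_records()
  ann <- te_annotation(recs, seqlengths = c(chr9 = 7000000))
  params <- calling_params()
  pairs <- dplyr::bind_rows(
    aln_row("q1", "chrUn", 1000),
    aln_row("q1", "chr9", 2000100, strand = "-"))
  expect_warning(ev <- extract_te_evidence(pairs, ann, params), "chrUn")
  expect_equal(nrow(ev), 0)
})
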