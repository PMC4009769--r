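## Virtual reference, insertion planting, SNPs and read simulation.

test_that("virtual reference excises annotated copies and conserves bases", {
  set.seed(3)
  fx <- random_fixture_annotation(10000L, 4L)
  vr <- build_virtual_reference(fx$genome, fx$annotation)
  expect_equal(length(vr$contigs), nrow(fx$annotation$records))
  expect_equal(sum(Biostrings::width(vr$chromosomes)) +
                 sum(Biostrings::width(vr$contigs)),
               sum(Biostrings::width(fx$genome)))
  ## contig sequence equals the annotated slice
  r <- fx$annotation$records[1, ]
  expect_equal(as.character(vr$contigs[[r$te_id]]),
               as.character(Biostrings::subseq(fx$genome[[r$chrom]],
                                               r$start, r$end)))
  ## genome without TEs is unchanged
  none <- te_annotation(fx$annotation$records[0, ])
  vr0 <- build_virtual_reference(fx$genome, none)
  expect_equal(as.character(vr0$chromosomes), as.character(fx$genome))
  expect_equal(length(vr0$contigs), 0)
})

test_that("overlapping annotations merge into one excision with per-record contigs", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 500)))
  recs <- tibble::tibble(te_id = c("A", "B"), chrom = "c1",
                         start = c(101L, 151L), end = c(200L, 260L),
                         strand = "+", family = "F", superfamily = "S",
                         class = "C")
  vr <- build_virtual_reference(genome, te_annotation(recs))
  ## one merged excision of 101..260 -> chromosome loses 160 bp
  expect_equal(Biostrings::width(vr$chromosomes)[[1]], 2000L - 160L)
  expect_equal(unname(Biostrings::width(vr$contigs)), c(100L, 110L))
  expect_equal(unique(vr$junctions$virtual_pos), 101L)
})

test_that("insertion planting is reproducible, conservative and bounded", {
  set.seed(8)
  fx <- random_fixture_annotation(20000L, 5L)
  vr <- build_virtual_reference(fx$genome, fx$annotation)

  p0 <- plant_insertions(vr$chromosomes, vr$contigs, 0, seed = 1)
  expect_equal(as.character(p0$genome), as.character(vr$chromosomes))
  expect_equal(nrow(p0$truth), 0)

  p1 <- plant_insertions(vr$chromosomes, vr$contigs, 3,
                         annotation = fx$annotation, seed = 9)
  p2 <- plant_insertions(vr$chromosomes, vr$contigs, 3,
                         annotation = fx$annotation, seed = 9)
  expect_identical(p1$truth, p2$truth)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  expect_equal(sum(Biostrings::width(p1$genome)),
               sum(Biostrings::width(vr$chromosomes)) + sum(p1$truth$length))
  ## planted sequence equals the element sequence (or its revcomp)
  for (k in seq_len(nrow(p1$truth))) {
    tr <- p1$truth[k, ]
    got <- as.character(Biostrings::subseq(p1$genome[[tr$chrom]],
                                           tr$sample_start,
                                           tr$sample_start + tr$length - 1))
    want <- as.character(vr$contigs[[tr$te_id]])
    if (tr$strand == "-") {
      want <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(want)))
    }
    expect_equal(got, want)
  }
  expect_error(plant_insertions(vr$chromosomes, vr$contigs,
                                length(vr$contigs) + 1, seed = 1),
               "exceeds")
})

test_that("SNP mutation changes exactly n positions, each to a new base", {
  genome <- Biostrings::DNAStringSet(c(g = strrep("ACGT", 2500)))
  m0 <- mutate_snps(genome, 0, seed = 2)
  expect_equal(as.character(m0), as.character(genome))
  m <- mutate_snps(genome, 137, seed = 2)
  a <- strsplit(as.character(genome[[1]]), "")[[1]]
  b <- strsplit(as.character(m[[1]]), "")[[1]]
  expect_equal(sum(a != b), 137)
  m2 <- mutate_snps(genome, 137, seed = 2)
  expect_identical(as.character(m), as.character(m2))
  expect_error(mutate_snps(genome, 1e6), "exceeds")
})

test_that("read count follows coverage and error-free reads are genome substrings", {
  genome <- Biostrings::DNAStringSet(
    c(g = paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")))
  sp <- sim_params(coverage = 2, read_length = 50, insert_mean = 200,
                   insert_sd = 30)
  sim <- simulate_read_pairs(genome, NULL, sp, seed = 4)
  expect_equal(sim$n_pairs, round(2 * 10000 / (2 * 50)))
  expect_equal(nrow(sim$alignments), 2 * sim$n_pairs)
  gseq <- as.character(genome[[1]])
  some <- sim$alignments[sample(nrow(sim$alignments), 50), ]
  for (k in seq_len(nrow(some))) {
    expect_true(grepl(some$seq[k], gseq, fixed = TRUE))
  }
  ## empirical depth within 10% of request
  depth <- sum(nchar(sim$alignments$seq)) / 10000
  expect_lt(abs(depth - 2) / 2, 0.1)
})

test_that("truth alignments project reads onto the virtual reference", {
  set.seed(12)
  ref <- build_reference_fixture(5)
  vr <- build_virtual_reference(ref$genome, ref$annotation)
  sp <- sim_params(coverage = 5, read_length = 100)
  sim <- simulate_individual(vr, ref$annotation, "i1", sp, seed = 6)
  aln <- sim$alignments
  contig_reads <- aln[aln$chrom %in% names(vr$contigs), ]
  expect_gt(nrow(contig_reads), 0)
  ## TE-body reads carry MAPQ 0 and stay within their contig
  lens <- Biostrings::width(vr$contigs)[match(contig_reads$chrom,
                                              names(vr$contigs))]
  expect_true(all(contig_reads$pos >= 1))
  expect_true(all(contig_reads$pos + 99 <= lens + 99))
  ## reads wholly inside a TE body carry MAPQ 0; only breakpoint-straddling
  ## reads on a contig keep MAPQ 60, so MAPQ-0 dominates
  expect_true(all(contig_reads$mapq %in% c(0L, 60L)))
  expect_gt(mean(contig_reads$mapq == 0L), 0.5)
  expect_true(all(aln$mapq[aln$mapq == 0L] %in% contig_reads$mapq))
  expect_true(all(aln$chrom[aln$mapq == 0L] %in% names(vr$contigs)))
  ## chromosome reads carry MAPQ 60
  chrom_reads <- aln[aln$chrom %in% names(vr$chromosomes), ]
  expect_true(all(chrom_reads$mapq == 60L))

  ## truth SAM written from these alignments parses back
  seqlens <- setNames(
    c(Biostrings::width(vr$chromosomes), Biostrings::width(vr$contigs)),
    c(names(vr$chromosomes), names(vr$contigs)))
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(aln, seqlens, sam)
  back <- read_pair_alignments(sam, "i1")
  expect_equal(nrow(back), nrow(aln))
  expect_equal(sort(back$pos), sort(aln$pos))
})

test_that("identical seeds reproduce identical simulations", {
  ref <- build_reference_fixture(5)
  vr <- build_virtual_reference(ref$genome, ref$annotation)
  sp <- sim_params(coverage = 2, read_length = 76, base_error_rate = 0.01)
  s1 <- simulate_individual(vr, ref$annotation, "x", sp, seed = 31)
  s2 <- simulate_individual(vr, ref$annotation, "x", sp, seed = 31)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)
})
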