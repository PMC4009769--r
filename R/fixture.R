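## Desk-scale synthetic fixture: a small multi-chromosome genome with
## annotated TE copies, planted insertions per individual, and truth
## alignments, so the whole pipeline runs without an external aligner.

fixture_te_library <- function() {
  tribble(
    ~family,      ~superfamily, ~class,
    "ATCOPIA4",   "Copia",      "LTR",
    "ATCOPIA78",  "Copia",      "LTR",
    "ATGP3",      "Gypsy",      "LTR",
    "ATHILA2",    "Gypsy",      "LTR",
    "ATREP3",     "Helitron",   "RC",
    "ATREP10",    "Helitron",   "RC",
    "ATMU1",      "MuDR",       "DNA",
    "VANDAL21",   "MuDR",       "DNA",
    "ATAC1",      "HAT",        "DNA",
    "TA11",       "L1",         "LINE"
  )
}

#' Build an in-memory reference fixture
#'
#' A ~200 kb two-chromosome genome carrying 20 annotated TE copies, two per
#' family across 6 superfamilies (Copia, Gypsy, Helitron, MuDR, HAT, L1),
#' with element lengths of 400-2500 bp and random strands.  Deterministic
#' per seed.
#'
#' @param seed Integer seed.
#' @param n_elements Number of annotated TE copies (2 chromosomes share
#'   them roughly by length).
#' @return List with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([te_annotation()], with chromosome lengths recorded) and `hierarchy`
#'   (tibble).
#' @export
build_reference_fixture <- function(seed, n_elements = 20L) {
  withr::with_seed(seed, {
    lib <- fixture_te_library()
    fam <- lib[rep(seq_len(nrow(lib)), length.out = n_elements), ]
    te_len <- sample(400:2500, n_elements, replace = TRUE)
    te_seq <- vapply(te_len, random_dna, character(1))
    chrom_of <- rep(c("chr1", "chr2"), length.out = n_elements)

    chroms <- character(0)
    recs <- list()
    target <- c(chr1 = 120000L, chr2 = 80000L)
    idx <- 0L
    for (ch in names(target)) {
      sel <- which(chrom_of == ch)
      n_gap <- length(sel) + 1L
      gap_total <- max(target[[ch]] - sum(te_len[sel]), 2000L * n_gap)
      cuts <- sort(sample.int(gap_total - n_gap * 500L, n_gap - 1L))
      gaps <- diff(c(0L, cuts, gap_total - n_gap * 500L)) + 500L
      pieces <- character(0)
      pos <- 0L
      for (j in seq_along(sel)) {
        g <- random_dna(gaps[j])
        pieces <- c(pieces, g, te_seq[sel[j]])
        idx <- idx + 1L
        start <- pos + gaps[j] + 1L
        recs[[idx]] <- tibble(
          te_id = sprintf("%sTE%03d", toupper(ch), idx),
          chrom = ch, start = start, end = start + te_len[sel[j]] - 1L,
          strand = sample(c("+", "-"), 1),
          family = fam$family[sel[j]], superfamily = fam$superfamily[sel[j]],
          class = fam$class[sel[j]])
        pos <- start + te_len[sel[j]] - 1L
      }
      pieces <- c(pieces, random_dna(gaps[n_gap]))
      chroms[ch] <- paste(pieces, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(chroms)
    recs <- bind_rows(recs)
    hierarchy <- tibble(te_id = recs$te_id, family = recs$family,
                        superfamily = recs$superfamily, class = recs$class)
    ann <- te_annotation(recs,
                         seqlengths = setNames(nchar(chroms), names(chroms)))
    list(genome = genome, annotation = ann, hierarchy = hierarchy)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate one individual on a virtual reference
#'
#' Plants insertions into the TE-free chromosomes, adds SNPs, simulates
#' read pairs and returns their truth alignments against the virtual
#' reference.  Insertion points keep `min_gap` distance from each other and
#' from `avoid` (used to keep different individuals' plantings resolvable),
#' and `margin` distance from chromosome ends.
#'
#' @param vr A virtual reference from [build_virtual_reference()].
#' @param annotation The matching [te_annotation()].
#' @param individual_id Label for the simulated individual.
#' @param params A [sim_params()]; `n_snps` SNPs are planted before reads
#'   are drawn.
#' @param n_insertions Number of planted insertions.
#' @param seed Integer seed (local).
#' @param min_gap,margin,avoid Passed to [plant_insertions()].
#' @return List with `truth` (tibble incl. `individual_id`) and
#'   `alignments` (truth-alignment tibble incl. `individual_id` and `mapq`,
#'   ready for [extract_te_evidence()] with `reference_style = "virtual"`).
#' @export
simulate_individual <- function(vr, annotation, individual_id, params,
                                n_insertions = 10L, seed = 1L,
                                min_gap = 2000, margin = 1000,
                                avoid = NULL) {
  withr::with_seed(seed, {
    planted <- plant_insertions(vr$chromosomes, vr$contigs, n_insertions,
                                annotation = annotation, min_gap = min_gap,
                                margin = margin, avoid = avoid)
    sample_genome <- planted$genome
    if (params$n_snps > 0) {
      sample_genome <- mutate_snps(sample_genome, params$n_snps)
    }
    sim <- simulate_read_pairs(sample_genome, planted$truth, params,
                               read_prefix = paste0(individual_id, "_r"))
    truth <- planted$truth
    truth$individual_id <- individual_id
    aln <- sim$alignments
    aln$individual_id <- individual_id
    list(truth = relocate(truth, "individual_id"),
         alignments = aln, n_pairs = sim$n_pairs)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates the reference fixture ([build_reference_fixture()]), its
#' virtual reference, and `n_individuals` simulated individuals, and writes
#' everything as plain text: `reference.fa`, `te_annotation.gff3`,
#' `te_hierarchy.tsv`, `virtual_reference.fa`, per-individual truth SAMs
#' (`<id>_truth.sam`, optionally FASTQ pairs), the pooled `truth.tsv`
#' (`individual_id`, `chrom`, `pos`, `te_id`, `superfamily`, `strand`) and
#' an arm/pericentromere/centromere partition `regions.tsv` on the TE-free
#' coordinates.  Byte-identical for identical seeds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling everything.
#' @param n_individuals Number of simulated individuals (2-5 is typical).
#' @param n_insertions Planted insertions per individual.
#' @param coverage,read_length,insert_mean,insert_sd,base_error_rate
#'   Read-simulation settings; see [sim_params()].
#' @param snp_rate SNPs per bp planted in each individual (0.004 emulates
#'   a diverged natural accession).
#' @param write_fastq Also write the FASTQ pairs (off by default; the truth
#'   SAMs are what the caller consumes).
#' @return Invisibly, a list with the file paths plus the in-memory
#'   `annotation`, virtual reference `vr` and pooled `truth`.
#' @export
make_te_fixture <- function(dir, seed, n_individuals = 3L,
                            n_insertions = 10L, coverage = 20,
                            read_length = 100L, insert_mean = 300,
                            insert_sd = 100, base_error_rate = 0,
                            snp_rate = 0.004, write_fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- build_reference_fixture(seed)
  vr <- build_virtual_reference(ref$genome, ref$annotation)
  total_len <- sum(Biostrings::width(vr$chromosomes))
  params <- sim_params(coverage = coverage, read_length = read_length,
                       insert_mean = insert_mean, insert_sd = insert_sd,
                       base_error_rate = base_error_rate,
                       n_snps = round(snp_rate * total_len))

  ref_fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref$genome, ref_fa)
  gff <- file.path(dir, "te_annotation.gff3")
  write_te_gff(ref$annotation, gff)
  hier <- file.path(dir, "te_hierarchy.tsv")
  readr::write_tsv(ref$hierarchy, hier, progress = FALSE)
  vref_fa <- file.path(dir, "virtual_reference.fa")
  Biostrings::writeXStringSet(c(vr$chromosomes, vr$contigs), vref_fa)

  seqlens <- setNames(
    c(Biostrings::width(vr$chromosomes), Biostrings::width(vr$contigs)),
    c(names(vr$chromosomes), names(vr$contigs)))

  ids <- sprintf("ind%02d", seq_len(n_individuals))
  truth_all <- list()
  sams <- character(0)
  avoid <- NULL
  for (k in seq_along(ids)) {
    sim <- simulate_individual(vr, ref$annotation, ids[k], params,
                               n_insertions = n_insertions,
                               seed = seed + 1000L * k, avoid = avoid)
    avoid <- bind_rows(avoid, select(sim$truth, "chrom", "pos"))
    truth_all[[k]] <- sim$truth
    sam <- file.path(dir, paste0(ids[k], "_truth.sam"))
    write_alignments_sam(sim$alignments, seqlens, sam)
    sams[ids[k]] <- sam
    if (write_fastq) {
      write_fastq_pair(sim$alignments, file.path(dir, ids[k]))
    }
  }
  truth <- bind_rows(truth_all)
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(select(truth, "individual_id", "chrom", "pos", "te_id",
                          "superfamily", "strand"),
                   truth_path, progress = FALSE)

  regions_path <- file.path(dir, "regions.tsv")
  readr::write_tsv(fixture_regions(vr$chromosomes), regions_path,
                   progress = FALSE)

  invisible(list(dir = dir, reference = ref_fa, gff = gff, hierarchy = hier,
                 virtual_reference = vref_fa, sams = sams,
                 truth_path = truth_path, regions_path = regions_path,
                 annotation = ref$annotation, vr = vr, truth = truth,
                 params = params))
}

## centromere = middle 10% of each chromosome, pericentromere = 15% flanks,
## arms = the rest (fixture-scale analogue of a real partition)
fixture_regions <- function(chromosomes) {
  bind_rows(lapply(names(chromosomes), function(ch) {
    L <- Biostrings::width(chromosomes[ch])
    c1 <- round(L * 0.45); c2 <- round(L * 0.55)
    p1 <- round(L * 0.30); p2 <- round(L * 0.70)
    tibble(chrom = ch,
           start = c(1L, p1 + 1L, c1 + 1L, c2 + 1L, p2 + 1L),
           end = c(p1, c1, c2, p2, L),
           region = c("arm", "pericentromere", "centromere",
                      "pericentromere", "arm"))
  }))
}

#' Write a TE annotation as GFF3
#'
#' @param annotation A [te_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_gff <- function(annotation, path) {
  rec <- annotation$records
  lines <- paste(rec$chrom, "tescout", "transposable_element",
                 rec$start, rec$end, ".",
                 ifelse(rec$strand %in% c("+", "-"), rec$strand, "."), ".",
                 paste0("ID=", rec$te_id, ";Alias=", rec$class, "/",
                        rec$superfamily),
                 sep = "\t")
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

write_fastq_pair <- function(aln, prefix) {
  for (mate in c(TRUE, FALSE)) {
    m <- aln[aln$first == mate, ]
    readseq <- ifelse(m$strand == "+", m$seq, revcomp_chr(m$seq))
    lines <- as.vector(rbind(
      paste0("@", m$read_name, if (mate) "/1" else "/2"),
      readseq, "+", strrep("I", nchar(readseq))))
    readr::write_lines(lines,
                       paste0(prefix, if (mate) "_1.fq" else "_2.fq"))
  }
  invisible(prefix)
}
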