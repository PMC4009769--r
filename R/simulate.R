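## Validation-data simulator: virtual reference, planted insertions, SNPs,
## paired reads with a truth-alignment emitter.

#' Build a virtual reference
#'
#' Excises every annotated TE interval from the genome (overlapping
#' annotations are merged into one excision) and emits each annotated
#' element as its own contig, named by `te_id` and holding the
#' forward-strand genomic slice of the record.  Coordinates of downstream
#' sequence shift left accordingly; total base count is conserved when
#' annotations do not overlap.
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA).
#' @param annotation A [te_annotation()] within the genome's bounds.
#' @return List with `chromosomes` (TE-free [Biostrings::DNAStringSet]),
#'   `contigs` (one per record, named by `te_id`) and `junctions`, a tibble
#'   mapping each record to its excision junction in TE-free coordinates
#'   (`te_id`, `chrom`, `ref_start`, `ref_end`, `virtual_pos`).
#' @export
build_virtual_reference <- function(genome, annotation) {
  genome <- load_genome(genome)
  rec <- annotation$records
  bad <- !(rec$chrom %in% names(genome)) |
    rec$end > Biostrings::width(genome)[match(rec$chrom, names(genome))]
  if (any(bad)) {
    abort(paste0("TE records outside genome bounds: ",
                 paste(rec$te_id[bad], collapse = ", ")))
  }
  contigs <- if (nrow(rec) > 0) {
    Biostrings::DNAStringSet(vapply(seq_len(nrow(rec)), function(i) {
      as.character(Biostrings::subseq(genome[[rec$chrom[i]]],
                                      rec$start[i], rec$end[i]))
    }, character(1)))
  } else {
    Biostrings::DNAStringSet()
  }
  names(contigs) <- rec$te_id

  chromosomes <- genome
  junctions <- list()
  for (ch in names(genome)) {
    ri <- rec[rec$chrom == ch, ]
    if (nrow(ri) == 0) next
    blocks <- IRanges::reduce(IRanges::IRanges(ri$start, ri$end))
    bs <- IRanges::start(blocks)
    be <- IRanges::end(blocks)
    keep <- IRanges::gaps(blocks, start = 1,
                          end = Biostrings::width(genome[ch]))
    parts <- vapply(seq_along(keep), function(k) {
      as.character(Biostrings::subseq(genome[[ch]], IRanges::start(keep)[k],
                                      IRanges::end(keep)[k]))
    }, character(1))
    chromosomes[[ch]] <- Biostrings::DNAString(paste(parts, collapse = ""))
    ## junction of a record = start of its merged block, shifted left by the
    ## excised bases before that block
    excised_before <- c(0, cumsum(be - bs + 1))[-(length(bs) + 1)]
    blk <- findInterval(ri$start, bs)
    junctions[[ch]] <- tibble(
      te_id = ri$te_id, chrom = ch, ref_start = ri$start, ref_end = ri$end,
      virtual_pos = as.integer(bs[blk] - excised_before[blk])
    )
  }
  junctions <- if (length(junctions)) bind_rows(junctions) else {
    tibble(te_id = character(), chrom = character(), ref_start = integer(),
           ref_end = integer(), virtual_pos = integer())
  }
  list(chromosomes = chromosomes, contigs = contigs, junctions = junctions)
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genome
}

#' Plant TE insertions into a TE-free genome
#'
#' Samples elements from the TE contigs and inserts their sequence (or its
#' reverse complement, for minus-strand plantings) back into the TE-free
#' chromosomes at uniformly random positions.  A planted copy never lands
#' inside another planted copy; `min_gap`/`margin` can additionally keep
#' insertion points apart and away from chromosome ends.  Reproducible
#' under a fixed seed.
#'
#' The truth coordinate `pos` is on the TE-free genome: the element occupies
#' `pos ... pos+length-1` of the *sample* once all upstream insertions are
#' accounted for; equivalently, the sample is the TE-free sequence with the
#' element spliced in immediately before TE-free position `pos`.
#'
#' @param te_free TE-free chromosomes ([Biostrings::DNAStringSet]).
#' @param contigs TE contigs named by `te_id`.
#' @param n Number of insertions; must not exceed `length(contigs)` unless
#'   `replace = TRUE`.
#' @param annotation Optional [te_annotation()] used to attach superfamily
#'   labels to the truth table.
#' @param seed Optional integer seed (local to this call).
#' @param min_gap Minimum distance in bp between insertion points (and from
#'   positions listed in `avoid`).
#' @param margin Keep insertion points at least this far from chromosome
#'   ends.
#' @param avoid Optional tibble (`chrom`, `pos`) of positions to stay
#'   `min_gap` away from, e.g. plantings of other individuals.
#' @param replace Sample elements with replacement.
#' @return List with `genome` (sample [Biostrings::DNAStringSet]) and
#'   `truth`, a tibble (`chrom`, `pos`, `te_id`, `superfamily`, `strand`,
#'   `length`, `sample_start`) where `sample_start` is the first base of the
#'   planted copy in sample coordinates.
#' @export
plant_insertions <- function(te_free, contigs, n, annotation = NULL,
                             seed = NULL, min_gap = 0, margin = 0,
                             avoid = NULL, replace = FALSE) {
  if (!replace && n > length(contigs)) {
    abort("n exceeds the number of TE contigs (sampling without replacement)")
  }
  run <- function() {
    truth <- tibble(chrom = character(), pos = integer(), te_id = character(),
                    superfamily = character(), strand = character(),
                    length = integer(), sample_start = integer())
    if (n == 0) return(list(genome = te_free, truth = truth))
    ids <- sample(names(contigs), n, replace = replace)
    lens <- setNames(Biostrings::width(te_free), names(te_free))
    usable <- lens > 2 * margin + 2
    if (!any(usable)) abort("no chromosome long enough for the margin")
    taken <- if (is.null(avoid)) {
      tibble(chrom = character(), pos = numeric())
    } else {
      tibble(chrom = avoid$chrom, pos = as.numeric(avoid$pos))
    }
    chrom <- character(n); pos <- integer(n)
    for (k in seq_len(n)) {
      for (try in 1:1000) {
        ch <- sample(names(lens)[usable], 1,
                     prob = lens[usable] / sum(lens[usable]))
        p <- sample.int(lens[ch] - 2L * margin, 1) + as.integer(margin)
        ok <- !any(taken$chrom == ch & abs(taken$pos - p) <= min_gap)
        if (ok) break
      }
      if (!ok) abort("could not place insertions with the requested min_gap")
      chrom[k] <- ch; pos[k] <- p
      taken <- bind_rows(taken, tibble(chrom = ch, pos = as.numeric(p)))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    sf <- if (!is.null(annotation)) {
      te_item(annotation, ids, "superfamily")
    } else {
      NA_character_
    }
    truth <- tibble(chrom = chrom, pos = pos, te_id = ids, superfamily = sf,
                    strand = strand,
                    length = Biostrings::width(contigs)[match(ids, names(contigs))]) |>
      arrange(.data$chrom, .data$pos)

    genome <- te_free
    truth$sample_start <- NA_integer_
    for (ch in unique(truth$chrom)) {
      ti <- which(truth$chrom == ch)
      shift <- c(0, cumsum(truth$length[ti]))[-(length(ti) + 1)]
      truth$sample_start[ti] <- truth$pos[ti] + as.integer(shift)
      base <- as.character(genome[[ch]])
      cuts <- c(1L, truth$pos[ti])          # flank segment starts
      ends <- c(truth$pos[ti] - 1L, nchar(base))
      flanks <- stringr::str_sub(base, cuts, ends)
      ins <- vapply(ti, function(i) {
        s <- as.character(contigs[[truth$te_id[i]]])
        if (truth$strand[i] == "-") revcomp_chr(s) else s
      }, character(1))
      pieces <- character(2 * length(ti) + 1)
      pieces[seq(1, length(pieces), by = 2)] <- flanks
      pieces[seq(2, length(pieces), by = 2)] <- ins
      genome[[ch]] <- Biostrings::DNAString(paste(pieces, collapse = ""))
    }
    list(genome = genome, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plant SNPs into a genome
#'
#' Mutates exactly `n_snps` distinct, uniformly chosen positions, each to a
#' base different from the original.
#'
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path).
#' @param n_snps Number of positions to mutate (`<=` genome length).
#' @param seed Optional integer seed (local to this call).
#' @return The mutated [Biostrings::DNAStringSet].
#' @export
mutate_snps <- function(genome, n_snps, seed = NULL) {
  genome <- load_genome(genome)
  total <- sum(Biostrings::width(genome))
  if (n_snps > total) abort("n_snps exceeds genome length")
  if (n_snps == 0) return(genome)
  run <- function() {
    at_global <- sort(sample.int(total, n_snps))
    offsets <- c(0, cumsum(Biostrings::width(genome)))
    bases <- c("A", "C", "G", "T")
    for (i in seq_along(genome)) {
      at <- at_global[at_global > offsets[i] & at_global <= offsets[i + 1]] -
        offsets[i]
      if (length(at) == 0) next
      old <- as.character(Biostrings::extractAt(
        genome[[i]], IRanges::IRanges(at, at)))
      new <- vapply(old, function(b) {
        sample(setdiff(bases, toupper(b)), 1)
      }, character(1))
      genome[[i]] <- Biostrings::replaceLetterAt(
        genome[[i]], at, paste(new, collapse = ""))
    }
    genome
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate paired-end reads with truth alignments
#'
#' Draws `round(coverage * genome_length / (2 * read_length))` fragments
#' with Normal(`insert_mean`, `insert_sd`) lengths (truncated below at twice
#' the read length), takes the two outermost `read_length` stretches as an
#' inner-facing pair, applies per-base substitution errors, and emits the
#' *truth alignment* of every read projected onto the virtual reference:
#' reads from flanking sequence land on the TE-free chromosome (MAPQ 60),
#' reads wholly inside a planted element land on its TE contig (MAPQ 0,
#' mimicking the multi-mapping an aligner would report there), and
#' breakpoint-straddling reads go to the side holding the majority of their
#' bases.  This gives an aligner-free gold-standard input for the caller.
#'
#' @param sample_genome The planted sample genome from [plant_insertions()].
#' @param truth The truth tibble from [plant_insertions()] (needs
#'   `sample_start`); pass an empty tibble for an insertion-free genome.
#' @param params A [sim_params()].
#' @param seed Optional integer seed (local to this call).
#' @param read_prefix Read-name prefix.
#' @return List with `alignments` (tibble directly consumable by
#'   [extract_te_evidence()]: `read_name`, `chrom`, `pos`, `end`, `strand`,
#'   `mapq`, plus `seq`, `first`, mate fields) and `n_pairs`.
#' @export
simulate_read_pairs <- function(sample_genome, truth, params, seed = NULL,
                                read_prefix = "sim") {
  if (is.null(truth) || nrow(truth) == 0) {
    truth <- tibble(chrom = character(), pos = integer(),
                    te_id = character(), strand = character(),
                    length = integer(), sample_start = integer())
  }
  run <- function() {
    rl <- params$read_length
    lens <- setNames(Biostrings::width(sample_genome), names(sample_genome))
    total <- sum(lens)
    n_pairs <- round(params$coverage * total / (2 * rl))
    if (n_pairs == 0) {
      return(list(alignments = empty_alignments(), n_pairs = 0L))
    }
    chrom <- sample(names(lens), n_pairs, replace = TRUE,
                    prob = lens / total)
    frag <- pmax(2L * rl,
                 as.integer(round(rnorm(n_pairs, params$insert_mean,
                                        params$insert_sd))))
    frag <- pmin(frag, lens[chrom])
    start <- floor(runif(n_pairs) * (lens[chrom] - frag + 1)) + 1L
    start <- as.integer(start)

    seqs <- as.character(sample_genome)[chrom]
    r1 <- stringr::str_sub(seqs, start, start + rl - 1L)
    r2_fwd <- stringr::str_sub(seqs, start + frag - rl, start + frag - 1L)

    ## per-base substitution errors (in read orientation downstream; errors
    ## are strand-symmetric so injecting on the forward slice is equivalent)
    if (params$base_error_rate > 0) {
      r1 <- inject_errors(r1, params$base_error_rate)
      r2_fwd <- inject_errors(r2_fwd, params$base_error_rate)
    }

    name <- paste0(read_prefix, seq_len(n_pairs))
    a1 <- project_reads(chrom, start, start + rl - 1L, "+", truth, lens, rl)
    a2 <- project_reads(chrom, start + frag - rl, start + frag - 1L, "-",
                        truth, lens, rl)
    ## `seq` is stored in mapped-forward orientation (SAM convention);
    ## reads whose projection flipped strand get reverse-complemented
    seq1 <- ifelse(a1$strand == "+", r1, revcomp_chr(r1))
    seq2 <- ifelse(a2$strand == "-", r2_fwd, revcomp_chr(r2_fwd))
    aln <- bind_rows(
      tibble(read_name = name, chrom = a1$chrom, pos = a1$pos,
             end = a1$pos + rl - 1L, strand = a1$strand, mapq = a1$mapq,
             seq = seq1, first = TRUE,
             mate_chrom = a2$chrom, mate_pos = a2$pos,
             mate_strand = a2$strand),
      tibble(read_name = name, chrom = a2$chrom, pos = a2$pos,
             end = a2$pos + rl - 1L, strand = a2$strand, mapq = a2$mapq,
             seq = seq2, first = FALSE,
             mate_chrom = a1$chrom, mate_pos = a1$pos,
             mate_strand = a1$strand)
    )
    list(alignments = arrange(aln, .data$chrom, .data$pos, .data$read_name),
         n_pairs = as.integer(n_pairs))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

empty_alignments <- function() {
  tibble(read_name = character(), chrom = character(), pos = integer(),
         end = integer(), strand = character(), mapq = integer(),
         seq = character(), first = logical(), mate_chrom = character(),
         mate_pos = integer(), mate_strand = character())
}

inject_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  total <- length(reads) * rl
  hit <- which(runif(total) < rate)
  if (length(hit) == 0) return(reads)
  ri <- ((hit - 1L) %/% rl) + 1L
  off <- ((hit - 1L) %% rl) + 1L
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(hit)) {
    old <- substr(reads[ri[k]], off[k], off[k])
    substr(reads[ri[k]], off[k], off[k]) <-
      sample(setdiff(bases, toupper(old)), 1)
  }
  reads
}

## Project sample-coordinate read intervals onto the virtual reference.
## `truth` holds the planted blocks (sample_start .. sample_start+length-1
## -> contig te_id with orientation `strand`; `pos` is the TE-free junction).
project_reads <- function(chrom, a, b, strand, truth, sample_lens, rl) {
  n <- length(chrom)
  out_chrom <- chrom
  out_pos <- integer(n)
  out_strand <- rep(strand, n)
  out_mapq <- rep(60L, n)

  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ti <- truth[truth$chrom == ch, ]
    if (nrow(ti) == 0) {
      out_pos[sel] <- a[sel]
      next
    }
    bs <- ti$sample_start
    be <- ti$sample_start + ti$length - 1L
    ins_before <- c(0L, cumsum(ti$length))   # total planted bp through block k
    ka <- findInterval(a[sel], bs)
    kb <- findInterval(b[sel], bs)
    ov_a <- ifelse(ka > 0, pmax(0L, pmin(b[sel], be[pmax(ka, 1)]) -
                                  pmax(a[sel], bs[pmax(ka, 1)]) + 1L), 0L)
    ov_b <- ifelse(kb > 0 & kb != ka,
                   pmax(0L, pmin(b[sel], be[pmax(kb, 1)]) -
                          pmax(a[sel], bs[pmax(kb, 1)]) + 1L), 0L)
    ov_te <- ov_a + ov_b
    in_te <- ov_te > (b[sel] - a[sel] + 1L) / 2
    blk <- ifelse(ov_a >= ov_b, ka, kb)

    for (j in seq_along(sel)) {
      i <- sel[j]
      if (in_te[j]) {
        k <- blk[j]
        if (ti$strand[k] == "+") {
          cpos <- a[i] - bs[k] + 1L
        } else {
          cpos <- be[k] - b[i] + 1L
          out_strand[i] <- if (strand == "+") "-" else "+"
        }
        out_chrom[i] <- ti$te_id[k]
        out_pos[i] <- max(1L, min(cpos, ti$length[k] - rl + 1L))
        out_mapq[i] <- if (ov_te[j] == rl) 0L else 60L
      } else {
        ## flank read; project the flank-resident start onto TE-free coords
        aa <- a[i]
        k <- ka[j]
        if (k > 0 && aa <= be[k]) {
          ## starts inside a block but majority flank: clip to the junction
          out_pos[i] <- ti$pos[k]
          next
        }
        shift <- if (k > 0) ins_before[k + 1L] else 0L
        out_pos[i] <- as.integer(aa - shift)
      }
    }
  }
  list(chrom = out_chrom, pos = out_pos, strand = out_strand, mapq = out_mapq)
}
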