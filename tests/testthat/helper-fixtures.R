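## Shared in-code fixtures: a tiny annotation, engineered evidence rows,
## and writers for minimal GFF/SAM inputs.

tiny_records <- function() {
  tibble::tribble(
    ~te_id,     ~chrom,  ~start,   ~end,     ~strand, ~family,     ~superfamily, ~class,
    "TE_MUDR1", "chr9",  1000000L, 1007678L, "+",     "ATMU1",     "MuDR",       "DNA",
    "TE_COP1",  "chr9",  2000000L, 2002940L, "+",     "ATCOPIA4",  "Copia",      "LTR",
    "TE_COP2",  "chr9",  3000000L, 3000381L, "-",     "ATCOPIA78", "Copia",      "LTR",
    "TE_GYP1",  "chr9",  4000000L, 4000650L, "+",     "ATGP3",     "Gypsy",      "LTR",
    "TE_HEL1",  "chr9",  5000000L, 5003889L, "+",     "ATREP3",    "Helitron",   "RC",
    "TE_HAT1",  "chr9",  6000000L, 6000899L, "-",     "ATAC1",     "HAT",        "DNA"
  )
}

tiny_annotation <- function() te_annotation(tiny_records())

## Evidence rows for one engineered cluster: `p` parallel votes (anchor +,
## TE mate -) and `i` inverse votes (anchor +, TE mate +) around `center`.
ev_cluster <- function(center, item, te_id, p = 0, i = 0,
                       chrom = "chr1", individual_id = "ind1",
                       te_strand = "+", spread = 40L, mapq = 60L) {
  n <- p + i
  if (n == 0) return(NULL)
  tibble::tibble(
    individual_id = individual_id,
    read_name = paste0(individual_id, "_", item, "_", center, "_", seq_len(n)),
    anchor_chrom = chrom,
    anchor_pos = as.integer(center + seq(-spread, spread, length.out = n)),
    anchor_strand = "+",
    anchor_mapq = as.integer(mapq),
    te_id = te_id,
    te_strand = te_strand,
    te_mate_strand = rep(c("-", "+"), c(p, i)),
    item = item
  )
}

write_tiny_gff <- function(features, path = tempfile(fileext = ".gff3")) {
  readr::write_lines(c("##gff-version 3", features), path)
  path
}

gff_feature <- function(chrom, start, end, id, type = "transposable_element",
                        strand = "+", alias = NULL) {
  attrs <- paste0("ID=", id, if (!is.null(alias)) paste0(";Alias=", alias))
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

tiny_hierarchy <- function() {
  r <- tiny_records()
  tibble::tibble(te_id = r$te_id, family = r$family,
                 superfamily = r$superfamily, class = r$class)
}

## Minimal SAM with the given alignment rows (list of c(qname, flag, rname,
## pos, mapq, cigar, rnext, pnext)).
write_tiny_sam <- function(rows, seqlengths, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(seqlengths), "\tLN:", seqlengths))
  body <- vapply(rows, function(r) {
    paste(c(r, "0", "ACGT", "IIII"), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  path
}

## brute-force single-linkage partition over 1-d positions (oracle)
brute_single_linkage <- function(pos, window) {
  if (length(pos) == 1) return(1L)
  hc <- stats::hclust(stats::dist(pos), method = "single")
  stats::cutree(hc, h = window)
}

## normalise a cluster labelling to compare partitions
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

## brute-force all-pairs windowed pairwise difference (oracle)
brute_pairwise_diversity <- function(x, loc, window_size) {
  n <- ncol(x)
  pairs <- utils::combn(n, 2)
  win <- floor((loc - 1) / window_size) * window_size + 1
  vapply(sort(unique(win)), function(w) {
    rows <- which(win == w)
    d <- apply(pairs, 2, function(pr) {
      sum(x[rows, pr[1]] != x[rows, pr[2]])
    })
    mean(d) / window_size
  }, numeric(1))
}

## quick random non-overlapping annotation on a random genome
random_fixture_annotation <- function(genome_len = 5000L, n_te = 3L) {
  starts <- sort(sample.int(genome_len - 400L, n_te))
  ok <- c(TRUE, diff(starts) > 350L)
  starts <- starts[ok]
  widths <- sample(100:300, length(starts), replace = TRUE)
  recs <- tibble::tibble(
    te_id = sprintf("TEX%02d", seq_along(starts)),
    chrom = "c1", start = starts, end = starts + widths - 1L,
    strand = sample(c("+", "-"), length(starts), replace = TRUE),
    family = "FAM", superfamily = "Copia", class = "LTR")
  genome <- Biostrings::DNAStringSet(setNames(paste(
    sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
    collapse = ""), "c1"))
  list(genome = genome, annotation = te_annotation(recs))
}
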