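## Paired-end alignment I/O: SAM/BAM in (via Rsamtools), SAM out.

#' Read primary paired alignments from a SAM/BAM file
#'
#' Loads the primary, mapped records of a coordinate-sortable paired-end
#' alignment file into a tibble.  Secondary, supplementary and
#' duplicate-flagged records are dropped.  SAM input is converted with
#' [Rsamtools::asBam()] first.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param individual_id Optional individual label attached to every record.
#' @return Tibble with columns `individual_id`, `read_name`, `flag`, `chrom`,
#'   `pos`, `end` (reference span from the CIGAR), `strand`, `mapq`.
#' @export
read_pair_alignments <- function(path, individual_id = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(b$qname) == 0) {
    return(tibble(individual_id = character(), read_name = character(),
                  flag = integer(), chrom = character(), pos = integer(),
                  end = integer(), strand = character(), mapq = integer()))
  }
  if (!any(bitwAnd(b$flag, 1L) > 0L)) {
    abort(paste0("no paired records in ", path,
                 ": mate information is required"))
  }
  tibble(
    individual_id = individual_id %||% "sample",
    read_name = b$qname,
    flag = b$flag,
    chrom = as.character(b$rname),
    pos = b$pos,
    end = b$pos + cigar_ref_width(b$cigar) - 1L,
    strand = as.character(b$strand),
    mapq = as.integer(b$mapq)
  )
}

## reference-consuming CIGAR width (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  vapply(ops, function(m) {
    if (nrow(m) == 0) return(0L)
    keep <- m[, 3] %in% c("M", "D", "N", "=", "X")
    as.integer(sum(as.numeric(m[keep, 2])))
  }, integer(1))
}

#' Write alignment records as SAM text
#'
#' Emits a minimal valid SAM file (header with `@SQ` lines plus one line per
#' read).  Used by the simulator's truth-alignment emitter; any SAM-aware
#' tool can consume the result.
#'
#' @param aln Tibble with columns `read_name`, `chrom`, `pos`, `strand`,
#'   `mapq`, `seq` (forward-strand orientation), `first` (logical: first in
#'   pair), `mate_chrom`, `mate_pos`, `mate_strand`.
#' @param seqlengths Named vector of reference sequence lengths for the
#'   header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(aln, seqlengths, path) {
  flag <- 1L +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate_strand == "-", 32L, 0L) +
    ifelse(aln$first, 64L, 128L)
  rnext <- ifelse(aln$mate_chrom == aln$chrom, "=", aln$mate_chrom)
  lines <- paste(aln$read_name, flag, aln$chrom, aln$pos, aln$mapq,
                 paste0(nchar(aln$seq), "M"), rnext, aln$mate_pos, 0L,
                 aln$seq, strrep("I", nchar(aln$seq)), sep = "\t")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(seqlengths), "\tLN:",
                     as.integer(seqlengths)))
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

revcomp_chr <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}
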