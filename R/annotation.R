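## TE annotation + hierarchy: parsing, interval index, item naming.

te_hierarchy_levels <- c("element", "family", "superfamily", "class")

#' Read a TE hierarchy table
#'
#' The hierarchy table maps every annotated element to its family,
#' superfamily and class/order (GyDB-style nesting).  Plain TSV with header
#' columns `te_id`, `family`, `superfamily`, `class`.
#'
#' @param path Path to the TSV, or a data frame already holding the columns.
#' @return A tibble with one row per element.
#' @export
read_te_hierarchy <- function(path) {
  h <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("te_id", "family", "superfamily", "class")
  if (!all(need %in% names(h))) {
    abort(paste0("hierarchy table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  h <- h[need]
  bad <- !stats::complete.cases(h) | apply(h == "", 1, any)
  if (any(bad)) {
    abort(paste0("hierarchy rows with empty names for: ",
                 paste(h$te_id[bad], collapse = ", ")))
  }
  if (anyDuplicated(h$te_id)) {
    abort("duplicate te_id in hierarchy table")
  }
  h
}

new_te_annotation <- function(records, seqlengths = NULL) {
  records <- as_tibble(records)
  records$strand <- ifelse(records$strand %in% c("+", "-"), records$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(records$start, records$end),
    strand = records$strand
  )
  structure(list(records = records, gr = gr, seqlengths = seqlengths),
            class = "te_annotation")
}

#' Build a TE annotation index from tabular records
#'
#' Mostly useful for constructing small annotations in code; real inputs go
#' through [read_te_annotation()].
#'
#' @param records Data frame with columns `te_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`+`, `-` or anything else for unknown),
#'   `family`, `superfamily`, `class`.
#' @param seqlengths Optional named vector of chromosome lengths; when
#'   present, alignments on unknown sequences are warned about and skipped.
#' @return A `te_annotation` object holding the records and an interval index.
#' @export
te_annotation <- function(records, seqlengths = NULL) {
  records <- as_tibble(records)
  need <- c("te_id", "chrom", "start", "end", "strand",
            "family", "superfamily", "class")
  if (!all(need %in% names(records))) {
    abort(paste0("records must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(records$start > records$end)) abort("start > end in TE records")
  if (anyDuplicated(records$te_id)) abort("duplicate te_id in TE records")
  new_te_annotation(records[need], seqlengths)
}

#' Parse a TE annotation (GFF3) plus hierarchy table
#'
#' Keeps features whose `type` contains any of `feature_types` (TAIR uses
#' `transposable_element` and friends), resolves each feature's identifier in
#' the hierarchy table, and builds an interval index for TE-membership
#' queries.  Coordinates stay 1-based inclusive as in GFF.
#'
#' Features missing from the hierarchy table fall back to an inline
#' `Alias`/`family` attribute of the form `"LTR/Copia"` (class/superfamily);
#' if neither source resolves, an error lists the offending ids.
#'
#' @param gff_path Path to the GFF3 annotation.
#' @param hierarchy Path to (or data frame of) the hierarchy table; see
#'   [read_te_hierarchy()].  May be `NULL` if every feature carries an inline
#'   family attribute.
#' @param feature_types Character vector; a feature is kept when its type
#'   contains any of these strings (fixed match).
#' @param fasta_path Optional reference FASTA used only to record chromosome
#'   lengths.
#' @return A `te_annotation` object.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   paste("chr1", "TAIR", "transposable_element", "1000", "2000",
#'         ".", "+", ".", "ID=AT1TE001", sep = "\t")), gff)
#' hier <- data.frame(te_id = "AT1TE001", family = "ATCOPIA4",
#'                    superfamily = "Copia", class = "LTR")
#' ann <- read_te_annotation(gff, hier)
#' te_item(ann, "AT1TE001", "superfamily")
#' @export
read_te_annotation <- function(gff_path, hierarchy = NULL,
                               feature_types = "transposable_element",
                               fasta_path = NULL) {
  validate_gff_lines(gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  keep <- rep(FALSE, length(gr))
  type <- as.character(gr$type)
  for (ft in feature_types) keep <- keep | grepl(ft, type, fixed = TRUE)
  gr <- gr[keep]

  seqlengths <- NULL
  if (!is.null(fasta_path)) {
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    seqlengths <- setNames(Biostrings::width(genome), names(genome))
  }

  if (length(gr) == 0) {
    return(new_te_annotation(
      tibble(te_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), family = character(),
             superfamily = character(), class = character()),
      seqlengths))
  }

  ids <- gr$ID %||% gr$Name
  if (is.null(ids) || anyNA(ids)) {
    abort("every TE feature needs an ID (or Name) attribute")
  }
  rec <- tibble(
    te_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )

  h <- if (!is.null(hierarchy)) read_te_hierarchy(hierarchy) else NULL
  rec <- resolve_hierarchy(rec, h, gr)
  if (anyDuplicated(rec$te_id)) abort("duplicate te_id in GFF annotation")
  new_te_annotation(rec, seqlengths)
}

## GFF3 body lines must have 9 tab-separated fields; report the first bad line.
validate_gff_lines <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1]]
    abort(paste0("malformed GFF line ", lineno, " in ", path,
                 " (expected 9 tab-separated fields)"))
  }
  invisible(TRUE)
}

resolve_hierarchy <- function(rec, h, gr) {
  if (!is.null(h)) {
    rec <- left_join(rec, h, by = "te_id")
  } else {
    rec$family <- rec$superfamily <- rec$class <- NA_character_
  }
  miss <- is.na(rec$superfamily)
  if (any(miss)) {
    ## inline fallback: Alias or family attribute like "LTR/Copia"
    alias <- gr$Alias %||% gr$family
    if (!is.null(alias)) {
      alias <- vapply(alias, function(x) as.character(x)[1] %||% NA_character_,
                      character(1))
      parts <- stringr::str_split_fixed(alias[miss], stringr::fixed("/"), 2)
      ok <- nzchar(parts[, 1]) & nzchar(parts[, 2])
      rec$class[miss][ok] <- parts[ok, 1]
      rec$superfamily[miss][ok] <- parts[ok, 2]
      rec$family[miss][ok] <- alias[miss][ok]
    }
  }
  miss <- is.na(rec$superfamily) | is.na(rec$family) | is.na(rec$class)
  if (any(miss)) {
    abort(paste0("TE ids absent from hierarchy table (and no inline family): ",
                 paste(rec$te_id[miss], collapse = ", ")))
  }
  rec
}

#' @export
print.te_annotation <- function(x, ...) {
  cat("<te_annotation> ", nrow(x$records), " TE records on ",
      length(unique(x$records$chrom)), " sequence(s); ",
      length(unique(x$records$superfamily)), " superfamilies\n", sep = "")
  invisible(x)
}

#' Name of the hierarchy item an element belongs to
#'
#' @param annotation A `te_annotation`.
#' @param te_id Element identifier(s); vectorised.
#' @param level One of `"element"`, `"family"`, `"superfamily"`, `"class"`.
#' @return Character vector of item names; `level = "element"` returns
#'   `te_id` itself.  Unknown ids are an error.
#' @export
te_item <- function(annotation, te_id, level = "superfamily") {
  level <- match.arg(level, te_hierarchy_levels)
  rec <- annotation$records
  idx <- match(te_id, rec$te_id)
  if (anyNA(idx)) {
    abort(paste0("unknown te_id: ", paste(te_id[is.na(idx)], collapse = ", ")))
  }
  switch(level,
         element = rec$te_id[idx],
         family = rec$family[idx],
         superfamily = rec$superfamily[idx],
         class = rec$class[idx])
}

#' Reference loci of a hierarchy item
#'
#' All annotated intervals whose record maps to `item` at `level`; used for
#' new/old classification, where at higher levels *all* loci of the item
#' count (any Copia near any annotated Copia copy is "old").
#'
#' @inheritParams te_item
#' @param item Item name at `level`.
#' @return Tibble with `te_id`, `chrom`, `start`, `end`; empty (not an
#'   error) for an unknown name.
#' @export
te_loci <- function(annotation, item, level = "superfamily") {
  level <- match.arg(level, te_hierarchy_levels)
  rec <- annotation$records
  key <- switch(level, element = rec$te_id, family = rec$family,
                superfamily = rec$superfamily, class = rec$class)
  rec[key %in% item, c("te_id", "chrom", "start", "end")]
}

#' TE records overlapping genomic intervals
#'
#' Interval-index lookup: which annotated TEs overlap each query interval
#' (1-based inclusive; a single position is `start == end`).
#'
#' @inheritParams te_item
#' @param chrom,start,end Parallel vectors of query intervals.
#' @return Tibble with `query` (row index into the input) and all record
#'   columns, one row per (query, overlapping record).
#' @export
te_overlaps <- function(annotation, chrom, start, end = start) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, annotation$gr, ignore.strand = TRUE)
  out <- annotation$records[S4Vectors::subjectHits(hits), ]
  out$query <- S4Vectors::queryHits(hits)
  relocate(out, "query")
}
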