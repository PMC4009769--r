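## Evidence extraction: mate-pairs with one end outside all TEs (anchor)
## and the other end inside an annotated TE.

#' Extract TE anchor evidence from paired alignments
#'
#' Scans paired-end alignments and keeps exactly the informative pairs: one
#' end ("anchor") mapped with good quality (MAPQ >= `min_anchor_mapq`) and
#' overlapping no annotated TE, the other end overlapping at least one TE.
#' Pairs with both ends inside TEs, both outside, or a low-quality anchor
#' contribute nothing.  The TE-side mate has no quality requirement because
#' multi-mapping within near-identical TE copies is expected; the hierarchy
#' level absorbs that ambiguity.
#'
#' Two reference styles are supported:
#' * `"annotated"` — alignments are against the ordinary reference; TE
#'   membership is decided by overlap (>= 1 bp) with the annotation index.
#' * `"virtual"` — alignments are against a virtual reference whose TE
#'   copies were excised into one contig per element (see
#'   [build_virtual_reference()]); a read on a TE contig is inside that TE
#'   by construction, and chromosomal reads are always outside.
#'
#' When the TE-side mate overlaps several records, one evidence row is
#' emitted per distinct item at `params$level` (duplicates collapsed);
#' within an item the most-overlapped record is kept.
#'
#' @param pairs Tibble from [read_pair_alignments()] (or a path to a
#'   SAM/BAM, which is read for you).  Both mates of a pair must be present;
#'   reads whose mate is missing are skipped.
#' @param annotation A [te_annotation()].
#' @param params A [calling_params()].
#' @param reference_style `"annotated"` or `"virtual"` (see above).
#' @param individual_id Label used when `pairs` lacks an `individual_id`
#'   column.
#' @return Tibble with one row per qualifying (pair, item): `individual_id`,
#'   `read_name`, `anchor_chrom`, `anchor_pos` (leftmost mapped base),
#'   `anchor_strand`, `anchor_mapq`, `te_id`, `te_strand` (annotated strand
#'   of the source copy), `te_mate_strand`, `item`.  Rows are canonically
#'   sorted, so the result is independent of input record order.
#' @export
extract_te_evidence <- function(pairs, annotation, params,
                                reference_style = c("annotated", "virtual"),
                                individual_id = NULL) {
  reference_style <- match.arg(reference_style)
  if (is.character(pairs)) {
    pairs <- read_pair_alignments(pairs, individual_id = individual_id)
  }
  pairs <- as_tibble(pairs)
  need <- c("read_name", "chrom", "pos", "end", "strand", "mapq")
  if (!all(need %in% names(pairs))) {
    abort(paste0("pairs must have columns: ", paste(need, collapse = ", ")))
  }
  if (!"individual_id" %in% names(pairs)) {
    pairs$individual_id <- individual_id %||% "sample"
  }
  empty <- tibble(individual_id = character(), read_name = character(),
                  anchor_chrom = character(), anchor_pos = integer(),
                  anchor_strand = character(), anchor_mapq = integer(),
                  te_id = character(), te_strand = character(),
                  te_mate_strand = character(), item = character())
  if (nrow(pairs) == 0) return(empty)

  rec <- annotation$records
  ## drop alignments on sequences unknown to the annotation's genome
  if (!is.null(annotation$seqlengths)) {
    known <- c(names(annotation$seqlengths), rec$te_id)
    bad <- !(pairs$chrom %in% known)
    if (any(bad)) {
      warn(paste0("skipping ", sum(bad), " alignment(s) on sequence(s) ",
                  "absent from the annotation's genome: ",
                  paste(unique(pairs$chrom[bad]), collapse = ", ")))
      pairs <- pairs[!bad, ]
      if (nrow(pairs) == 0) return(empty)
    }
  }

  pairs$.row <- seq_len(nrow(pairs))
  rec$item <- te_item(annotation, rec$te_id, params$level)

  ## per-alignment TE hits (row -> best record per item, overlap width)
  if (reference_style == "annotated") {
    q <- GenomicRanges::GRanges(pairs$chrom,
                                IRanges::IRanges(pairs$pos, pairs$end))
    hits <- GenomicRanges::findOverlaps(q, annotation$gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(pairs$end[qh], rec$end[sh]) - pmax(pairs$pos[qh], rec$start[sh]) + 1L
    hit_tbl <- tibble(.row = qh, te_id = rec$te_id[sh],
                      te_strand = rec$strand[sh], item = rec$item[sh],
                      overlap = ov)
  } else {
    m <- match(pairs$chrom, rec$te_id)
    in_contig <- !is.na(m)
    hit_tbl <- tibble(.row = pairs$.row[in_contig],
                      te_id = rec$te_id[m[in_contig]],
                      te_strand = rec$strand[m[in_contig]],
                      item = rec$item[m[in_contig]],
                      overlap = pairs$end[in_contig] - pairs$pos[in_contig] + 1L)
  }
  pairs$in_te <- pairs$.row %in% hit_tbl$.row

  ## pair up mates by read name; keep pairs with exactly one end in a TE
  pp <- pairs |>
    group_by(.data$individual_id, .data$read_name) |>
    filter(n() == 2L) |>
    mutate(.mate_in_te = rev(.data$in_te)) |>
    ungroup()
  anchors <- pp |>
    filter(!.data$in_te, .data$.mate_in_te,
           .data$mapq >= params$min_anchor_mapq)
  mates <- pp |> filter(.data$in_te, !.data$.mate_in_te)
  if (nrow(anchors) == 0) return(empty)

  ## one evidence row per (pair, item); best-overlapped record within item
  mate_items <- hit_tbl |>
    filter(.data$.row %in% mates$.row) |>
    group_by(.data$.row, .data$item) |>
    arrange(desc(.data$overlap), .data$te_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    left_join(select(mates, ".row", "individual_id", "read_name",
                     te_mate_strand = "strand"),
              by = ".row")

  out <- anchors |>
    select("individual_id", "read_name", anchor_chrom = "chrom",
           anchor_pos = "pos", anchor_strand = "strand",
           anchor_mapq = "mapq") |>
    inner_join(select(mate_items, "individual_id", "read_name", "te_id",
                      "te_strand", "te_mate_strand", "item"),
               by = c("individual_id", "read_name"))
  arrange(out, .data$individual_id, .data$anchor_chrom, .data$anchor_pos,
          .data$item, .data$read_name)
}
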