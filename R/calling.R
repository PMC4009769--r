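## Clustering anchors and deriving event attributes.

#' Single-linkage clustering of anchor evidence
#'
#' Anchors are clustered separately per (chromosome, item): after sorting by
#' position, a new cluster starts whenever the gap to the previous anchor
#' exceeds the clustering window `insert_mean + window_multiplier *
#' insert_sd` (single linkage by a sorted linear sweep, O(n log n)).
#' Evidence from all individuals is pooled into the same clusters, which is
#' what lets low-coverage individuals borrow support from the population.
#'
#' @param evidence Evidence tibble from [extract_te_evidence()] (any number
#'   of individuals, same hierarchy level).
#' @param params A [calling_params()].
#' @return `evidence` with an added `cluster_id` column
#'   (`"<chrom>:<item>:<k>"`), sorted by chromosome, item and position.
#' @export
cluster_anchors <- function(evidence, params) {
  if (nrow(evidence) == 0) {
    evidence$cluster_id <- character(0)
    return(evidence)
  }
  window <- cluster_window(params)
  evidence |>
    arrange(.data$anchor_chrom, .data$item, .data$anchor_pos,
            .data$individual_id, .data$read_name, .data$te_id) |>
    group_by(.data$anchor_chrom, .data$item) |>
    mutate(.k = cumsum(c(1L, (diff(.data$anchor_pos) > window)))) |>
    ungroup() |>
    mutate(cluster_id = paste(.data$anchor_chrom, .data$item, .data$.k,
                              sep = ":")) |>
    select(-".k")
}

#' Orientation of an insertion relative to its source copy
#'
#' Each supporting pair votes from its strand geometry.  For an
#' inner-facing (FR) library, a fragment spanning a breakpoint yields an
#' anchor and a TE-side mate on *opposite* strands exactly when the inserted
#' copy runs in the same direction as the annotated source copy, so a pair
#' votes **parallel** when `anchor_strand != te_mate_strand` and **inverse**
#' otherwise.  The event is labelled by majority vote; ties are
#' `"uncertain"`, as is any cluster containing votes against a source copy
#' of unknown strand (relative orientation is undefined there).
#'
#' @param cluster Evidence rows of one cluster (columns `anchor_strand`,
#'   `te_mate_strand`, `te_strand`).
#' @return List with `orientation` (`"parallel"`, `"inverse"` or
#'   `"uncertain"`), `p_pairs`, `i_pairs`.
#' @export
classify_orientation <- function(cluster) {
  known <- cluster$te_strand %in% c("+", "-")
  par <- cluster$anchor_strand != cluster$te_mate_strand
  p <- sum(par & known)
  i <- sum(!par & known)
  orientation <- if (any(!known) || p == i) {
    "uncertain"
  } else if (p > i) "parallel" else "inverse"
  list(orientation = orientation, p_pairs = p, i_pairs = i)
}

#' New/old classification of a called event
#'
#' An event is `"old"` when some annotated locus of the *same item* (at the
#' active hierarchy level) contains the called position or lies within the
#' clustering window of it — at higher levels all loci of the item count,
#' e.g. any Copia called near any annotated Copia copy is "old".  Otherwise
#' the event is a `"new"` insertion.
#'
#' @param chrom,loc Called position (1-based).
#' @param item Item name at the active level.
#' @param annotation A [te_annotation()].
#' @param params A [calling_params()]; supplies the level and window.
#' @return `"new"` or `"old"` (vectorised over `chrom`/`loc`/`item`).
#' @export
classify_novelty <- function(chrom, loc, item, annotation, params) {
  window <- cluster_window(params)
  loci <- te_loci(annotation, unique(item), params$level)
  out <- rep("new", length(loc))
  if (nrow(loci) == 0) return(out)
  key <- switch(params$level,
                element = annotation$records$te_id,
                family = annotation$records$family,
                superfamily = annotation$records$superfamily,
                class = annotation$records$class)
  loci_item <- key[match(loci$te_id, annotation$records$te_id)]
  for (j in seq_along(loc)) {
    cand <- loci$chrom == chrom[j] & loci_item == item[j]
    if (!any(cand)) next
    d <- pmax(0, loci$start[cand] - loc[j], loc[j] - loci$end[cand])
    if (any(d <= window)) out[j] <- "old"
  }
  out
}

#' Format the event-type string of a source record
#'
#' Events are labelled `"TE+<class>/<superfamily>/<class>/<superfamily>"`,
#' e.g. `"TE+LTR/Copia/LTR/Copia"`.
#'
#' @param class,superfamily Class/order and superfamily names (vectorised).
#' @return Character vector of event-type strings.
#' @export
format_event_type <- function(class, superfamily) {
  paste0("TE+", class, "/", superfamily, "/", class, "/", superfamily)
}
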