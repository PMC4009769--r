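## Scoring calls against planted truth: 3-sigma/superfamily matching,
## FP/FN rates, region stratification.

#' Match calls to planted truth insertions
#'
#' Greedy nearest-first one-to-one matching.  A (call, truth) pair is
#' admissible iff both name the same superfamily and
#' `|loc - pos| <= window_multiplier * insert_sd` (default 3 standard
#' deviations of the insert size; the boundary counts as correct).  Each
#' call and each truth insertion is matched at most once.
#'
#' @param calls Tibble with columns `chrom`, `loc`, `superfamily` (a
#'   `te_call_set` called at superfamily level works after
#'   `tidy()` + renaming `item`; see [score_calls()] which does this).
#' @param truth Tibble with columns `chrom`, `pos`, `superfamily`.
#' @param params A [calling_params()]; supplies `insert_sd` and
#'   `window_multiplier`.
#' @return Tibble `call_idx`, `truth_idx`, `dist` (row indices into the
#'   inputs).
#' @export
match_calls <- function(calls, truth, params) {
  max_dist <- params$window_multiplier * params$insert_sd
  empty <- tibble(call_idx = integer(), truth_idx = integer(),
                  dist = numeric())
  if (nrow(calls) == 0 || nrow(truth) == 0) return(empty)
  cand <- inner_join(
    tibble(call_idx = seq_len(nrow(calls)), chrom = calls$chrom,
           loc = calls$loc, superfamily = calls$superfamily),
    tibble(truth_idx = seq_len(nrow(truth)), chrom = truth$chrom,
           pos = truth$pos, superfamily = truth$superfamily),
    by = c("chrom", "superfamily"), relationship = "many-to-many") |>
    mutate(dist = abs(.data$loc - .data$pos)) |>
    filter(.data$dist <= max_dist) |>
    arrange(.data$dist, .data$call_idx, .data$truth_idx)
  if (nrow(cand) == 0) return(empty)
  used_c <- logical(nrow(calls)); used_t <- logical(nrow(truth))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ci <- cand$call_idx[k]; ti <- cand$truth_idx[k]
    if (!used_c[ci] && !used_t[ti]) {
      keep[k] <- TRUE; used_c[ci] <- TRUE; used_t[ti] <- TRUE
    }
  }
  cand[keep, c("call_idx", "truth_idx", "dist")]
}

#' False-positive / false-negative rates of a call set
#'
#' `fp_rate` is the ratio of false calls to all calls (0 when there are no
#' calls); `fn_rate` the ratio of missed insertions to all insertions
#' planted.  With a region partition the rates are additionally stratified
#' by region class (calls counted by call position, truth by truth
#' position), with an `"overall"` row.
#'
#' When `truth` carries an `individual_id` column and `calls` is a
#' `te_call_set`, matching is done per individual against the events that
#' individual carries — an event only recovers an insertion for the
#' individuals it is assigned to.
#'
#' @param calls A `te_call_set`, or a tibble with `chrom`, `loc`,
#'   `superfamily` (and optionally `individual_id`).
#' @param truth Truth tibble with `chrom`, `pos`, `superfamily` (optionally
#'   `individual_id`).
#' @param annotation A [te_annotation()]; used to map call items/source
#'   elements to superfamilies.
#' @param params A [calling_params()].
#' @param partition Optional region partition tibble (`chrom`, `start`,
#'   `end`, `region`), e.g. from [read_region_partition()].
#' @return Tibble with one row per region class (plus `"overall"`):
#'   `region`, `n_truth`, `n_calls`, `n_correct`, `fp_rate`, `fn_rate`.
#' @export
score_calls <- function(calls, truth, annotation, params, partition = NULL) {
  cdf <- call_frame(calls, annotation, params)
  if ("individual_id" %in% names(truth) && "individual_id" %in% names(cdf)) {
    ids <- unique(truth$individual_id)
    pieces <- lapply(ids, function(id) {
      m <- match_calls(cdf[cdf$individual_id == id, ],
                       truth[truth$individual_id == id, ], params)
      cc <- cdf[cdf$individual_id == id, ]
      tt <- truth[truth$individual_id == id, ]
      cc$matched <- seq_len(nrow(cc)) %in% m$call_idx
      tt$matched <- seq_len(nrow(tt)) %in% m$truth_idx
      list(calls = cc, truth = tt)
    })
    cdf <- bind_rows(lapply(pieces, `[[`, "calls"))
    tdf <- bind_rows(lapply(pieces, `[[`, "truth"))
  } else {
    m <- match_calls(cdf, truth, params)
    cdf$matched <- seq_len(nrow(cdf)) %in% m$call_idx
    tdf <- truth
    tdf$matched <- seq_len(nrow(tdf)) %in% m$truth_idx
  }
  cdf$region <- assign_region(cdf$chrom, cdf$loc, partition)
  tdf$region <- assign_region(tdf$chrom, tdf$pos, partition)
  regions <- unique(c("overall",
                      if (!is.null(partition)) sort(unique(partition$region))))
  bind_rows(lapply(regions, function(rg) {
    cc <- if (rg == "overall") cdf else cdf[cdf$region == rg, ]
    tt <- if (rg == "overall") tdf else tdf[tdf$region == rg, ]
    tibble(region = rg,
           n_truth = nrow(tt), n_calls = nrow(cc),
           n_correct = sum(cc$matched),
           fp_rate = if (nrow(cc) == 0) 0 else mean(!cc$matched),
           fn_rate = if (nrow(tt) == 0) 0 else mean(!tt$matched))
  }))
}

## normalise calls input into chrom/loc/superfamily (+ individual_id rows
## for carriers when a full call set is given)
call_frame <- function(calls, annotation, params) {
  if (inherits(calls, "te_call_set")) {
    ev <- calls$events
    sf <- te_item(annotation, ev$te_id, "superfamily")
    base <- tibble(event_id = ev$event_id, chrom = ev$chrom, loc = ev$loc,
                   superfamily = sf)
    cf <- left_join(calls$carriers, base, by = "event_id")
    return(select(cf, "individual_id", "chrom", "loc", "superfamily"))
  }
  calls <- as_tibble(calls)
  if (!"superfamily" %in% names(calls)) {
    if ("te_id" %in% names(calls)) {
      calls$superfamily <- te_item(annotation, calls$te_id, "superfamily")
    } else if ("item" %in% names(calls) && params$level == "superfamily") {
      calls$superfamily <- calls$item
    } else {
      abort("calls need a superfamily (or te_id) column")
    }
  }
  calls
}

assign_region <- function(chrom, pos, partition) {
  if (is.null(partition)) return(rep("overall", length(pos)))
  out <- rep(NA_character_, length(pos))
  for (k in seq_len(nrow(partition))) {
    hit <- chrom == partition$chrom[k] & pos >= partition$start[k] &
      pos <= partition$end[k]
    out[hit & is.na(out)] <- partition$region[k]
  }
  out
}

#' Read a region partition file
#'
#' TSV with columns `chrom`, `start`, `end`, `region` labelling each
#' chromosome stretch as `arm`, `pericentromere` or `centromere` (intervals
#' 1-based inclusive, disjoint, covering each chromosome).  Repeat-dense
#' pericentromeres map worse and show higher error rates, so benchmark
#' results are reported per region class.
#'
#' @param path Path to the TSV.  The package ships *approximate*
#'   *Arabidopsis thaliana* (TAIR10) boundaries (2 Mb centromere cores,
#'   3 Mb pericentromeric flanks around published centromere midpoints) in
#'   `system.file("extdata", "athaliana_regions_approx.tsv", package =
#'   "tescout")`; treat them as a convenience default, not as exact
#'   annotation.
#' @return Tibble with the four columns.
#' @export
read_region_partition <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "region")
  if (!all(need %in% names(p))) {
    abort(paste0("partition must have columns: ", paste(need, collapse = ", ")))
  }
  p[need]
}
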