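## Population-level event calling, the call-set container, and output files.

#' Call TE events on a population of individuals
#'
#' Pools the evidence of all individuals, clusters it with
#' [cluster_anchors()], and emits one event per cluster in which at least
#' one individual reaches `min_support` pairs.  Any other individual with at
#' least `rescue_min_support` pairs in the same cluster is marked a carrier
#' ("population rescue": a genuine event confidently seen in one individual
#' rescues low-coverage evidence in others).  Only carrier evidence enters
#' the reported position, support and orientation.
#'
#' Per event the call reports the median anchor position (rounded down), the
#' pooled carrier support, the majority orientation
#' ([classify_orientation()]), the new/old status ([classify_novelty()]),
#' and the length of the annotated reference copy of the most-supported
#' source element in the cluster (ties broken by lexicographically smallest
#' `te_id`).
#'
#' @param evidence Either one evidence tibble carrying an `individual_id`
#'   column, or a *named* list of per-individual evidence tibbles (names =
#'   individual ids; duplicate names are an error).
#' @param annotation A [te_annotation()].
#' @param params A [calling_params()].
#' @return A `te_call_set`: list with `events` (tibble sorted by chromosome
#'   and position), `carriers` (long tibble `event_id`, `individual_id`,
#'   `n_pairs`), `presence` (wide 0/1 tibble, one column per individual),
#'   `individuals`, `params`.
#' @examples
#' ## see vignette("te-insertion-calling") for an end-to-end example
#' @export
call_te_events <- function(evidence, annotation, params) {
  if (is.list(evidence) && !is.data.frame(evidence)) {
    ids <- names(evidence)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
      abort("per-individual evidence lists need unique, non-empty names")
    }
    evidence <- bind_rows(lapply(ids, function(id) {
      ev <- evidence[[id]]
      ev$individual_id <- id
      ev
    }))
  }
  individuals <- sort(unique(evidence$individual_id))
  cl <- cluster_anchors(evidence, params)

  events <- list()
  carriers <- list()
  if (nrow(cl) > 0) {
    chunks <- split(cl, factor(cl$cluster_id, levels = unique(cl$cluster_id)))
    for (cc in chunks) {
      ## support per individual; one confident carrier required
      per_ind <- table(cc$individual_id)
      if (max(per_ind) < params$min_support) next
      carrier_ids <- names(per_ind)[per_ind >= params$rescue_min_support]
      cc <- cc[cc$individual_id %in% carrier_ids, ]
      ev <- summarise_cluster(cc, annotation, params)
      events[[length(events) + 1L]] <- ev
      carriers[[length(carriers) + 1L]] <-
        tibble(event_id = ev$event_id,
               individual_id = names(per_ind)[per_ind >= params$rescue_min_support],
               n_pairs = as.integer(per_ind[per_ind >= params$rescue_min_support]))
    }
  }
  events <- if (length(events)) {
    arrange(bind_rows(events), .data$chrom, .data$loc, .data$item)
  } else {
    tibble(event_id = character(), chrom = character(), loc = integer(),
           len = integer(), item = character(), event_type_ref = character(),
           non_ref_counts = integer(), anc_status = character(),
           read_pair_support = integer(), call_method = character(),
           orientation = character(), p_pairs = integer(),
           i_pairs = integer(), novelty = character(), te_id = character())
  }
  carriers <- if (length(carriers)) bind_rows(carriers) else {
    tibble(event_id = character(), individual_id = character(),
           n_pairs = integer())
  }
  carriers <- carriers[match_order(carriers$event_id, events$event_id), ]

  presence <- presence_matrix(events, carriers, individuals)
  structure(list(events = events, carriers = carriers, presence = presence,
                 individuals = individuals, params = params),
            class = "te_call_set")
}

match_order <- function(x, levels) order(match(x, levels), method = "radix")

summarise_cluster <- function(cc, annotation, params) {
  rec <- annotation$records
  ## most-supported source element; tie -> lexicographically smallest te_id
  src <- sort(table(cc$te_id), decreasing = TRUE)
  src_id <- sort(names(src)[src == max(src)])[1]
  src_rec <- rec[rec$te_id == src_id, ]
  loc <- as.integer(floor(median(cc$anchor_pos)))
  item <- cc$item[1]
  chrom <- cc$anchor_chrom[1]
  novelty <- classify_novelty(chrom, loc, item, annotation, params)
  ori <- classify_orientation(cc)
  if (novelty == "old") {
    ori <- list(orientation = "uncertain", p_pairs = NA_integer_,
                i_pairs = NA_integer_)
  } else if (ori$orientation == "uncertain") {
    ori$p_pairs <- NA_integer_
    ori$i_pairs <- NA_integer_
  }
  tibble(
    event_id = paste(chrom, loc, item, sep = ":"),
    chrom = chrom,
    loc = loc,
    len = as.integer(src_rec$end - src_rec$start + 1L),
    item = item,
    event_type_ref = format_event_type(src_rec$class, src_rec$superfamily),
    non_ref_counts = length(unique(cc$individual_id)),
    anc_status = "N",
    read_pair_support = nrow(cc),
    call_method = "PairEndTE",
    orientation = ori$orientation,
    p_pairs = as.integer(ori$p_pairs),
    i_pairs = as.integer(ori$i_pairs),
    novelty = novelty,
    te_id = src_id
  )
}

presence_matrix <- function(events, carriers, individuals) {
  base <- tibble(event_id = events$event_id)
  for (id in individuals) base[[id]] <- 0L
  if (nrow(carriers) > 0) {
    for (k in seq_len(nrow(carriers))) {
      base[base$event_id == carriers$event_id[k],
           carriers$individual_id[k]] <- 1L
    }
  }
  base
}

#' @export
print.te_call_set <- function(x, ...) {
  cat("<te_call_set> ", nrow(x$events), " events across ",
      length(x$individuals), " individual(s) at level '",
      x$params$level, "'\n", sep = "")
  if (nrow(x$events) > 0) {
    print(head(select(x$events, -"event_id"), 10))
    if (nrow(x$events) > 10) cat("... and", nrow(x$events) - 10, "more\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TE call set
#'
#' @param x A `te_call_set`.
#' @param ... Unused.
#' @return The events tibble.
#' @method tidy te_call_set
#' @export
tidy.te_call_set <- function(x, ...) x$events

#' One-row summary of a TE call set
#'
#' @param x A `te_call_set`.
#' @param ... Unused.
#' @return Tibble with event, carrier and support summaries.
#' @method glance te_call_set
#' @export
glance.te_call_set <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_new = sum(x$events$novelty == "new"),
    n_old = sum(x$events$novelty == "old"),
    n_individuals = length(x$individuals),
    total_support = sum(x$events$read_pair_support),
    mean_support = if (nrow(x$events)) mean(x$events$read_pair_support) else NA_real_,
    level = x$params$level
  )
}

#' Write the two caller output files
#'
#' Writes (a) the tab-separated info file, one line per event with columns
#' `chr`, `loc`, `len`, `event_type_ref`, `non_ref_counts`, `anc_status`,
#' `read_pair_support`, a literal `"|"` placeholder for four unused columns
#' (`bp_range1`, `bp_range2`, `four_gamete_left`, `four_gamete_right`),
#' `call_method` (constant `"PairEndTE"`), `orientation`, `p_pairs`,
#' `i_pairs`, `new_old` — pair-count cells are left empty when the
#' orientation is `"uncertain"` — and (b) the CSV presence/absence matrix
#' (events x individuals, 0/1) with a header row of individual ids.
#'
#' @param calls A `te_call_set` from [call_te_events()].
#' @param out_prefix Output path prefix; writes `<prefix>_info.tsv` and
#'   `<prefix>_presence.csv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_te_calls <- function(calls, out_prefix) {
  info_path <- paste0(out_prefix, "_info.tsv")
  csv_path <- paste0(out_prefix, "_presence.csv")
  ev <- calls$events
  info <- tibble(
    chr = ev$chrom, loc = ev$loc, len = ev$len,
    event_type_ref = ev$event_type_ref,
    non_ref_counts = ev$non_ref_counts,
    anc_status = ev$anc_status,
    read_pair_support = ev$read_pair_support,
    unused = rep("|", nrow(ev)),
    call_method = ev$call_method,
    orientation = ev$orientation,
    p_pairs = ifelse(is.na(ev$p_pairs), "", as.character(ev$p_pairs)),
    i_pairs = ifelse(is.na(ev$i_pairs), "", as.character(ev$i_pairs)),
    new_old = ev$novelty
  )
  readr::write_tsv(info, info_path, na = "", progress = FALSE)
  readr::write_csv(calls$presence, csv_path, progress = FALSE)
  invisible(c(info = info_path, presence = csv_path))
}

#' Read caller output files back
#'
#' Round-trips the files written by [write_te_calls()] into an events tibble
#' and presence matrix.
#'
#' @param out_prefix The prefix passed to [write_te_calls()].
#' @return List with `events` and `presence` tibbles.
#' @export
read_te_calls <- function(out_prefix) {
  info <- readr::read_tsv(paste0(out_prefix, "_info.tsv"),
                          col_types = readr::cols(
                            chr = "c", loc = "i", len = "i",
                            event_type_ref = "c", non_ref_counts = "i",
                            anc_status = "c", read_pair_support = "i",
                            unused = "c", call_method = "c",
                            orientation = "c", p_pairs = "i", i_pairs = "i",
                            new_old = "c"),
                          progress = FALSE)
  presence <- readr::read_csv(paste0(out_prefix, "_presence.csv"),
                              show_col_types = FALSE, progress = FALSE)
  events <- tibble(
    chrom = info$chr, loc = info$loc, len = info$len,
    event_type_ref = info$event_type_ref,
    non_ref_counts = info$non_ref_counts,
    anc_status = info$anc_status,
    read_pair_support = info$read_pair_support,
    call_method = info$call_method,
    orientation = info$orientation,
    p_pairs = info$p_pairs, i_pairs = info$i_pairs,
    novelty = info$new_old
  )
  list(events = events, presence = presence)
}
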