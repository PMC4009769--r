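## Windowed pairwise-difference diversity on presence/absence matrices and
## the TE-vs-SNP window correlation.

#' Windowed pairwise-difference diversity
#'
#' For each non-overlapping window, the mean over all unordered pairs of
#' individuals of the number of events at which they differ, normalised to
#' 1 bp of window.  Events count once each regardless of their length and
#' are assigned to windows by position.  Computed by the equivalent
#' frequency formula: per event with carrier frequency `p` among `n`
#' individuals the pairwise difference contribution is
#' `2 * p * (1 - p) * n / (n - 1)`; windows sum these and divide by
#' `window_size`.
#'
#' @param presence Presence/absence tibble: an `event_id` column (or row
#'   identifier as first column) plus one 0/1 column per individual — the
#'   `presence` slot of a `te_call_set`, or any site-by-individual genotype
#'   matrix in the same shape (e.g. SNPs).
#' @param positions Tibble `event_id`, `chrom`, `loc` giving each row's
#'   genomic position.  For a `te_call_set`, `tidy(calls)` provides this.
#' @param window_size Window width in bp (default 20000).
#' @param chrom_lengths Optional named vector; when given, every window of
#'   each chromosome appears in the track (value 0 where no events fall),
#'   otherwise windows span up to the last observed event.
#' @return A `diversity_track` tibble: `chrom`, `window_start`,
#'   `window_end`, `n_events`, `value` (mean pairwise difference per bp).
#' @examples
#' pres <- tibble::tibble(event_id = "e1", a = 1L, b = 0L)
#' pos <- tibble::tibble(event_id = "e1", chrom = "chr1", loc = 1500L)
#' pairwise_diversity(pres, pos)$value  # 1/20000
#' @export
pairwise_diversity <- function(presence, positions, window_size = 20000,
                               chrom_lengths = NULL) {
  presence <- as_tibble(presence)
  id_col <- names(presence)[1]
  ind_cols <- setdiff(names(presence), id_col)
  n <- length(ind_cols)
  if (n < 2) abort("pairwise diversity needs >= 2 individuals")
  x <- as.matrix(presence[ind_cols])
  storage.mode(x) <- "numeric"
  p <- rowMeans(x)
  contrib <- 2 * p * (1 - p) * n / (n - 1)

  df <- tibble(event_id = presence[[id_col]], contrib = contrib) |>
    inner_join(select(positions, event_id = 1, "chrom", "loc"),
               by = "event_id") |>
    mutate(window_start = floor((.data$loc - 1) / window_size) *
             window_size + 1) |>
    group_by(.data$chrom, .data$window_start) |>
    summarise(n_events = n(), value = sum(.data$contrib) / window_size,
              .groups = "drop")

  grid <- if (!is.null(chrom_lengths)) {
    bind_rows(lapply(names(chrom_lengths), function(ch) {
      tibble(chrom = ch,
             window_start = seq(1, chrom_lengths[[ch]], by = window_size))
    }))
  } else {
    df |> group_by(.data$chrom) |>
      summarise(last = max(.data$window_start), .groups = "drop") |>
      rowwise() |>
      reframe(chrom = .data$chrom,
              window_start = seq(1, .data$last, by = window_size))
  }
  out <- left_join(grid, df, by = c("chrom", "window_start")) |>
    mutate(n_events = coalesce(.data$n_events, 0L),
           value = coalesce(.data$value, 0),
           window_end = .data$window_start + window_size - 1) |>
    select("chrom", "window_start", "window_end", "n_events", "value") |>
    arrange(.data$chrom, .data$window_start)
  class(out) <- c("diversity_track", class(out))
  attr(out, "window_size") <- window_size
  out
}

#' Correlation between two windowed diversity tracks
#'
#' Joins the two tracks on (chromosome, window) and correlates their values
#' over the windows where *both* tracks contain at least one event — a
#' window with no event in either track is skipped entirely.
#'
#' @param track_a,track_b `diversity_track` tibbles on the same window grid
#'   (e.g. TE-event diversity vs SNP diversity).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble `estimate`, `p_value`, `n_windows`, `method`.
#'   With fewer than 3 surviving windows the correlation is undefined and
#'   reported as `NA` (with a warning).
#' @export
window_correlation <- function(track_a, track_b, method = c("pearson",
                                                            "spearman")) {
  method <- match.arg(method)
  j <- inner_join(
    select(as_tibble(track_a), "chrom", "window_start", a_n = "n_events",
           a = "value"),
    select(as_tibble(track_b), "chrom", "window_start", b_n = "n_events",
           b = "value"),
    by = c("chrom", "window_start")) |>
    filter(.data$a_n > 0, .data$b_n > 0)
  if (nrow(j) < 3) {
    warn("fewer than 3 windows with events in both tracks; correlation undefined")
    return(tibble(estimate = NA_real_, p_value = NA_real_,
                  n_windows = nrow(j), method = method))
  }
  ct <- suppressWarnings(cor.test(j$a, j$b, method = method))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n_windows = nrow(j), method = method)
}
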