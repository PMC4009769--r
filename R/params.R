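#' Calling parameters
#'
#' Bundles every tunable of the evidence-collection and clustering stages.
#' The clustering (and novelty-matching) distance is
#' `insert_mean + window_multiplier * insert_sd`: two anchors support the
#' same insertion only if their distance can be explained by the fragment
#' size distribution.
#'
#' @param level Hierarchy level at which TE-side hits are named and clustered:
#'   `"element"`, `"family"`, `"superfamily"` or `"class"`.  Higher levels
#'   trade specificity for reliability because reads mapping inside highly
#'   similar elements cannot distinguish them.
#' @param min_anchor_mapq Minimum mapping quality (Phred) for the anchor
#'   read, the end mapped outside all TEs.  The TE-side mate has no MAPQ
#'   requirement: multi-mapping inside TE copies is expected.
#' @param min_support Minimum number of supporting read pairs a single
#'   individual must contribute before a cluster becomes an event.
#' @param insert_mean,insert_sd Mean and standard deviation of the library
#'   insert (fragment) size in bp.
#' @param window_multiplier How many standard deviations of the insert size
#'   the clustering window extends beyond the mean (default 3).
#' @param rescue_min_support Once one individual passes `min_support`, any
#'   other individual with at least this many pairs in the same cluster is
#'   marked a carrier ("population rescue" for low-coverage individuals).
#'
#' @return A list of class `"calling_params"`.
#' @examples
#' p <- calling_params(level = "superfamily", insert_mean = 300, insert_sd = 100)
#' cluster_window(p)  # 300 + 3 * 100
#' @export
calling_params <- function(level = c("superfamily", "family", "element", "class"),
                           min_anchor_mapq = 20L,
                           min_support = 3L,
                           insert_mean = 300,
                           insert_sd = 100,
                           window_multiplier = 3,
                           rescue_min_support = 1L) {
  level <- match.arg(level)
  num <- c(min_anchor_mapq = min_anchor_mapq, min_support = min_support,
           insert_mean = insert_mean, insert_sd = insert_sd,
           window_multiplier = window_multiplier,
           rescue_min_support = rescue_min_support)
  if (any(!is.finite(num)) || any(num <= 0 & names(num) != "min_anchor_mapq") ||
      min_anchor_mapq < 0) {
    abort("all numeric calling parameters must be positive (min_anchor_mapq >= 0)")
  }
  structure(list(level = level,
                 min_anchor_mapq = as.integer(min_anchor_mapq),
                 min_support = as.integer(min_support),
                 insert_mean = insert_mean,
                 insert_sd = insert_sd,
                 window_multiplier = window_multiplier,
                 rescue_min_support = as.integer(rescue_min_support)),
            class = "calling_params")
}

#' @rdname calling_params
#' @param params A `calling_params` object.
#' @export
cluster_window <- function(params) {
  params$insert_mean + params$window_multiplier * params$insert_sd
}

#' @export
print.calling_params <- function(x, ...) {
  cat("<calling_params>\n")
  cat("  level:", x$level, "\n")
  cat("  min_anchor_mapq:", x$min_anchor_mapq,
      " min_support:", x$min_support,
      " rescue_min_support:", x$rescue_min_support, "\n")
  cat("  insert:", x$insert_mean, "+/-", x$insert_sd,
      " window:", cluster_window(x), "bp\n")
  invisible(x)
}

#' Read-simulation parameters
#'
#' @param coverage Fold coverage of the sample genome.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-size distribution (bp); fragments are
#'   drawn Normal(`insert_mean`, `insert_sd`) truncated below at
#'   `2 * read_length`.
#' @param base_error_rate Per-base substitution error probability.
#' @param n_snps Number of SNPs to plant when mutating a sample genome.
#'
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(coverage = 20,
                       read_length = 100L,
                       insert_mean = 300,
                       insert_sd = 100,
                       base_error_rate = 0,
                       n_snps = 0L) {
  stopifnot(coverage > 0, read_length > 0, insert_mean > 0, insert_sd > 0,
            base_error_rate >= 0, base_error_rate < 1, n_snps >= 0)
  if (insert_mean <= read_length) {
    abort("insert_mean must exceed read_length")
  }
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_error_rate = base_error_rate, n_snps = as.integer(n_snps)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> coverage", x$coverage, "x, reads", x$read_length,
      "bp, insert", x$insert_mean, "+/-", x$insert_sd,
      "bp, error", x$base_error_rate, "\n")
  invisible(x)
}
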