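#' Estimate the probability that a sequenced spacer appears within a pair
#'
#' From a per-sample spacer table, the fraction of spacer observations
#' that come from reads carrying two or more spacers. This pair
#' probability `p` drives the completeness test for single-spacer
#' mini-array candidates: a spacer from a long array should frequently be
#' sequenced next to a neighbour, while a genuine one-spacer mini-array
#' can never be.
#'
#' @param spacers Spacer table with columns `read_id` and (optionally)
#'   `sample_id`; one row per spacer observation.
#' @param sample_id Restrict to one sample if the table carries several.
#' @return List of class `pair_probability`: `p`, `n_obs_single`,
#'   `n_obs_multi`, `sample_id`.
#' @export
estimate_pair_probability <- function(spacers, sample_id = NULL) {
  stopifnot("read_id" %in% names(spacers))
  if (!is.null(sample_id) && "sample_id" %in% names(spacers)) {
    spacers <- spacers[spacers$sample_id == sample_id, , drop = FALSE]
  }
  if (nrow(spacers) == 0) stop("no spacer-bearing reads in sample")
  per_read <- table(spacers$read_id)
  multi_reads <- names(per_read)[per_read >= 2L]
  n_multi <- sum(per_read[per_read >= 2L])
  n_total <- nrow(spacers)
  structure(list(
    p = as.numeric(n_multi / n_total),
    n_obs_single = as.integer(n_total - n_multi),
    n_obs_multi = as.integer(n_multi),
    sample_id = if (is.null(sample_id)) NA_character_ else sample_id
  ), class = "pair_probability")
}

#' @export
print.pair_probability <- function(x, ...) {
  cat(sprintf(
    "Pair probability p = %.4f (%d of %d spacer observations in reads ",
    x$p, x$n_obs_multi, x$n_obs_multi + x$n_obs_single))
  cat("with >= 2 spacers)\n")
  invisible(x)
}

#' Completeness P-value for a single-spacer mini-array candidate
#'
#' Probability of never observing a neighbouring pair for a spacer
#' sequenced `N` times if it actually sits in a longer array:
#' `P = (1 - p)^N`, with `p` the per-sample pair probability. Small `P`
#' supports the candidate being a complete one-spacer mini-array.
#'
#' @param p Pair probability in `[0, 1]`.
#' @param N Times the spacer was sequenced (integer >= 1).
#' @return P-value in `(0, 1]`.
#' @examples
#' single_spacer_pvalue(0.5, 100)  # ~7.9e-31
#' @export
single_spacer_pvalue <- function(p, N) {
  if (any(N < 1) || any(N != round(N))) stop("N must be an integer >= 1")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  (1 - p)^N
}

#' Completeness P-value for a two-spacer mini-array candidate
#'
#' For a pair sequenced `N` times: each spacer has probability 0.5 of
#' appearing first in a pair, so observing one spacer only ever first and
#' the other only ever second across the remaining `N - 1` pairs has
#' probability `0.5^(N-1)` per side; the array is incomplete on some side
#' with probability `(1 - 0.5^(N-1))^2`, giving
#' `P = 1 - (1 - 0.5^(N-1))^2` that the two-spacer array is complete.
#'
#' @param N Times the pair was sequenced (integer >= 1).
#' @return P-value in `(0, 1]`.
#' @examples
#' two_spacer_pvalue(20)  # ~3.8e-06
#' @export
two_spacer_pvalue <- function(N) {
  if (any(N < 1) || any(N != round(N))) stop("N must be an integer >= 1")
  x <- 0.5^(N - 1)
  # algebraically 1 - (1 - x)^2, written to stay exact when x underflows
  # the (1 - x)^2 rounding at ~1e-17
  x * (2 - x)
}

#' Minimal abundance reaching significance for a mini-array candidate
#'
#' Smallest integer `N` whose completeness P-value falls below `alpha`
#' for a candidate of `k_spacers` (1 or 2) spacers.
#'
#' @param alpha Significance level in `(0, 1)`.
#' @param p Pair probability (needed for `k_spacers = 1`).
#' @param k_spacers 1 or 2.
#' @return Integer `N` with `P(N) < alpha <= P(N - 1)`.
#' @export
min_abundance_threshold <- function(alpha, p = NULL, k_spacers) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!k_spacers %in% c(1L, 2L)) stop("k_spacers must be 1 or 2")
  if (k_spacers == 1L) {
    if (is.null(p)) stop("p is required for single-spacer candidates")
    if (p <= 0) stop("no finite threshold when p = 0")
    pv <- function(N) single_spacer_pvalue(p, N)
  } else {
    pv <- function(N) two_spacer_pvalue(N)
  }
  N <- 1L
  while (pv(N) >= alpha) {
    N <- N + 1L
    if (N > 1e7) stop("no threshold below 1e7; alpha unreachable")
  }
  N
}

#' Call complete mini-CRISPR arrays among 1- and 2-spacer candidates
#'
#' Candidates are the reconstructed paths of length 1 or 2 lying in graph
#' components whose maximum node eccentricity is at most 2 (a spacer
#' embedded in a long array lies on a long path and is screened out).
#' Each candidate is tested against the null hypothesis that it is a
#' truncated fragment of a longer array; it is called a complete
#' mini-array when its completeness P-value is below `alpha` AND its
#' abundance `N` reaches the fixed abundance threshold for its size (both
#' gates are reported separately). The default thresholds n = 100 (one
#' spacer) and n = 20 (two spacers) are deliberately conservative: they
#' exceed the formula minima returned by [min_abundance_threshold()].
#'
#' @param paths An [reconstruct_paths()] result.
#' @param eccentricity A [node_eccentricity()] result for the same graph.
#' @param cluster_abundance Named vector of per-cluster total counts.
#' @param pair_probability A [estimate_pair_probability()] result (or a
#'   plain probability).
#' @param alpha Significance level (default 0.01).
#' @param thresholds Named vector `c("1" = 100, "2" = 20)` of abundance
#'   thresholds by candidate size.
#' @param sample_id Sample label for the report.
#' @return Object of class `mini_array_calls`: data frame with one row
#'   per candidate (`cluster_ids`, `k`, `N`, `p_used`, `p_value`,
#'   `passes_alpha`, `passes_threshold`, `complete`, `threshold_used`).
#' @export
call_mini_arrays <- function(paths, eccentricity, cluster_abundance,
                             pair_probability, alpha = 0.01,
                             thresholds = c(`1` = 100L, `2` = 20L),
                             sample_id = NA_character_) {
  stopifnot(inherits(paths, "array_paths"))
  p <- if (inherits(pair_probability, "pair_probability")) {
    pair_probability$p
  } else as.numeric(pair_probability)
  ecc <- stats::setNames(eccentricity$eccentricity,
                         eccentricity$cluster_id)
  comp_max_ecc <- tapply(ecc[names(paths$components)], paths$components,
                         max)
  wmap <- stats::setNames(paths$edges$weight,
                          paste(paths$edges$from, paths$edges$to,
                                sep = "\r"))
  rows <- list()
  for (i in seq_along(paths$paths)) {
    pth <- paths$paths[[i]]
    k <- length(pth)
    if (k > 2L) next
    comp <- paths$components[[pth[1]]]
    if (comp_max_ecc[[as.character(comp)]] > 2L) next
    if (k == 1L) {
      N <- as.integer(cluster_abundance[[pth[1]]])
      pv <- single_spacer_pvalue(p, N)
    } else {
      N <- as.integer(wmap[[paste(pth[1], pth[2], sep = "\r")]])
      pv <- two_spacer_pvalue(N)
    }
    thr <- as.integer(thresholds[[as.character(k)]])
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_ids = paste(pth, collapse = ","), k = k, N = N,
      p_used = p, p_value = pv,
      passes_alpha = pv < alpha, passes_threshold = N >= thr,
      complete = pv < alpha && N >= thr,
      threshold_used = thr, sample_id = sample_id
    )
  }
  calls <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cluster_ids = character(0), k = integer(0), N = integer(0),
               p_used = numeric(0), p_value = numeric(0),
               passes_alpha = logical(0), passes_threshold = logical(0),
               complete = logical(0), threshold_used = integer(0),
               sample_id = character(0))
  }
  structure(calls, class = c("mini_array_calls", "data.frame"))
}

#' @export
print.mini_array_calls <- function(x, ...) {
  cat(sprintf("Mini-CRISPR array candidates: %d (%d called complete)\n",
              nrow(x), sum(x$complete)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Immunity contribution of long-array versus mini-array spacers
#'
#' For every sample and target genome, sums the abundance of the spacer
#' clusters with a protospacer hit in that genome, split by the source
#' class of the cluster (long host array, viral mini-array, or unknown).
#' The totals compare host-mediated and virus-mediated CRISPR immunity
#' against each targeted genome.
#'
#' @param hits Protospacer hit table with columns `cluster_id` and
#'   `genome_id`.
#' @param abundance Cluster x sample abundance matrix.
#' @param source_class Named vector mapping cluster id to `"long"` or
#'   `"mini"` (missing clusters are counted as `"unknown"`, with a
#'   warning).
#' @return Data frame (`sample_id`, `genome_id`, `source_class`,
#'   `total_abundance`).
#' @export
immunity_contributions <- function(hits, abundance, source_class) {
  if (nrow(hits) == 0) {
    return(data.frame(sample_id = character(0), genome_id = character(0),
                      source_class = character(0),
                      total_abundance = numeric(0)))
  }
  cls <- source_class[hits$cluster_id]
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " targeting cluster(s) without a source ",
            "class; counted as 'unknown'")
    cls[is.na(cls)] <- "unknown"
  }
  targeting <- unique(data.frame(cluster_id = hits$cluster_id,
                                 genome_id = hits$genome_id,
                                 source_class = unname(cls)))
  rows <- list()
  for (s in colnames(abundance)) {
    ab <- abundance[, s]
    agg <- stats::aggregate(
      list(total_abundance = ab[targeting$cluster_id]),
      by = list(genome_id = targeting$genome_id,
                source_class = targeting$source_class),
      FUN = sum
    )
    agg$sample_id <- s
    rows[[s]] <- agg[, c("sample_id", "genome_id", "source_class",
                         "total_abundance")]
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$sample_id, out$genome_id, out$source_class), ,
      drop = FALSE]
}
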