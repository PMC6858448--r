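# distance scoring: 0 for match, -1 for mismatch or gap column, so the
# optimal score is minus the (mismatch + internal gap) count
.DIST_MAT <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 0
  m["N", ] <- -1
  m[, "N"] <- -1
  m
})

# identity of one query against many centroids under free end gaps;
# identity = matches / aligned columns excluding terminal gap columns
# (internal gaps count as mismatched columns). The denominator is floored
# at the shorter sequence's length so that a degenerate short
# suffix/prefix overlap between unrelated sequences does not score as
# identity 1: any unaligned overhang of the shorter sequence counts as
# non-matching.
.sgi_batch <- function(centroids, query) {
  if (length(centroids) == 0) return(numeric(0))
  .sg_identity_many_cpp(query, centroids)
}

#' Semi-global (free end gap) identity between two sequences
#'
#' Optimal alignment with zero penalty for terminal gaps; identity is the
#' fraction of matching columns among aligned columns, excluding terminal
#' gap columns and counting internal gaps as mismatches. The denominator
#' is floored at the shorter sequence's length, so an alignment that
#' degenerates to a short perfect overlap between otherwise unrelated
#' sequences does not count as full identity. This is the identity used
#' for 85%-threshold spacer clustering, where spacers of different
#' lengths must be comparable without penalising length differences at
#' the ends.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' semi_global_identity("AAAAAAAAAA", "TTAAAAAAAAAATT")  # 1: end gaps free
#' @export
semi_global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- .sg_pair_cpp(toupper(a), toupper(b))
  r[["matches"]] / max(r[["cols"]], min(nchar(a), nchar(b)))
}

#' Greedy centroid clustering of spacers at an identity threshold
#'
#' Deduplicates the observed spacer sequences, processes unique sequences
#' in descending abundance (ties broken lexicographically), and assigns
#' each to the first existing centroid reaching the identity threshold
#' under [semi_global_identity()], founding a new cluster otherwise. This
#' greedy-centroid scheme is deterministic and mirrors standard
#' centroid-based clustering practice; cluster abundance is the summed
#' read count of the members, per sample.
#'
#' @param sequences Character vector of spacer observations (one entry per
#'   observation; duplicates are the abundance signal).
#' @param samples Optional sample label per observation.
#' @param threshold Identity threshold (default 0.85).
#' @return Object of class `spacer_clusters`: `clusters` data frame
#'   (`cluster_id`, `centroid`, `n_members`, `total`), `abundance` matrix
#'   (clusters x samples), `assignment` (unique sequence -> `cluster_id`)
#'   and `obs_cluster` (per input observation).
#' @export
cluster_spacers <- function(sequences, samples = NULL, threshold = 0.85) {
  stopifnot(length(sequences) > 0)
  if (is.null(samples)) samples <- rep("sample1", length(sequences))
  stopifnot(length(samples) == length(sequences))

  tab <- table(sequences)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]
  cnt <- cnt[ord]

  centroids <- character(0)
  assign_idx <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    hit <- .sg_first_match_cpp(uniq[i], centroids, threshold)
    if (hit == 0L) {
      centroids <- c(centroids, uniq[i])
      hit <- length(centroids)
    }
    assign_idx[i] <- hit
  }

  cluster_ids <- sprintf("c%05d", seq_along(centroids))
  assignment <- stats::setNames(cluster_ids[assign_idx], uniq)
  obs_cluster <- unname(assignment[sequences])

  sample_levels <- sort(unique(samples))
  abundance <- matrix(0L, nrow = length(centroids),
                      ncol = length(sample_levels),
                      dimnames = list(cluster_ids, sample_levels))
  tt <- table(factor(obs_cluster, levels = cluster_ids),
              factor(samples, levels = sample_levels))
  abundance[] <- as.integer(tt)

  n_members <- as.integer(table(factor(assignment[uniq],
                                       levels = cluster_ids)))
  structure(list(
    clusters = data.frame(
      cluster_id = cluster_ids, centroid = centroids,
      n_members = n_members, total = as.integer(rowSums(abundance))
    ),
    abundance = abundance,
    assignment = assignment,
    obs_cluster = obs_cluster,
    threshold = threshold
  ), class = "spacer_clusters")
}

#' @export
print.spacer_clusters <- function(x, ...) {
  cat("Spacer clusters\n")
  cat(sprintf("  observations: %d\n", length(x$obs_cluster)))
  cat(sprintf("  unique sequences: %d\n", length(x$assignment)))
  cat(sprintf("  clusters: %d (identity >= %.2f)\n",
              nrow(x$clusters), x$threshold))
  invisible(x)
}

#' Good's coverage estimate
#'
#' `C = 1 - N / S` where `N` is the number of clusters observed once or
#' twice and `S` the total number of clusters: the estimated fraction of
#' the underlying diversity captured by the sample.
#'
#' @param cluster_counts Positive integer vector of per-cluster counts.
#' @param rare_max Count at or below which a cluster is "rare" (default 2).
#' @return Coverage fraction in `[0, 1]`.
#' @export
goods_coverage <- function(cluster_counts, rare_max = 2L) {
  if (length(cluster_counts) == 0) stop("empty count vector")
  if (any(cluster_counts < 1)) stop("counts must be >= 1")
  1 - sum(cluster_counts <= rare_max) / length(cluster_counts)
}

#' Shannon entropy and Chao1 richness
#'
#' `H = -sum p_i log p_i` (nats) and
#' `chao1 = S_obs + F1^2 / (2 F2)` where `F1`/`F2` are the singleton and
#' doubleton counts; the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used when there are no
#' doubletons.
#'
#' @param cluster_counts Positive integer vector of per-cluster counts.
#' @return List with `shannon_H`, `chao1`, `n_clusters`, `n_rare`.
#' @export
shannon_chao <- function(cluster_counts) {
  if (length(cluster_counts) == 0) stop("empty count vector")
  if (any(cluster_counts < 1)) stop("counts must be >= 1")
  p <- cluster_counts / sum(cluster_counts)
  H <- -sum(p * log(p))
  S <- length(cluster_counts)
  F1 <- sum(cluster_counts == 1)
  F2 <- sum(cluster_counts == 2)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
  list(shannon_H = H, chao1 = chao1, n_clusters = S,
       n_rare = sum(cluster_counts <= 2))
}

#' Confidence half-width for a lost-spacer proportion
#'
#' Normal-approximation half-width `z(0.975) * sqrt(lost (1 - lost) / N)`
#' for the proportion of spacers lost between samples (e.g. during
#' enrichment cultivation).
#'
#' @param lost Fraction lost, in `[0, 1]`.
#' @param N Group size (number of spacers in the group).
#' @return Half-width; 0 when `lost` is 0 or 1.
#' @export
loss_confidence <- function(lost, N) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(lost < 0 | lost > 1)) stop("lost must be in [0, 1]")
  stats::qnorm(0.975) * sqrt(lost * (1 - lost) / N)
}

# distance matrix (mismatches + gaps, end gaps of the longer sequence
# free) between two sequence sets; rows = set_a, cols = set_b
.free_end_distance <- function(set_a, set_b) {
  n_a <- length(set_a); n_b <- length(set_b)
  d1 <- matrix(Inf, n_a, n_b)
  for (j in seq_len(n_b)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(set_a), set_b[j],
      type = "global-local", substitutionMatrix = .DIST_MAT,
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE
    )
    d1[, j] <- -aln
  }
  d2 <- matrix(Inf, n_a, n_b)
  for (i in seq_len(n_a)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(set_b), set_a[i],
      type = "global-local", substitutionMatrix = .DIST_MAT,
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE
    )
    d2[i, ] <- -aln
  }
  pmin(d1, d2)
}

#' Cross-repeat-type spacer intersection
#'
#' For each ordered pair of repeat types, the fraction of type-i spacers
#' that have a counterpart among type-j spacers within `max_mismatch`
#' mismatches, allowing end gaps and insertions (the shorter sequence is
#' matched inside the longer with free ends; internal gaps and mismatches
#' each cost 1). Used to evaluate primer cross-amplification between
#' repeat types.
#'
#' @param spacer_sets Named list (one element per repeat type) of spacer
#'   centroid character vectors.
#' @param max_mismatch Allowed mismatches + gaps (default 2).
#' @return Square matrix of fractions; entry `(i, j)` is the fraction of
#'   type-i spacers found in type-j. Diagonal is `NA`.
#' @export
cross_type_intersection <- function(spacer_sets, max_mismatch = 2L) {
  if (length(spacer_sets) < 2) stop("need at least two repeat types")
  types <- names(spacer_sets)
  M <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      if (i == j) next
      a <- spacer_sets[[i]]; b <- spacer_sets[[j]]
      if (length(a) == 0) { M[i, j] <- NaN; next }
      if (length(b) == 0) { M[i, j] <- 0; next }
      D <- .free_end_distance(a, b)
      M[i, j] <- mean(apply(D, 1, min) <= max_mismatch)
    }
  }
  M
}
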