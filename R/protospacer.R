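# positions (1-based) of every word_size-mer of `chars`, as an
# environment keyed by k-mer
.kmer_index <- function(chars, word_size) {
  n <- length(chars)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (n < word_size) return(env)
  km <- substring(paste(chars, collapse = ""),
                  seq_len(n - word_size + 1L),
                  seq_len(n - word_size + 1L) + word_size - 1L)
  sp <- split(seq_along(km), km)
  for (k in names(sp)) assign(k, sp[[k]], envir = env)
  env
}

# ungapped identity of `sp_chars` against the genome at 1-based offsets
.offset_identity <- function(sp_chars, g_chars, offsets) {
  len <- length(sp_chars)
  vapply(offsets, function(o) {
    sum(g_chars[o:(o + len - 1L)] == sp_chars) / len
  }, numeric(1))
}

#' Map spacers to protospacers in a genome
#'
#' Seed-and-extend matcher: exact `word_size`-mer seeds shared between
#' the spacer and the genome (both strands) anchor ungapped full-length
#' comparisons; loci reaching `min_identity` over the full spacer length
#' are reported. Reverse-strand hits are reported in forward coordinates
#' with strand `"-"`. Overlapping hits of the same spacer on the same
#' strand (>= 50% overlap) are merged, keeping the highest identity.
#'
#' A hit with `m` mismatches is guaranteed to retain an exact seed only
#' when `(m + 1) * word_size <= spacer length`; the per-spacer
#' `seed_guaranteed` flag reports this condition so the theoretical miss
#' regime is visible.
#'
#' @param spacers Named character vector of spacer sequences (25-60 nt);
#'   names become `cluster_id` in the output.
#' @param genome Genome sequence (character scalar).
#' @param genome_id Label for the output.
#' @param min_identity Identity threshold over the full spacer length
#'   (default 0.85).
#' @param word_size Seed length (default 8).
#' @param both_strands Search the reverse strand too (default `TRUE`).
#' @param flank_len Flank length captured for PAM inference (default 10).
#' @return Data frame of class `protospacer_hits`: `cluster_id`,
#'   `genome_id`, `start`, `end` (0-based half-open, forward strand),
#'   `strand`, `identity`, `flank_5`, `flank_3` (oriented to the
#'   protospacer strand, `N`-padded at genome edges), `seed_guaranteed`.
#' @export
find_protospacers <- function(spacers, genome, genome_id = "genome",
                              min_identity = 0.85, word_size = 8L,
                              both_strands = TRUE, flank_len = 10L) {
  stopifnot(length(genome) == 1L)
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer%04d", seq_along(spacers))
  }
  g_chars <- strsplit(toupper(genome), "", fixed = TRUE)[[1]]
  n <- length(g_chars)
  idx <- .kmer_index(g_chars, word_size)
  g_str <- paste(g_chars, collapse = "")

  rows <- list()
  for (si in seq_along(spacers)) {
    sp <- toupper(spacers[[si]])
    len <- nchar(sp)
    if (n < len) next
    m_budget <- floor(len * (1 - min_identity) + 1e-9)
    seed_guaranteed <- (m_budget + 1L) * word_size <= len
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      qs <- if (strand == "+") sp else revcomp(sp)
      q_chars <- strsplit(qs, "", fixed = TRUE)[[1]]
      if (len < word_size) next
      kms <- substring(qs, seq_len(len - word_size + 1L),
                       seq_len(len - word_size + 1L) + word_size - 1L)
      offs <- integer(0)
      for (ki in seq_along(kms)) {
        hit <- idx[[kms[ki]]]
        if (!is.null(hit)) offs <- c(offs, hit - ki + 1L)
      }
      offs <- sort(unique(offs))
      offs <- offs[offs >= 1L & offs + len - 1L <= n]
      if (!length(offs)) next
      ident <- .offset_identity(q_chars, g_chars, offs)
      ok <- ident >= min_identity
      if (!any(ok)) next
      for (w in which(ok)) {
        o <- offs[w]
        up <- substr(g_str, max(1L, o - flank_len), o - 1L)
        dn <- substr(g_str, o + len, min(n, o + len + flank_len - 1L))
        up <- paste0(strrep("N", flank_len - nchar(up)), up)
        dn <- paste0(dn, strrep("N", flank_len - nchar(dn)))
        if (strand == "-") {
          tmp <- revcomp(dn); dn <- revcomp(up); up <- tmp
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = names(spacers)[si], genome_id = genome_id,
          start = o - 1L, end = o - 1L + len, strand = strand,
          identity = ident[w], flank_5 = up, flank_3 = dn,
          seed_guaranteed = seed_guaranteed
        )
      }
    }
  }
  hits <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cluster_id = character(0), genome_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               identity = numeric(0), flank_5 = character(0),
               flank_3 = character(0), seed_guaranteed = logical(0))
  }
  hits <- .dedupe_hits(hits)
  class(hits) <- c("protospacer_hits", "data.frame")
  hits
}

# merge same-spacer same-strand hits overlapping >= 50%, keeping the
# highest identity (ties: leftmost)
.dedupe_hits <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  keep <- logical(nrow(hits))
  ord <- order(hits$cluster_id, hits$strand, -hits$identity, hits$start)
  taken <- list()
  for (i in ord) {
    key <- paste(hits$cluster_id[i], hits$strand[i])
    ivs <- taken[[key]]
    olap <- FALSE
    if (!is.null(ivs)) {
      for (v in ivs) {
        ov <- min(hits$end[i], v[2]) - max(hits$start[i], v[1])
        if (ov >= 0.5 * min(hits$end[i] - hits$start[i], v[2] - v[1])) {
          olap <- TRUE
          break
        }
      }
    }
    if (!olap) {
      keep[i] <- TRUE
      taken[[key]] <- c(ivs, list(c(hits$start[i], hits$end[i])))
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$cluster_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PAM consensus from protospacer flanks
#'
#' Aligns the strand-oriented flanking sequences of protospacer hits and
#' profiles per-position base frequencies on each side; the consensus
#' takes the majority base where its frequency exceeds 0.5 and `N`
#' elsewhere. `N`-padded positions (hits at genome edges) are excluded
#' position-wise from the frequencies.
#'
#' @param hits A [find_protospacers()] result (>= 2 hits).
#' @param flank_len Flank length to profile.
#' @return List of class `pam_profile`: `profile_5`, `profile_3` (4 x
#'   flank_len frequency matrices), `consensus_5`, `consensus_3`.
#' @export
pam_consensus <- function(hits, flank_len = 10L) {
  if (nrow(hits) < 2) stop("need at least 2 hits for a PAM profile")
  profile_one <- function(flanks) {
    mat <- do.call(rbind, strsplit(flanks, "", fixed = TRUE))
    freq <- vapply(seq_len(ncol(mat)), function(j) {
      col <- mat[, j]
      col <- col[col != "N"]
      if (!length(col)) return(rep(NA_real_, 4))
      as.numeric(table(factor(col, levels = c("A", "C", "G", "T")))) /
        length(col)
    }, numeric(4))
    rownames(freq) <- c("A", "C", "G", "T")
    cons <- apply(freq, 2, function(f) {
      if (anyNA(f) || max(f) <= 0.5) "N" else rownames(freq)[which.max(f)]
    })
    list(profile = freq, consensus = paste(cons, collapse = ""))
  }
  p5 <- profile_one(substr(hits$flank_5,
                           nchar(hits$flank_5) - flank_len + 1L,
                           nchar(hits$flank_5)))
  p3 <- profile_one(substr(hits$flank_3, 1L, flank_len))
  structure(list(profile_5 = p5$profile, profile_3 = p3$profile,
                 consensus_5 = p5$consensus, consensus_3 = p3$consensus),
            class = "pam_profile")
}

#' @export
print.pam_profile <- function(x, ...) {
  cat("PAM consensus  5':", x$consensus_5, "  3':", x$consensus_3, "\n")
  invisible(x)
}

#' Conservation track from a two-genome alignment
#'
#' Flags each alignment column as identical (same base, no gap) or not,
#' and computes a sliding-window identity track for reporting. A
#' protospacer span is later classified "conserved" iff every column of
#' its span is identical; anything else is "variable".
#'
#' @param alignment Character vector of exactly 2 aligned sequences of
#'   equal length (gaps as `-`).
#' @param window Window size for the identity track (default 50).
#' @return Object of class `conservation_track`: `identical` (logical per
#'   column), `window_identity` (numeric, NA at the edges), `labels`
#'   (per-column `conserved`/`variable`), `length`.
#' @export
classify_conservation <- function(alignment, window = 50L) {
  if (length(alignment) != 2) stop("alignment must contain 2 sequences")
  a <- strsplit(toupper(alignment[[1]]), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(alignment[[2]]), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences differ in length")
  }
  ident <- a == b & a != "-" & b != "-"
  win <- as.numeric(stats::filter(as.numeric(ident), rep(1 / window,
                                                         window)))
  structure(list(
    identical = ident,
    window_identity = win,
    labels = ifelse(ident, "conserved", "variable"),
    length = length(ident)
  ), class = "conservation_track")
}

# classify spans (1-based start, length) against a track: conserved iff
# no non-identical column in the span
.classify_spans <- function(track, starts, lens) {
  cs <- c(0L, cumsum(!track$identical))
  (cs[starts + lens] - cs[starts]) == 0L
}

#' Protospacer spans classified against a conservation track
#'
#' @param track A [classify_conservation()] result.
#' @param hits A hit table with `start`, `end` (0-based half-open) on the
#'   alignment coordinate system.
#' @return Character vector `conserved`/`variable` per hit.
#' @export
classify_hits <- function(track, hits) {
  starts <- hits$start + 1L
  lens <- hits$end - hits$start
  if (any(starts < 1L) || any(hits$end > track$length)) {
    stop("hit span outside the alignment")
  }
  ifelse(.classify_spans(track, starts, lens), "conserved", "variable")
}

#' Test whether CRISPR targeting coincides with genome divergence
#'
#' Observed protospacer spans are classified conserved/variable against
#' the two-genome alignment; `n_sim` spacers with lengths resampled from
#' the observed spans are then placed at uniform random alignment
#' positions and classified the same way. The observed conserved/variable
#' split is tested against the simulated proportions with a df = 1
#' chi-square goodness of fit (expected counts scaled to the observed
#' total). A 2x2 contingency chi-square of observed vs simulated counts
#' is reported alongside, since both framings appear in practice.
#'
#' @param hits Observed hit table (`start`, `end`, 0-based half-open, on
#'   alignment coordinates).
#' @param track A [classify_conservation()] result with both classes
#'   present.
#' @param n_sim Number of simulated spacers (default 10000).
#' @param seed Integer seed for the placement simulation.
#' @return Object of class `coincidence_test`: observed and simulated
#'   counts, `chi_square`, `p_value` (goodness of fit),
#'   `p_value_contingency`, `n_sim`, `seed`.
#' @export
coincidence_test <- function(hits, track, n_sim = 10000L, seed = 1L) {
  stopifnot(inherits(track, "conservation_track"))
  if (nrow(hits) < 1) stop("need at least one observed hit")
  if (all(track$identical) || !any(track$identical)) {
    stop("conservation track is degenerate (single class)")
  }
  obs_lens <- hits$end - hits$start
  obs_cons <- .classify_spans(track, hits$start + 1L, obs_lens)
  obs_c <- sum(obs_cons)
  obs_v <- sum(!obs_cons)

  .with_seed(seed, {
    lens <- sample(obs_lens, n_sim, replace = TRUE)
    starts <- 1L + floor(stats::runif(n_sim) * (track$length - lens + 1L))
    sim_cons <- .classify_spans(track, starts, lens)
  })
  sim_c <- sum(sim_cons)
  sim_v <- n_sim - sim_c
  total <- obs_c + obs_v
  expected <- total * c(sim_c, sim_v) / n_sim
  if (any(expected == 0)) stop("simulated class proportions degenerate")
  chi <- sum((c(obs_c, obs_v) - expected)^2 / expected)
  p_gof <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  p_cont <- suppressWarnings(stats::chisq.test(
    matrix(c(obs_c, obs_v, sim_c, sim_v), nrow = 2)
  )$p.value)
  structure(list(
    obs_conserved = obs_c, obs_variable = obs_v,
    sim_conserved = sim_c, sim_variable = sim_v,
    n_sim = as.integer(n_sim), chi_square = chi, p_value = p_gof,
    p_value_contingency = p_cont, seed = seed
  ), class = "coincidence_test")
}

#' @export
print.coincidence_test <- function(x, ...) {
  cat("Targeting/divergence coincidence test\n")
  cat(sprintf("  observed:  %d conserved / %d variable\n",
              x$obs_conserved, x$obs_variable))
  cat(sprintf("  simulated: %d / %d of %d\n", x$sim_conserved,
              x$sim_variable, x$n_sim))
  cat(sprintf("  chi-square = %.3f, P = %.3g (goodness of fit, df = 1)\n",
              x$chi_square, x$p_value))
  cat(sprintf("  2x2 contingency P = %.3g\n", x$p_value_contingency))
  invisible(x)
}

#' Fraction of a genome covered by protospacer hits
#'
#' Union length of the hit intervals divided by the genome length.
#'
#' @param hits Hit table with `start`, `end` (0-based half-open).
#' @param genome_length Genome length (nt).
#' @return Coverage fraction in `[0, 1]`.
#' @export
genome_protospacer_coverage <- function(hits, genome_length) {
  if (nrow(hits) == 0) return(0)
  if (any(hits$start < 0) || any(hits$end > genome_length)) {
    stop("hit outside genome bounds")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$start + 1L,
                                         end = hits$end))
  sum(IRanges::width(ir)) / genome_length
}
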