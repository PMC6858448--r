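#' Degenerate motif (repeat or primer)
#'
#' @param label Motif name, e.g. the repeat-type label (`"A"`) or a primer
#'   name.
#' @param pattern IUPAC string.
#' @return Object of class `degenerate_motif`.
#' @export
degenerate_motif <- function(label, pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) stop("pattern must be non-empty")
  .pattern_allowed(chars)  # validates symbols
  structure(list(label = label, pattern = pattern),
            class = "degenerate_motif")
}

#' Spacer extraction parameters
#'
#' Defaults follow the published procedure: repeat motifs are matched with
#' up to 3 mismatches and primers with up to 2 (the stated allowance is a
#' 2-5 range without a per-motif assignment), extracted spacers shorter
#' than 25 nt or longer than 60 nt are discarded, and every base of a kept
#' spacer must have Phred quality strictly greater than 20.
#'
#' @param max_mismatch_repeat Mismatches tolerated in repeat motifs.
#' @param max_mismatch_primer Mismatches tolerated in primer motifs.
#' @param min_spacer_len,max_spacer_len Spacer length bounds (inclusive).
#' @param min_phred Quality floor; the filter is strict (`> min_phred`).
#' @param search_both_strands If `TRUE`, a read whose reverse complement
#'   carries more repeat hits than the forward orientation is flipped
#'   before extraction, so spacer order follows repeat orientation.
#' @return Object of class `extraction_params`.
#' @export
extraction_params <- function(max_mismatch_repeat = 3L,
                              max_mismatch_primer = 2L,
                              min_spacer_len = 25L,
                              max_spacer_len = 60L,
                              min_phred = 20L,
                              search_both_strands = TRUE) {
  stopifnot(max_mismatch_repeat >= 0, max_mismatch_primer >= 0,
            min_spacer_len < max_spacer_len)
  structure(list(
    max_mismatch_repeat = as.integer(max_mismatch_repeat),
    max_mismatch_primer = as.integer(max_mismatch_primer),
    min_spacer_len = as.integer(min_spacer_len),
    max_spacer_len = as.integer(max_spacer_len),
    min_phred = as.integer(min_phred),
    search_both_strands = isTRUE(search_both_strands)
  ), class = "extraction_params")
}

# precompile motif patterns for repeated scanning
.compile_motif <- function(motif) {
  chars <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  list(label = motif$label, len = length(chars),
       allowed = .pattern_allowed(chars))
}

# scan pre-encoded base codes; returns 1-based starts
.scan_codes <- function(codes, compiled, max_mismatch) {
  L <- compiled$len
  n <- length(codes)
  if (L > n) return(list(start = integer(0), mismatches = integer(0)))
  nwin <- n - L + 1L
  mism <- integer(nwin)
  allowed <- compiled$allowed
  for (j in seq_len(L)) {
    mism <- mism + !allowed[[j]][codes[j:(j + nwin - 1L)]]
  }
  keep <- which(mism <= max_mismatch)
  list(start = keep, mismatches = mism[keep])
}

# core per-read extraction on precompiled motifs; plain lists for speed
.extract_core <- function(seq, qual, rep_c, prim_c, params) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- .BASE_CODE[chars]
  if (anyNA(codes)) stop("non-ACGTN character in read")
  qv <- .phred_decode(qual)
  if (length(qv) != length(codes)) {
    stop("sequence and quality strings differ in length")
  }

  hits_f <- .scan_codes(codes, rep_c, params$max_mismatch_repeat)
  flipped <- FALSE
  if (params$search_both_strands) {
    codes_r <- rev((c(4L, 3L, 2L, 1L, 5L))[codes])
    hits_r <- .scan_codes(codes_r, rep_c, params$max_mismatch_repeat)
    if (length(hits_r$start) > length(hits_f$start)) {
      flipped <- TRUE
      codes <- codes_r
      chars <- c("A", "C", "G", "T", "N")[codes]
      qv <- rev(qv)
      hits_f <- hits_r
    }
  }

  starts <- hits_f$start
  mism <- hits_f$mismatches
  lens <- rep.int(rep_c$len, length(starts))
  is_rep <- rep.int(TRUE, length(starts))
  for (pc in prim_c) {
    ph <- .scan_codes(codes, pc, params$max_mismatch_primer)
    starts <- c(starts, ph$start)
    mism <- c(mism, ph$mismatches)
    lens <- c(lens, rep.int(pc$len, length(ph$start)))
    is_rep <- c(is_rep, rep.int(FALSE, length(ph$start)))
  }
  if (length(starts) < 2L) {
    return(list(seqs = character(0), minq = integer(0),
                n_candidates = 0L, flipped = flipped))
  }
  ord <- order(starts, mism)
  starts <- starts[ord]; mism <- mism[ord]
  lens <- lens[ord]; is_rep <- is_rep[ord]

  # greedy left-to-right non-overlapping subset (ties already broken by
  # lowest mismatch count in the ordering)
  keep <- integer(0)
  cur_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > cur_end) {
      keep <- c(keep, i)
      cur_end <- starts[i] + lens[i] - 1L
    }
  }
  if (length(keep) < 2L) {
    return(list(seqs = character(0), minq = integer(0),
                n_candidates = 0L, flipped = flipped))
  }
  ks <- starts[keep]; kl <- lens[keep]; kr <- is_rep[keep]
  seq_str <- paste(chars, collapse = "")

  reg_from <- ks[-length(ks)] + kl[-length(kl)]        # 1-based
  reg_to <- ks[-1] - 1L
  # a spacer needs a repeat on at least one side
  bounded <- kr[-length(kr)] | kr[-1]
  ok <- which(reg_to >= reg_from & bounded)
  n_cand <- length(ok)
  if (n_cand == 0L) {
    return(list(seqs = character(0), minq = integer(0),
                n_candidates = 0L, flipped = flipped))
  }
  reg_from <- reg_from[ok]; reg_to <- reg_to[ok]
  widths <- reg_to - reg_from + 1L
  minq <- vapply(seq_along(reg_from), function(i) {
    min(qv[reg_from[i]:reg_to[i]])
  }, integer(1))
  pass <- which(widths >= params$min_spacer_len &
                  widths <= params$max_spacer_len &
                  minq > params$min_phred)
  if (length(pass) == 0L) {
    return(list(seqs = character(0), minq = integer(0),
                n_candidates = n_cand, flipped = flipped))
  }
  list(seqs = substring(seq_str, reg_from[pass], reg_to[pass]),
       minq = minq[pass], n_candidates = n_cand, flipped = flipped)
}

#' Extract spacers and neighbouring-spacer pairs from one read
#'
#' Finds degenerate repeat (and primer) motifs in the read, takes the
#' maximal substrings strictly between consecutive motif hits as candidate
#' spacers, and applies the length and quality filters. Overlapping motif
#' hits are resolved to a greedy left-to-right non-overlapping subset
#' (lowest mismatch count first on ties). Consecutive surviving spacers
#' yield pairs in read order, so a 3-spacer read yields 2 pairs.
#'
#' @param sequence Read sequence (ACGTN string).
#' @param quality Phred+33 quality string of the same length.
#' @param repeat_motif A [degenerate_motif()] for the CRISPR repeat.
#' @param primers Optional list of [degenerate_motif()] primers.
#' @param params An [extraction_params()].
#' @param read_id Identifier copied into the output rows.
#' @return List with `spacers` (`sequence`, `repeat_type`, `read_id`,
#'   `unit_index`, `min_phred`) and `pairs` (`first`, `second`,
#'   `repeat_type`, `read_id`).
#' @export
extract_from_read <- function(sequence, quality, repeat_motif,
                              primers = NULL,
                              params = extraction_params(),
                              read_id = "read1") {
  stopifnot(inherits(repeat_motif, "degenerate_motif"),
            inherits(params, "extraction_params"))
  if (nchar(sequence) != nchar(quality)) {
    stop("sequence and quality strings differ in length")
  }
  rep_c <- .compile_motif(repeat_motif)
  prim_c <- lapply(primers, function(p) {
    stopifnot(inherits(p, "degenerate_motif"))
    .compile_motif(p)
  })
  res <- .extract_core(sequence, quality, rep_c, prim_c, params)
  n <- length(res$seqs)
  spacers <- data.frame(
    sequence = res$seqs,
    repeat_type = rep(repeat_motif$label, n),
    read_id = rep(read_id, n),
    unit_index = seq_len(n) - 1L,
    min_phred = res$minq
  )
  if (n >= 2L) {
    pairs <- data.frame(
      first = res$seqs[-n], second = res$seqs[-1],
      repeat_type = repeat_motif$label, read_id = read_id
    )
  } else {
    pairs <- data.frame(first = character(0), second = character(0),
                        repeat_type = character(0), read_id = character(0))
  }
  list(spacers = spacers, pairs = pairs)
}

#' Extract spacers from a whole sample
#'
#' Applies [extract_from_read()] to every read of a sample and aggregates
#' the results, with exact accounting of how many candidate spacers the
#' length/quality filters removed. Unreadable records are skipped and
#' counted.
#'
#' @param reads A reads table (`read_id`, `sequence`, `quality`) or a path
#'   to a FASTQ file.
#' @param repeat_motif A [degenerate_motif()] for the repeat type.
#' @param primers Optional list of primer [degenerate_motif()]s.
#' @param params An [extraction_params()].
#' @param sample_id Sample label copied into the output.
#' @return Object of class `spacer_extraction`: list with `spacers`
#'   (`sample_id`, `read_id`, `unit_index`, `repeat_type`, `sequence`,
#'   `min_phred`), `pairs` (`repeat_type`, `first`, `second`, `read_id`)
#'   and `summary` (reads scanned, spacers kept, spacers filtered, reads
#'   failed).
#' @export
extract_sample <- function(reads, repeat_motif, primers = NULL,
                           params = extraction_params(),
                           sample_id = "sample1") {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_fastq(reads)
  }
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  rep_c <- .compile_motif(repeat_motif)
  prim_c <- lapply(primers, .compile_motif)

  n <- nrow(reads)
  sp_seq <- vector("list", n)
  sp_minq <- vector("list", n)
  sp_read <- vector("list", n)
  n_candidates <- 0L
  n_failed <- 0L
  for (r in seq_len(n)) {
    res <- tryCatch(
      .extract_core(reads$sequence[r], reads$quality[r], rep_c, prim_c,
                    params),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    n_candidates <- n_candidates + res$n_candidates
    if (length(res$seqs)) {
      sp_seq[[r]] <- res$seqs
      sp_minq[[r]] <- res$minq
      sp_read[[r]] <- r
    }
  }
  got <- which(!vapply(sp_seq, is.null, logical(1)))
  counts <- lengths(sp_seq[got])
  seqs <- unlist(sp_seq[got], use.names = FALSE)
  minq <- unlist(sp_minq[got], use.names = FALSE)
  read_of <- rep(reads$read_id[got], counts)
  unit_index <- sequence(counts) - 1L

  spacers <- data.frame(
    sample_id = rep(sample_id, length(seqs)),
    read_id = read_of,
    unit_index = unit_index,
    repeat_type = rep(repeat_motif$label, length(seqs)),
    sequence = seqs,
    min_phred = minq
  )
  # pairs: consecutive surviving spacers within each read
  multi <- which(counts >= 2L)
  if (length(multi)) {
    firsts <- unlist(lapply(multi, function(i) {
      s <- sp_seq[[got[i]]]
      s[-length(s)]
    }), use.names = FALSE)
    seconds <- unlist(lapply(multi, function(i) {
      sp_seq[[got[i]]][-1]
    }), use.names = FALSE)
    pair_read <- rep(reads$read_id[got[multi]], counts[multi] - 1L)
    pairs <- data.frame(repeat_type = repeat_motif$label, first = firsts,
                        second = seconds, read_id = pair_read)
  } else {
    pairs <- data.frame(repeat_type = character(0), first = character(0),
                        second = character(0), read_id = character(0))
  }
  n_kept <- nrow(spacers)
  structure(list(
    spacers = spacers, pairs = pairs,
    summary = list(
      sample_id = sample_id,
      reads_scanned = n,
      reads_failed = n_failed,
      spacers_candidate = n_candidates,
      spacers_kept = n_kept,
      spacers_filtered = n_candidates - n_kept
    )
  ), class = "spacer_extraction")
}

#' @export
print.spacer_extraction <- function(x, ...) {
  s <- x$summary
  cat("Spacer extraction:", s$sample_id, "\n")
  cat(sprintf("  reads scanned: %d (%d unreadable)\n",
              s$reads_scanned, s$reads_failed))
  cat(sprintf("  spacers kept:  %d of %d candidates (%.1f%% filtered)\n",
              s$spacers_kept, s$spacers_candidate,
              if (s$spacers_candidate > 0) {
                100 * s$spacers_filtered / s$spacers_candidate
              } else 0))
  cat(sprintf("  pairs:         %d\n", nrow(x$pairs)))
  invisible(x)
}
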