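#' IUPAC nucleotide degeneracy codes
#'
#' Named character vector mapping each IUPAC symbol to the set of concrete
#' bases it stands for (e.g. `H` = A, C or T; `K` = G or T; `N` = any base).
#' CRISPR repeat consensuses vary between genomes, so repeat and primer
#' motifs are expressed in this alphabet.
#'
#' @format Named character vector of length 15.
#' @export
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# base -> integer code used by the vectorised scanner (N in a *read* is a
# fifth letter that matches only a pattern N)
.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.encode_bases <- function(chars) {
  code <- .BASE_CODE[chars]
  if (anyNA(code)) {
    stop("sequence contains non-ACGTN character: ",
         paste(unique(chars[is.na(code)]), collapse = ", "))
  }
  unname(code)
}

# For each pattern position, logical length-5 vector saying which read base
# codes (A,C,G,T,N) the symbol accepts. Pattern N accepts everything.
.pattern_allowed <- function(pattern_chars) {
  sets <- IUPAC_CODES[pattern_chars]
  if (anyNA(sets)) {
    stop("invalid IUPAC symbol in pattern: ",
         paste(unique(pattern_chars[is.na(sets)]), collapse = ", "))
  }
  lapply(seq_along(sets), function(j) {
    allowed <- rep(FALSE, 5L)
    allowed[.BASE_CODE[strsplit(sets[[j]], "", fixed = TRUE)[[1]]]] <- TRUE
    if (pattern_chars[j] == "N") allowed[5L] <- TRUE
    allowed
  })
}

#' Match a single IUPAC pattern symbol against a base
#'
#' `TRUE` iff `base` belongs to the degeneracy set of `pattern_symbol`
#' (so `iupac_match("H", "T")` is `TRUE`, `iupac_match("K", "A")` is
#' `FALSE`); `N` matches every base. Both arguments are vectorised and
#' recycled.
#'
#' @param pattern_symbol Character vector of single IUPAC symbols.
#' @param base Character vector of single bases (`A`, `C`, `G`, `T`, `N`).
#' @return Logical vector.
#' @examples
#' iupac_match("H", "T")  # TRUE
#' iupac_match("K", "A")  # FALSE
#' @export
iupac_match <- function(pattern_symbol, base) {
  pattern_symbol <- toupper(as.character(pattern_symbol))
  base <- toupper(as.character(base))
  n <- max(length(pattern_symbol), length(base))
  pattern_symbol <- rep_len(pattern_symbol, n)
  base <- rep_len(base, n)
  sets <- IUPAC_CODES[pattern_symbol]
  if (anyNA(sets)) {
    stop("invalid IUPAC symbol: ",
         paste(unique(pattern_symbol[is.na(sets)]), collapse = ", "))
  }
  if (!all(base %in% names(.BASE_CODE))) {
    stop("invalid base: ",
         paste(unique(base[!base %in% names(.BASE_CODE)]), collapse = ", "))
  }
  out <- logical(n)
  for (i in seq_len(n)) {
    out[i] <- (base[i] != "N" && grepl(base[i], sets[[i]], fixed = TRUE)) ||
      pattern_symbol[i] == "N"
  }
  out
}

#' Scan a sequence for a degenerate motif
#'
#' Slides a window of the pattern length along `sequence` and reports every
#' 0-based start whose IUPAC-mismatch count is at most `max_mismatch`. A
#' mismatch is a position where the read base is not in the pattern symbol's
#' degeneracy set (Hamming scan; no indels).
#'
#' @param sequence Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @param pattern IUPAC motif string (e.g. a repeat or primer consensus).
#' @param max_mismatch Maximum tolerated mismatches per window.
#' @return `data.frame` with columns `start` (0-based) and `mismatches`,
#'   sorted by `start`. Empty when the pattern is longer than the sequence.
#' @examples
#' scan_motif("GATGAG", "GAK", 0)  # hits at 0 and 3 (K = G or T)
#' @export
scan_motif <- function(sequence, pattern, max_mismatch = 0L) {
  stopifnot(length(sequence) == 1L, length(pattern) == 1L, max_mismatch >= 0)
  seq_chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  pat_chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (length(pat_chars) == 0L) stop("pattern must be non-empty")
  n <- length(seq_chars)
  L <- length(pat_chars)
  if (L > n) {
    return(data.frame(start = integer(0), mismatches = integer(0)))
  }
  codes <- .encode_bases(seq_chars)
  allowed <- .pattern_allowed(pat_chars)
  nwin <- n - L + 1L
  mism <- integer(nwin)
  for (j in seq_len(L)) {
    mism <- mism + !allowed[[j]][codes[j:(j + nwin - 1L)]]
  }
  keep <- which(mism <= max_mismatch)
  data.frame(start = keep - 1L, mismatches = mism[keep])
}

#' Reverse complement
#'
#' Reverse-complements a DNA string, preserving IUPAC degeneracy codes
#' (e.g. `R` -> `Y`).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Realise one concrete sequence from an IUPAC consensus
#'
#' Replaces every degenerate symbol by one base drawn uniformly from its
#' degeneracy set. Used by the community generator: repeats vary between
#' genomes but are locally constant, so each strain fixes one realisation.
#'
#' @param pattern IUPAC string.
#' @return Concrete ACGT string.
#' @export
iupac_realize <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  sets <- IUPAC_CODES[chars]
  if (anyNA(sets)) {
    stop("invalid IUPAC symbol in pattern: ",
         paste(unique(chars[is.na(sets)]), collapse = ", "))
  }
  paste(vapply(sets, function(s) {
    opts <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# run code with a temporary RNG state seeded by `seed`; restores the caller's
# RNG so generators are deterministic without clobbering the session
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}
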