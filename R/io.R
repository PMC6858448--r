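#' Read a FASTQ file into a reads table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the flat
#' table used by the extraction functions. Qualities are kept as Phred+33
#' encoded strings.
#'
#' @param path FASTQ file path.
#' @return `data.frame` with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL
  )
}

#' Write a reads table to FASTQ
#'
#' @param reads `data.frame` with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 strings).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# TSV with header is the inter-stage contract: diffable and testable
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

# decode/encode Phred+33 quality strings
.phred_decode <- function(q) utf8ToInt(q) - 33L
.phred_encode <- function(scores) intToUtf8(scores + 33L)
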