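# Independent brute-force oracles used to check the optimised
# implementations, plus small fixture builders. Each oracle is written
# directly from the operation's definition, not from the implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic random sequence independent of the caller's RNG state
random_dna_fixed <- function(n, seed) {
  withr::with_seed(seed, random_dna(n))
}

# per-window Hamming scan over every window, straight from iupac_match
oracle_scan <- function(sequence, pattern, max_mismatch) {
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pat_chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(pat_chars)
  n <- length(seq_chars)
  out <- data.frame(start = integer(0), mismatches = integer(0))
  if (L > n) return(out)
  for (s in seq_len(n - L + 1L)) {
    mm <- sum(!iupac_match(pat_chars, seq_chars[s:(s + L - 1L)]))
    if (mm <= max_mismatch) {
      out <- rbind(out, data.frame(start = s - 1L, mismatches = mm))
    }
  }
  out
}

# exhaustive enumeration of all simple paths in a directed graph; the
# eccentricity of a node is the node count of the longest path through it
oracle_eccentricity <- function(nodes, edges) {
  succ <- lapply(nodes, function(v) edges$to[edges$from == v])
  names(succ) <- nodes
  best <- stats::setNames(rep(1L, length(nodes)), nodes)
  extend <- function(path) {
    for (v in path) {
      if (length(path) > best[[v]]) best[[v]] <<- length(path)
    }
    for (w in setdiff(succ[[path[length(path)]]], path)) {
      extend(c(path, w))
    }
  }
  for (v in nodes) extend(v)
  data.frame(cluster_id = nodes, eccentricity = as.integer(best))
}

# sliding-window ungapped protospacer scan on both strands
oracle_protospacers <- function(spacer, genome, min_identity = 0.85) {
  g <- strsplit(genome, "", fixed = TRUE)[[1]]
  out <- data.frame(start = integer(0), strand = character(0),
                    identity = numeric(0))
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else crisprome::revcomp(spacer)
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    len <- length(qc)
    if (len > length(g)) next
    for (s in seq_len(length(g) - len + 1L)) {
      id <- sum(g[s:(s + len - 1L)] == qc) / len
      if (id >= min_identity) {
        out <- rbind(out, data.frame(start = s - 1L, strand = strand,
                                     identity = id))
      }
    }
  }
  out
}

# brute-force best overlap between two spacers over all offsets and both
# strands. An overlap qualifies only when it contains a run of at least
# `word_size` consecutive matching bases (the extension is defined as
# seeded on a shared exact word), checked here by run-length encoding
# rather than any k-mer index. Identity is over the overlap length.
oracle_best_overlap <- function(a, b, min_overlap = 8L, word_size = 8L) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  best <- list(identity = 0, offset = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    bb <- if (strand == "+") b else crisprome::revcomp(b)
    bc <- strsplit(bb, "", fixed = TRUE)[[1]]
    for (d in (-length(bc) + min_overlap):(length(ac) - min_overlap)) {
      s <- max(1L, d + 1L)
      e <- min(length(ac), d + length(bc))
      if (e - s + 1L < min_overlap) next
      eq <- ac[s:e] == bc[(s - d):(e - d)]
      runs <- rle(eq)
      if (!any(runs$values & runs$lengths >= word_size)) next
      id <- sum(eq) / length(eq)
      if (id > best$identity) {
        best <- list(identity = id, offset = d, strand = strand)
      }
    }
  }
  best
}

# random DAG on n nodes: edges only from lower to higher label
random_dag <- function(n, p = 0.3, wmax = 50L) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  # expand each edge to a multiplicity-weighted pair table
  w <- sample.int(wmax, length(from), replace = TRUE)
  data.frame(first = rep(from, w), second = rep(to, w))
}

# small community + reads, shared by several module tests
small_sim <- function(seed = 7, depth = 0.5, substitution_rate = 0.005,
                      chimera_rate = 0.01, n_host = 4,
                      array_len = c(8L, 12L), n_virus = 2,
                      mini_sizes = c(1L, 2L)) {
  cfg <- community_config(
    n_host_strains = n_host, array_length_range = array_len,
    n_viral_genomes = n_virus, mini_array_sizes = mini_sizes,
    seed = seed
  )
  comm <- generate_community(cfg)
  rp <- read_sim_params(depth = depth,
                        substitution_rate = substitution_rate,
                        chimera_rate = chimera_rate, seed = seed + 1L)
  reads <- generate_amplicon_reads(comm, rp)
  list(config = cfg, community = comm, read_params = rp, reads = reads)
}

extract_sim <- function(sim, params = extraction_params()) {
  extract_sample(
    sim$reads$reads,
    degenerate_motif("A", sim$config$repeat_consensus_by_type[["A"]]),
    primers = list(
      degenerate_motif("pf", sim$read_params$primer_fwd),
      degenerate_motif("pr", revcomp(sim$read_params$primer_rev))
    ),
    params = params
  )
}
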