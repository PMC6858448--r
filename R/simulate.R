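#' Default CRISPR repeat consensus sequences
#'
#' Four IUPAC-degenerate repeat consensuses labelled A-D, standing in for
#' the four principal repeat families of Sulfolobales-type communities.
#' These are synthetic illustrative consensuses (constructed for the
#' generator, not copied from any genome database); each strain in a
#' simulated community fixes one concrete realisation of the consensus it
#' carries, mirroring the way real repeats vary between genomes but are
#' locally constant within an array.
#'
#' @return Named character vector of IUPAC strings.
#' @export
default_repeat_consensus <- function() {
  c(
    A = "GATAGAAYTTCAAWAGTTCTCTRACTGAA",
    B = "CTTTCAATTCCTTYYGGGATTAATCGG",
    C = "GTAAGGAAKCTTAAAMCGATCTGCAAT",
    D = "CCAGAAATYTCAAGWGATTCGGTAACC"
  )
}

#' Default amplification primer pair
#'
#' Synthetic primer sequences used by the read simulator: the forward
#' primer opens each amplicon and the reverse complement of the reverse
#' primer closes it.
#'
#' @return Named character vector with elements `fwd` and `rev`.
#' @export
default_primers <- function() {
  c(fwd = "ACGGTCAGCAATGCCTGAAG", rev = "TGCCAGTTGAAGCTCGGTTA")
}

#' Configuration for a synthetic CRISPR-carrying community
#'
#' Defines the community the downstream analysis is exercised on: host
#' strains carrying one long CRISPR array per requested repeat type, and
#' viral genomes carrying leader-preceded mini-CRISPR arrays of 1-2
#' spacers. Host abundances are drawn from a log-normal mixture (the
#' multimodal strain-abundance structure seen in environmental CRISPRome
#' data); viral abundances from their own log-normal component, higher by
#' default because the mini-array-carrying viruses dominate the samples
#' they are found in.
#'
#' @param n_host_strains Number of host strains (default 20).
#' @param array_length_range Integer `(min, max)` spacers per long array;
#'   `min` must be at least 4 (mini-arrays are 1-2 spacers by definition).
#' @param repeat_consensus_by_type Named character vector of IUPAC repeat
#'   consensuses; one long array per strain per entry.
#' @param spacer_length_range Integer `(min, max)` spacer length in nt.
#' @param n_viral_genomes Number of viral genomes carrying mini-arrays.
#' @param mini_array_sizes Integer vector over `{1, 2}`, recycled across
#'   viral genomes.
#' @param leader_length Length (nt) of the leader preceding each mini-array.
#' @param abundance_model List with `meanlog`, `sdlog`, `weights` (equal
#'   length, weights summing to 1) of the host log-normal mixture.
#' @param viral_abundance_model List with scalar `meanlog`, `sdlog` for
#'   viral genome abundances.
#' @param viral_flank_length Random sequence (nt) on each side of the
#'   leader + mini-array cassette in a viral genome.
#' @param seed Integer seed making the community reproducible.
#' @return Object of class `community_config`.
#' @export
community_config <- function(n_host_strains = 20,
                             array_length_range = c(10L, 30L),
                             repeat_consensus_by_type =
                               default_repeat_consensus()["A"],
                             spacer_length_range = c(35L, 45L),
                             n_viral_genomes = 5,
                             mini_array_sizes = c(1L, 2L, 1L, 2L, 2L),
                             leader_length = 120,
                             abundance_model = list(
                               meanlog = log(c(300, 500, 800)),
                               sdlog = c(0.1, 0.1, 0.1),
                               weights = c(1, 1, 1) / 3
                             ),
                             viral_abundance_model = list(
                               meanlog = log(1200), sdlog = 0.1
                             ),
                             viral_flank_length = 1200,
                             seed = 1L) {
  if (n_host_strains < 1) stop("configuration error: need >= 1 host strain")
  if (length(array_length_range) != 2 ||
      array_length_range[1] > array_length_range[2] ||
      array_length_range[1] < 4) {
    stop("configuration error: array_length_range must be (min, max) with ",
         "min >= 4")
  }
  if (length(spacer_length_range) != 2 ||
      spacer_length_range[1] > spacer_length_range[2] ||
      spacer_length_range[1] < 1) {
    stop("configuration error: invalid spacer_length_range")
  }
  if (is.null(names(repeat_consensus_by_type)) ||
      any(!nzchar(names(repeat_consensus_by_type)))) {
    stop("configuration error: repeat consensuses must be named by type")
  }
  for (p in repeat_consensus_by_type) .pattern_allowed(
    strsplit(toupper(p), "", fixed = TRUE)[[1]]
  )
  if (n_viral_genomes > 0 && !all(mini_array_sizes %in% c(1L, 2L))) {
    stop("configuration error: mini_array_sizes must be in {1, 2}")
  }
  with(abundance_model, {
    if (length(meanlog) != length(sdlog) ||
        length(meanlog) != length(weights)) {
      stop("configuration error: abundance mixture fields must have equal ",
           "length")
    }
    if (abs(sum(weights) - 1) > 1e-8) {
      stop("configuration error: mixture weights must sum to 1")
    }
  })
  structure(list(
    n_host_strains = as.integer(n_host_strains),
    array_length_range = as.integer(array_length_range),
    repeat_consensus_by_type = toupper(repeat_consensus_by_type),
    spacer_length_range = as.integer(spacer_length_range),
    n_viral_genomes = as.integer(n_viral_genomes),
    mini_array_sizes = as.integer(mini_array_sizes),
    leader_length = as.integer(leader_length),
    abundance_model = abundance_model,
    viral_abundance_model = viral_abundance_model,
    viral_flank_length = as.integer(viral_flank_length),
    seed = as.integer(seed)
  ), class = "community_config")
}

#' Draw strain abundances from the configured log-normal mixture
#'
#' Exposed separately so the multimodality of the abundance model can be
#' inspected directly.
#'
#' @param n Number of draws.
#' @param model Mixture list (`meanlog`, `sdlog`, `weights`).
#' @return Numeric vector of abundances.
#' @export
sample_abundances <- function(n, model) {
  comp <- sample.int(length(model$weights), n, replace = TRUE,
                     prob = model$weights)
  stats::rlnorm(n, meanlog = model$meanlog[comp], sdlog = model$sdlog[comp])
}

#' Generate a synthetic community with planted ground truth
#'
#' Builds host strains carrying long CRISPR arrays and viral genomes
#' carrying leader-preceded mini-CRISPR arrays, together with the full
#' ground truth needed to score every downstream stage: the ordered spacer
#' content of every array, the set of true neighbouring-spacer pairs, and
#' per-replicon abundances. Deterministic given `config$seed`.
#'
#' @param config A [community_config()].
#' @return Object of class `crisprome_community`: list with elements
#'   `arrays` (list of per-array records), `spacers` (table of all planted
#'   spacers with ids, array, position, repeat type and source class),
#'   `adjacency` (true ordered pairs), `abundance` (per replicon),
#'   `viruses` (genome sequences and mini-array coordinates, 0-based
#'   half-open) and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  .with_seed(config$seed, {
    types <- names(config$repeat_consensus_by_type)
    slr <- config$spacer_length_range
    alr <- config$array_length_range
    seen <- new.env(hash = TRUE, parent = emptyenv())
    n_sp <- 0L
    new_spacer <- function() {
      repeat {
        len <- sample(slr[1]:slr[2], 1L)
        s <- .random_dna(len)
        if (is.null(seen[[s]])) {
          seen[[s]] <- TRUE
          return(s)
        }
      }
    }

    arrays <- list()
    spacer_rows <- list()
    host_ab <- sample_abundances(config$n_host_strains,
                                 config$abundance_model)
    for (i in seq_len(config$n_host_strains)) {
      strain <- sprintf("strain%03d", i)
      for (ty in types) {
        rep_seq <- iupac_realize(config$repeat_consensus_by_type[[ty]])
        L <- sample(alr[1]:alr[2], 1L)
        seqs <- vapply(seq_len(L), function(k) new_spacer(), character(1))
        ids <- sprintf("sp%05d", n_sp + seq_len(L))
        n_sp <- n_sp + L
        array_id <- paste0(strain, "_", ty)
        arrays[[array_id]] <- list(
          array_id = array_id, replicon_id = strain, kind = "host",
          repeat_type = ty, repeat_seq = rep_seq,
          spacer_ids = ids, spacer_seqs = seqs
        )
        spacer_rows[[array_id]] <- data.frame(
          spacer_id = ids, sequence = seqs, array_id = array_id,
          replicon_id = strain, repeat_type = ty,
          position = seq_along(ids) - 1L, source_class = "long"
        )
      }
    }

    viruses <- list()
    if (config$n_viral_genomes > 0) {
      sizes <- rep_len(config$mini_array_sizes, config$n_viral_genomes)
      viral_ab <- stats::rlnorm(config$n_viral_genomes,
                                config$viral_abundance_model$meanlog,
                                config$viral_abundance_model$sdlog)
      for (j in seq_len(config$n_viral_genomes)) {
        vid <- sprintf("virus%02d", j)
        ty <- types[(j - 1L) %% length(types) + 1L]
        rep_seq <- iupac_realize(config$repeat_consensus_by_type[[ty]])
        sz <- sizes[j]
        seqs <- vapply(seq_len(sz), function(k) new_spacer(), character(1))
        ids <- sprintf("sp%05d", n_sp + seq_len(sz))
        n_sp <- n_sp + sz
        leader <- .random_dna(config$leader_length)
        cassette <- paste0(
          leader,
          paste0(vapply(seqs, function(s) paste0(rep_seq, s), character(1)),
                 collapse = ""),
          rep_seq
        )
        left <- .random_dna(config$viral_flank_length)
        right <- .random_dna(config$viral_flank_length)
        genome <- paste0(left, cassette, right)
        array_id <- paste0(vid, "_", ty)
        arrays[[array_id]] <- list(
          array_id = array_id, replicon_id = vid, kind = "virus",
          repeat_type = ty, repeat_seq = rep_seq,
          spacer_ids = ids, spacer_seqs = seqs
        )
        spacer_rows[[array_id]] <- data.frame(
          spacer_id = ids, sequence = seqs, array_id = array_id,
          replicon_id = vid, repeat_type = ty,
          position = seq_along(ids) - 1L, source_class = "mini"
        )
        arr_start <- nchar(left) + nchar(leader)
        viruses[[vid]] <- list(
          virus_id = vid, genome = genome, array_id = array_id,
          mini_spacer_ids = ids,
          leader_start = nchar(left),
          array_start = arr_start,
          array_end = arr_start + nchar(cassette) - nchar(leader)
        )
      }
    } else {
      viral_ab <- numeric(0)
    }

    spacers <- do.call(rbind, c(spacer_rows, list(make.row.names = FALSE)))
    adj <- do.call(rbind, lapply(arrays, function(a) {
      L <- length(a$spacer_ids)
      if (L < 2) return(NULL)
      data.frame(first_id = a$spacer_ids[-L], second_id = a$spacer_ids[-1],
                 array_id = a$array_id)
    }))
    if (is.null(adj)) {
      adj <- data.frame(first_id = character(0), second_id = character(0),
                        array_id = character(0))
    }
    rownames(adj) <- NULL
    abundance <- data.frame(
      replicon_id = c(sprintf("strain%03d", seq_len(config$n_host_strains)),
                      names(viruses)),
      kind = c(rep("host", config$n_host_strains),
               rep("virus", length(viruses))),
      abundance = c(host_ab, viral_ab)
    )
    structure(list(
      arrays = arrays, spacers = spacers, adjacency = adj,
      abundance = abundance, viruses = viruses, config = config
    ), class = "crisprome_community")
  })
}

#' @export
print.crisprome_community <- function(x, ...) {
  n_long <- sum(vapply(x$arrays, function(a) a$kind == "host", logical(1)))
  cat("Synthetic CRISPR community\n")
  cat("  host strains:   ", x$config$n_host_strains, "\n")
  cat("  long arrays:    ", n_long, "\n")
  cat("  mini-arrays:    ", length(x$viruses), "\n")
  cat("  planted spacers:", nrow(x$spacers), "\n")
  cat("  true adjacencies:", nrow(x$adjacency), "\n")
  invisible(x)
}

#' FASTA records for a synthetic community
#'
#' @param community A [generate_community()] result.
#' @return Named character vector: one record per CRISPR array (the full
#'   repeat-spacer cassette) and one per viral genome.
#' @export
community_fasta <- function(community) {
  arr <- vapply(community$arrays, function(a) {
    paste0(a$repeat_seq,
           paste0(vapply(a$spacer_seqs, function(s) paste0(s, a$repeat_seq),
                         character(1)), collapse = ""))
  }, character(1))
  gen <- vapply(community$viruses, function(v) v$genome, character(1))
  c(arr, gen)
}

#' Parameters for amplicon read simulation
#'
#' @param depth Reads per abundance unit; total reads are
#'   `round(depth * sum(abundance))`, allocated to replicons by a single
#'   multinomial draw with weight abundance x array length (each array
#'   offers one amplicon start per spacer).
#' @param read_length Read length in nt (merged single amplicon reads).
#' @param units_per_read Named probability vector over 1, 2, 3
#'   spacer-repeat units per amplicon.
#' @param substitution_rate Per-base substitution error rate.
#' @param chimera_rate Per-junction probability that the amplicon switches
#'   template to a different array (producing a chimeric spacer pair).
#' @param quality_mean,quality_sd Per-base Phred quality model (truncated
#'   normal, floored at 2, capped at 40).
#' @param primer_fwd,primer_rev Primer pair; the reverse complement of
#'   `primer_rev` closes each amplicon.
#' @param seed Integer seed.
#' @return Object of class `read_sim_params`.
#' @export
read_sim_params <- function(depth = 3,
                            read_length = 250,
                            units_per_read = c(`1` = 0.3, `2` = 0.4,
                                               `3` = 0.3),
                            substitution_rate = 0.005,
                            chimera_rate = 0.01,
                            quality_mean = 35,
                            quality_sd = 3,
                            primer_fwd = default_primers()[["fwd"]],
                            primer_rev = default_primers()[["rev"]],
                            seed = 1L) {
  if (any(units_per_read < 0) || abs(sum(units_per_read) - 1) > 1e-8) {
    stop("configuration error: units_per_read must be probabilities ",
         "summing to 1")
  }
  if (substitution_rate < 0 || substitution_rate > 1 ||
      chimera_rate < 0 || chimera_rate > 1) {
    stop("configuration error: rates must be in [0, 1]")
  }
  structure(list(
    depth = depth, read_length = as.integer(read_length),
    units_per_read = units_per_read,
    substitution_rate = substitution_rate, chimera_rate = chimera_rate,
    quality_mean = quality_mean, quality_sd = quality_sd,
    primer_fwd = toupper(primer_fwd), primer_rev = toupper(primer_rev),
    seed = as.integer(seed)
  ), class = "read_sim_params")
}

#' Simulate amplicon reads from a synthetic community
#'
#' Emits merged amplicon reads of the form
#' `primer + (repeat + spacer) x k + repeat + primer`, `k` in 1..3 (capped
#' by array length), truncated to `read_length`. Reads are sampled from
#' replicons proportionally to abundance x array length, so the expected
#' per-spacer coverage is proportional to replicon abundance alone. With
#' probability `chimera_rate` per junction the amplicon switches template
#' to a different array, joining two spacers that are not adjacent in any
#' real array. About half the reads are emitted reverse-complemented.
#'
#' The truth table records, per read, the planted spacers whose flanking
#' repeats both survive truncation (the extractable units), and the pair
#' truth table records each junction with its chimeric flag.
#'
#' @param community A [generate_community()] result.
#' @param params A [read_sim_params()].
#' @return Object of class `crisprome_reads`: list with `reads`
#'   (`read_id`, `sequence`, `quality`), `truth` (`read_id`, `spacer_id`,
#'   `array_id`, `position`, `is_chimeric`), `pair_truth` (`read_id`,
#'   `first_id`, `second_id`, `is_chimeric`) and `params`.
#' @export
generate_amplicon_reads <- function(community, params = read_sim_params()) {
  stopifnot(inherits(community, "crisprome_community"),
            inherits(params, "read_sim_params"))
  if (length(community$arrays) == 0) stop("community has no arrays")
  arrays <- community$arrays
  ab <- community$abundance
  ab_of <- stats::setNames(ab$abundance, ab$replicon_id)
  arr_len <- vapply(arrays, function(a) length(a$spacer_ids), integer(1))
  rep_len_nt <- vapply(arrays, function(a) nchar(a$repeat_seq), integer(1))
  min_unit <- nchar(params$primer_fwd) + 2L * max(rep_len_nt) +
    min(vapply(arrays, function(a) min(nchar(a$spacer_seqs)), integer(1)))
  if (params$read_length < min_unit) {
    stop("configuration error: read_length shorter than one ",
         "primer + repeat + spacer + repeat unit (", min_unit, " nt)")
  }
  w <- ab_of[vapply(arrays, function(a) a$replicon_id, character(1))] *
    arr_len
  n_reads <- max(1L, round(params$depth * sum(ab$abundance)))

  .with_seed(params$seed, {
    arr_idx <- sample.int(length(arrays), n_reads, replace = TRUE,
                          prob = w / sum(w))
    k_draw <- sample(as.integer(names(params$units_per_read)), n_reads,
                     replace = TRUE, prob = params$units_per_read)
    k_eff <- pmin(k_draw, arr_len[arr_idx])
    starts <- 1L + floor(stats::runif(n_reads) * (arr_len[arr_idx] -
                                                    k_eff + 1L))
    chim_u <- matrix(stats::runif(2L * n_reads), ncol = 2L)
    flip <- stats::runif(n_reads) < 0.5

    primer_tail <- revcomp(params$primer_rev)
    pf_len <- nchar(params$primer_fwd)

    seqs <- character(n_reads)
    truth_acc <- vector("list", n_reads)
    pair_acc <- vector("list", n_reads)

    for (r in seq_len(n_reads)) {
      ai <- arr_idx[r]
      k <- k_eff[r]
      owners <- rep(ai, k)
      poss <- starts[r] + seq_len(k) - 1L
      chim_junction <- rep(FALSE, max(k - 1L, 0L))
      for (j in seq_len(max(k - 1L, 0L))) {
        if (chim_u[r, j] < params$chimera_rate) {
          # template switch: remainder of the amplicon comes from another
          # array, entered at a uniform position
          others <- which(seq_along(arrays) != owners[j])
          fo <- others[sample.int(length(others), 1L,
                                  prob = w[others] / sum(w[others]))]
          fp <- sample.int(arr_len[fo], 1L)
          chim_junction[j] <- TRUE
          rem <- k - j
          take <- min(rem, arr_len[fo] - fp + 1L)
          k <- j + take
          owners <- c(owners[seq_len(j)], rep(fo, take))
          poss <- c(poss[seq_len(j)], fp + seq_len(take) - 1L)
          chim_junction <- c(chim_junction[seq_len(j)],
                             rep(FALSE, max(take - 1L, 0L)))
          break
        }
      }

      segs <- character(2L * k + 2L)
      segs[1] <- params$primer_fwd
      seg_end <- integer(2L * k + 2L)
      pos_cursor <- pf_len
      seg_end[1] <- pos_cursor
      sp_ids <- character(k); sp_arr <- character(k)
      unit_rep_end <- integer(k)  # end of the repeat *closing* each unit
      for (u in seq_len(k)) {
        a <- arrays[[owners[u]]]
        segs[2L * u] <- a$repeat_seq
        segs[2L * u + 1L] <- a$spacer_seqs[poss[u]]
        pos_cursor <- pos_cursor + nchar(a$repeat_seq) +
          nchar(a$spacer_seqs[poss[u]])
        sp_ids[u] <- a$spacer_ids[poss[u]]
        sp_arr[u] <- a$array_id
        unit_rep_end[u] <- pos_cursor +
          nchar(arrays[[owners[min(u + 1L, k)]]]$repeat_seq)
      }
      last <- arrays[[owners[k]]]
      segs[2L * k + 2L] <- paste0(last$repeat_seq, primer_tail)
      # closing repeat of the final unit is the trailing repeat
      unit_rep_end[k] <- pos_cursor + nchar(last$repeat_seq)
      full <- paste(segs, collapse = "")
      seqs[r] <- substr(full, 1L, params$read_length)

      kept <- which(unit_rep_end <= params$read_length)
      if (length(kept)) {
        truth_acc[[r]] <- list(sp = sp_ids[kept], arr = sp_arr[kept],
                               chim = any(chim_junction))
        if (length(kept) >= 2L) {
          jj <- seq_len(length(kept) - 1L)
          pair_acc[[r]] <- list(first = sp_ids[kept[jj]],
                                second = sp_ids[kept[jj + 1L]],
                                chim = chim_junction[kept[jj]])
        }
      }
    }
    t_has <- which(!vapply(truth_acc, is.null, logical(1)))
    t_n <- vapply(truth_acc[t_has], function(x) length(x$sp), integer(1))
    truth_read <- rep(t_has, t_n)
    truth_sp <- as.character(unlist(lapply(truth_acc[t_has], `[[`, "sp"),
                                    use.names = FALSE))
    truth_arr <- as.character(unlist(lapply(truth_acc[t_has], `[[`,
                                            "arr"), use.names = FALSE))
    truth_pos <- sequence(t_n) - 1L
    truth_chim <- rep(vapply(truth_acc[t_has], `[[`, logical(1), "chim"),
                      t_n)
    p_has <- which(!vapply(pair_acc, is.null, logical(1)))
    p_n <- vapply(pair_acc[p_has], function(x) length(x$first),
                  integer(1))
    pt_read <- rep(p_has, p_n)
    pt_first <- as.character(unlist(lapply(pair_acc[p_has], `[[`,
                                           "first"), use.names = FALSE))
    pt_second <- as.character(unlist(lapply(pair_acc[p_has], `[[`,
                                            "second"), use.names = FALSE))
    pt_chim <- as.logical(unlist(lapply(pair_acc[p_has], `[[`, "chim"),
                                 use.names = FALSE))

    # substitution errors: applied after assembly so the same seed with a
    # different rate yields the same error-free templates
    lens <- nchar(seqs)
    off <- cumsum(c(0L, lens))
    total <- off[length(off)]
    if (params$substitution_rate > 0) {
      hit <- which(stats::runif(total) < params$substitution_rate)
      if (length(hit)) {
        read_i <- findInterval(hit - 0.5, off)
        pos_i <- hit - off[read_i]
        alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                        "A", "C", "G"), nrow = 3,
                      dimnames = list(NULL, c("A", "C", "G", "T")))
        pick <- sample.int(3L, length(hit), replace = TRUE)
        for (e in seq_along(hit)) {
          r <- read_i[e]; p <- pos_i[e]
          old <- substr(seqs[r], p, p)
          substr(seqs[r], p, p) <- alt[pick[e], old]
        }
      }
    }

    # per-base Phred qualities: truncated normal, floor 2, cap 40
    qv <- pmin(40L, pmax(2L, as.integer(round(
      stats::rnorm(total, params$quality_mean, params$quality_sd)
    ))))
    quals <- vapply(seq_len(n_reads), function(r) {
      .phred_encode(qv[(off[r] + 1L):off[r + 1L]])
    }, character(1))

    if (any(flip)) {
      seqs[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])
      ))
      quals[flip] <- as.character(Biostrings::reverse(
        Biostrings::BStringSet(quals[flip])
      ))
    }

    read_ids <- sprintf("read%07d", seq_len(n_reads))
    structure(list(
      reads = data.frame(read_id = read_ids, sequence = seqs,
                         quality = quals),
      truth = data.frame(read_id = read_ids[truth_read],
                         spacer_id = truth_sp, array_id = truth_arr,
                         position = truth_pos, is_chimeric = truth_chim),
      pair_truth = data.frame(read_id = read_ids[pt_read],
                              first_id = pt_first, second_id = pt_second,
                              is_chimeric = pt_chim),
      params = params
    ), class = "crisprome_reads")
  })
}

#' @export
print.crisprome_reads <- function(x, ...) {
  cat("Simulated amplicon reads\n")
  cat("  reads:          ", nrow(x$reads), "\n")
  cat("  spacer units:   ", nrow(x$truth), "\n")
  cat("  spacer pairs:   ", nrow(x$pair_truth),
      sprintf(" (%.2f%% chimeric)\n",
              100 * mean(x$pair_truth$is_chimeric)))
  invisible(x)
}

#' Generate a pair of diverged genomes with planted protospacers
#'
#' Emulates a pair of closely related viral genomes (~92% identical by
#' default) whose divergence is concentrated in variable blocks, plus a
#' set of protospacer placements enriched in those variable regions with a
#' configurable odds ratio. Substitution-only divergence, so the two
#' genomes align column-to-column and the returned sequences are their own
#' alignment.
#'
#' @param base_length Genome length in nt.
#' @param target_identity Target alignment identity, in (0.5, 1).
#' @param n_protospacers Number of protospacer placements to plant.
#' @param variable_enrichment Odds ratio favouring placements whose span
#'   overlaps a mismatch column (1 = uniform).
#' @param spacer_length_range `(min, max)` protospacer length in nt.
#' @param variable_fraction Fraction of genome blocks that diverge.
#' @param block_size Block size (nt) for the conserved/variable mosaic.
#' @param seed Integer seed.
#' @return Object of class `diverged_pair`: `genome_a`, `genome_b`,
#'   `alignment` (length-2 character vector), `identity` (realised),
#'   `protospacers` (`start`, `end` 0-based half-open, `strand`, `label`
#'   conserved/variable, `spacer` sequence).
#' @export
generate_diverged_pair <- function(base_length = 20000,
                                   target_identity = 0.92,
                                   n_protospacers = 64,
                                   variable_enrichment = 3,
                                   spacer_length_range = c(35L, 45L),
                                   variable_fraction = 0.4,
                                   block_size = 500,
                                   seed = 1L) {
  if (target_identity <= 0.5 || target_identity >= 1) {
    stop("target_identity must be in (0.5, 1)")
  }
  if (variable_enrichment < 0) stop("variable_enrichment must be >= 0")
  .with_seed(seed, {
    a_chars <- sample(c("A", "C", "G", "T"), base_length, replace = TRUE)
    n_blocks <- ceiling(base_length / block_size)
    n_var <- max(1L, round(variable_fraction * n_blocks))
    var_blocks <- sort(sample.int(n_blocks, n_var))
    block_of <- pmin(n_blocks, (seq_len(base_length) - 1L) %/%
                       block_size + 1L)
    var_col_pool <- which(block_of %in% var_blocks)
    m <- (1 - target_identity) * base_length / length(var_col_pool)
    if (m > 1) {
      stop("generation error: variable blocks too small to reach the ",
           "requested divergence")
    }
    b_chars <- a_chars
    mut <- var_col_pool[stats::runif(length(var_col_pool)) < m]
    if (length(mut) == 0 && variable_enrichment != 1) {
      stop("generation error: enrichment requested but no variable columns")
    }
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                    "A", "C", "G"), nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    b_chars[mut] <- alt[cbind(sample.int(3L, length(mut), replace = TRUE),
                              match(a_chars[mut], colnames(alt)))]
    identity <- mean(a_chars == b_chars)
    mismatch_cs <- c(0L, cumsum(a_chars != b_chars))

    lens <- sample(spacer_length_range[1]:spacer_length_range[2],
                   n_protospacers, replace = TRUE)
    starts <- integer(n_protospacers)
    labels <- character(n_protospacers)
    for (i in seq_len(n_protospacers)) {
      len <- lens[i]
      cand <- seq_len(base_length - len + 1L)
      span_var <- (mismatch_cs[cand + len] - mismatch_cs[cand]) > 0L
      wgt <- ifelse(span_var, variable_enrichment, 1)
      starts[i] <- cand[sample.int(length(cand), 1L, prob = wgt)]
      labels[i] <- if (span_var[starts[i]]) "variable" else "conserved"
    }
    strands <- sample(c("+", "-"), n_protospacers, replace = TRUE)
    genome_a <- paste(a_chars, collapse = "")
    spacer_seq <- substring(genome_a, starts, starts + lens - 1L)
    neg <- strands == "-"
    if (any(neg)) spacer_seq[neg] <- revcomp(spacer_seq[neg])

    structure(list(
      genome_a = genome_a,
      genome_b = paste(b_chars, collapse = ""),
      alignment = c(a = genome_a, b = paste(b_chars, collapse = "")),
      identity = identity,
      protospacers = data.frame(
        start = starts - 1L, end = starts - 1L + lens,
        strand = strands, label = labels, spacer = spacer_seq
      ),
      target_identity = target_identity,
      variable_enrichment = variable_enrichment
    ), class = "diverged_pair")
  })
}

#' @export
print.diverged_pair <- function(x, ...) {
  cat("Diverged genome pair\n")
  cat(sprintf("  length: %d nt, identity %.4f (target %.2f)\n",
              nchar(x$genome_a), x$identity, x$target_identity))
  cat(sprintf("  protospacers: %d (%d conserved / %d variable)\n",
              nrow(x$protospacers),
              sum(x$protospacers$label == "conserved"),
              sum(x$protospacers$label == "variable")))
  invisible(x)
}
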