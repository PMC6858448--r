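# Synthetic community and amplicon read generator

test_that("community generation is deterministic and validates config", {
  cfg <- community_config(n_host_strains = 3, n_viral_genomes = 2,
                          mini_array_sizes = c(1L, 2L), seed = 5)
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1$spacers, c2$spacers)
  expect_identical(community_fasta(c1), community_fasta(c2))

  # no viral genomes -> no mini-arrays in the truth
  c0 <- generate_community(community_config(n_host_strains = 3,
                                            n_viral_genomes = 0, seed = 5))
  expect_length(c0$viruses, 0)
  expect_false(any(c0$spacers$source_class == "mini"))

  expect_error(community_config(array_length_range = c(2, 10)), "min >= 4")
  expect_error(community_config(
    repeat_consensus_by_type = c(A = "ACGTX")), "IUPAC")
  expect_error(community_config(abundance_model = list(
    meanlog = c(1, 2), sdlog = c(0.1, 0.1), weights = c(0.6, 0.6))),
    "sum to 1")

  # no within-array duplicate spacers
  comm <- generate_community(community_config(seed = 6))
  for (a in comm$arrays) expect_false(anyDuplicated(a$spacer_seqs) > 0)
})

test_that("abundance mixture draws are multimodal", {
  model <- community_config()$abundance_model
  draws <- withr::with_seed(21, sample_abundances(10000, model))
  d <- stats::density(log10(draws))
  peaks <- sum(diff(sign(diff(d$y))) == -2)
  expect_equal(peaks, length(model$weights))
})

test_that("read simulation conserves truth counts and is deterministic", {
  sim <- small_sim(seed = 31)
  rd <- sim$reads
  rd2 <- generate_amplicon_reads(sim$community, sim$read_params)
  expect_identical(rd$reads, rd2$reads)
  expect_identical(rd$truth, rd2$truth)

  # every truth row corresponds to one extractable spacer-repeat unit,
  # and pair rows are consecutive units of multi-unit reads
  per_read <- table(rd$truth$read_id)
  per_read_pairs <- table(factor(rd$pair_truth$read_id,
                                 levels = names(per_read)))
  expect_equal(as.integer(per_read_pairs),
               pmax(as.integer(per_read) - 1L, 0L))

  # reads have equal-length sequence and quality strings, qualities >= 2
  expect_equal(nchar(rd$reads$sequence), nchar(rd$reads$quality))
  qmin <- min(vapply(rd$reads$quality,
                     function(q) min(utf8ToInt(q)) - 33L, integer(1)))
  expect_gte(qmin, 2L)
})

test_that("chimeric pair fraction matches the configured rate", {
  sim <- small_sim(seed = 41, depth = 1, chimera_rate = 0.02)
  pt <- sim$reads$pair_truth
  c_hat <- mean(pt$is_chimeric)
  se <- sqrt(0.02 * 0.98 / nrow(pt))
  expect_lt(abs(c_hat - 0.02), 3 * se)

  # chimera_rate = 0: every pair lies in the true adjacency set
  sim0 <- small_sim(seed = 42, chimera_rate = 0)
  expect_false(any(sim0$reads$pair_truth$is_chimeric))
  adj <- paste(sim0$community$adjacency$first_id,
               sim0$community$adjacency$second_id)
  expect_true(all(paste(sim0$reads$pair_truth$first_id,
                        sim0$reads$pair_truth$second_id) %in% adj))
})

test_that("substitution errors follow the configured binomial rate", {
  cfg <- community_config(n_host_strains = 5, n_viral_genomes = 0,
                          seed = 51)
  comm <- generate_community(cfg)
  mk <- function(rate) {
    generate_amplicon_reads(comm, read_sim_params(
      depth = 4, substitution_rate = rate, chimera_rate = 0, seed = 52
    ))
  }
  clean <- mk(0)
  noisy <- mk(0.01)
  expect_identical(nchar(clean$reads$sequence),
                   nchar(noisy$reads$sequence))
  mismatches <- sum(vapply(seq_len(nrow(clean$reads)), function(i) {
    a <- strsplit(clean$reads$sequence[i], "", fixed = TRUE)[[1]]
    b <- strsplit(noisy$reads$sequence[i], "", fixed = TRUE)[[1]]
    sum(a != b)
  }, numeric(1)))
  total <- sum(nchar(clean$reads$sequence))
  expect_lt(abs(mismatches - total * 0.01), 3 * sqrt(total * 0.01 * 0.99))

  # with substitutions off, every extracted spacer is a planted sequence
  expect_true(all(clean$truth$spacer_id %in% comm$spacers$spacer_id))
})

test_that("read_length below one amplicon unit is a configuration error", {
  sim <- small_sim(seed = 61)
  expect_error(
    generate_amplicon_reads(sim$community,
                            read_sim_params(read_length = 60)),
    "configuration error"
  )
})

test_that("diverged genome pairs hit their identity target", {
  dp <- generate_diverged_pair(base_length = 20000,
                               target_identity = 0.92, seed = 71)
  expect_lt(abs(dp$identity - 0.92), 0.01)
  # alignment is column-to-column (substitution-only divergence)
  expect_equal(nchar(dp$genome_a), nchar(dp$genome_b))

  # near-identity limit
  dp2 <- generate_diverged_pair(base_length = 10000,
                                target_identity = 0.999,
                                variable_enrichment = 1, seed = 72)
  expect_gte(dp2$identity, 0.998)
  expect_error(generate_diverged_pair(target_identity = 1.0),
               "target_identity")

  # truth labels agree with a direct per-span check
  a <- strsplit(dp$genome_a, "", fixed = TRUE)[[1]]
  b <- strsplit(dp$genome_b, "", fixed = TRUE)[[1]]
  for (i in sample.int(nrow(dp$protospacers), 10)) {
    span <- (dp$protospacers$start[i] + 1L):dp$protospacers$end[i]
    lbl <- if (all(a[span] == b[span])) "conserved" else "variable"
    expect_equal(dp$protospacers$label[i], lbl)
  }
})

test_that("neutral enrichment places protospacers like the columns", {
  dp <- generate_diverged_pair(base_length = 20000,
                               target_identity = 0.92,
                               n_protospacers = 300,
                               variable_enrichment = 1, seed = 81)
  # null placement: conserved fraction of placements should match the
  # conserved fraction of random spans (estimated by simulation)
  tr <- classify_conservation(dp$alignment)
  lens <- dp$protospacers$end - dp$protospacers$start
  set.seed(82)
  sim_lens <- sample(lens, 5000, replace = TRUE)
  sim_starts <- 1L + floor(stats::runif(5000) * (tr$length - sim_lens + 1L))
  cs <- c(0L, cumsum(!tr$identical))
  p0 <- mean((cs[sim_starts + sim_lens] - cs[sim_starts]) == 0L)
  p_obs <- mean(dp$protospacers$label == "conserved")
  expect_lt(abs(p_obs - p0), 3 * sqrt(p0 * (1 - p0) / 300) + 0.02)
})
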