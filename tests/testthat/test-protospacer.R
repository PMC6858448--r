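# Protospacer mapping, PAM inference, conservation classification and the
# targeting/divergence coincidence test

test_that("planted protospacers are found on both strands", {
  set.seed(501)
  genome <- random_dna(3000)
  sp_fwd <- substr(genome, 1001, 1035)
  sp_rev <- revcomp(substr(genome, 2001, 2040))
  hits <- find_protospacers(c(f = sp_fwd, r = sp_rev), genome)
  hf <- hits[hits$cluster_id == "f", ]
  expect_equal(nrow(hf), 1L)
  expect_equal(hf$start, 1000L)
  expect_equal(hf$end, 1035L)
  expect_equal(hf$strand, "+")
  expect_equal(hf$identity, 1.0)
  hr <- hits[hits$cluster_id == "r", ]
  expect_equal(nrow(hr), 1L)
  expect_equal(hr$start, 2000L)
  expect_equal(hr$strand, "-")
  # flanks: 5' flank of the forward hit is upstream genome sequence
  expect_equal(hf$flank_5, substr(genome, 991, 1000))
  expect_equal(hf$flank_3, substr(genome, 1036, 1045))
  # reverse-strand flanks are oriented to the protospacer strand
  expect_equal(hr$flank_5, revcomp(substr(genome, 2041, 2050)))

  # genome shorter than the spacer: empty result
  expect_equal(nrow(find_protospacers(c(x = sp_fwd), "ACGTACGT")), 0L)
})

test_that("seeded matching equals the sliding-window oracle", {
  set.seed(502)
  genome <- random_dna(5000)
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  for (i in 1:25) {
    len <- sample(30:45, 1)
    pos <- sample(5000 - len, 1)
    sp <- substr(genome, pos, pos + len - 1L)
    # plant up to 3 substitutions, keeping an intact 8-mer seed
    k <- sample(0:3, 1)
    if (k > 0) {
      cc <- strsplit(sp, "", fixed = TRUE)[[1]]
      mut <- sample(setdiff(seq_len(len), 10:20), k)
      cc[mut] <- flip[cc[mut]]
      sp <- paste(cc, collapse = "")
    }
    if (i %% 3 == 0) sp <- revcomp(sp)
    got <- find_protospacers(c(q = sp), genome)
    want <- oracle_protospacers(sp, genome)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(got$start, want$start)
    expect_equal(sort(got$identity), sort(want$identity))
  }
  # random spacers with no planted match: both report nothing
  for (i in 1:10) {
    sp <- random_dna(35)
    expect_equal(nrow(find_protospacers(c(q = sp), genome)),
                 nrow(oracle_protospacers(sp, genome)))
  }
  # the theoretical miss condition is reported per spacer
  h <- find_protospacers(c(q = substr(genome, 101, 160)), genome)
  expect_true(all(h$seed_guaranteed == ((floor(60 * 0.15) + 1) * 8 <= 60)))
})

test_that("PAM consensus recovers planted flank motifs", {
  set.seed(503)
  mk_hits <- function(f5, f3) {
    data.frame(cluster_id = sprintf("c%02d", seq_along(f5)),
               flank_5 = f5, flank_3 = f3)
  }
  # identical flanks reproduce themselves
  h <- mk_hits(rep("CCAGGTTTAA", 6), rep("GGTACCAATT", 6))
  pc <- pam_consensus(h)
  expect_equal(pc$consensus_5, "CCAGGTTTAA")
  expect_equal(pc$consensus_3, "GGTACCAATT")
  # uniformly random flanks give all-N consensus
  h <- mk_hits(replicate(400, random_dna(10)),
               replicate(400, random_dna(10)))
  pc <- pam_consensus(h)
  expect_true(all(strsplit(pc$consensus_5, "")[[1]] == "N"))
  # a planted 3-mer PAM at 90% of sites is recovered
  f5 <- vapply(1:100, function(i) {
    paste0(random_dna(7), if (i <= 90) "CCA" else random_dna(3))
  }, character(1))
  pc <- pam_consensus(mk_hits(f5, replicate(100, random_dna(10))))
  expect_equal(substr(pc$consensus_5, 8, 10), "CCA")
  expect_error(pam_consensus(mk_hits("AAAAAAAAAA", "AAAAAAAAAA")[0, ]),
               "at least 2")
})

test_that("conservation classification is per-column exact", {
  a <- "ACGTACGTACGTACGTACGT"
  tr <- classify_conservation(c(a, a), window = 4)
  expect_true(all(tr$identical))
  expect_true(all(tr$labels == "conserved"))

  b <- a; substr(b, 10, 10) <- "A"  # one substitution column
  tr <- classify_conservation(c(a, b), window = 4)
  expect_equal(sum(!tr$identical), 1L)
  hits <- data.frame(start = c(0L, 11L), end = c(10L, 16L))
  expect_equal(classify_hits(tr, hits), c("variable", "conserved"))
  expect_error(classify_conservation(c(a, substr(b, 1, 10))),
               "length")

  # generated pair: classification equals an exhaustive per-span check
  dp <- generate_diverged_pair(base_length = 4000, seed = 504)
  tr <- classify_conservation(dp$alignment)
  ac <- strsplit(dp$genome_a, "", fixed = TRUE)[[1]]
  bc <- strsplit(dp$genome_b, "", fixed = TRUE)[[1]]
  starts <- seq(1, 4000 - 35, by = 97)
  got <- classify_hits(tr, data.frame(start = starts - 1L,
                                      end = starts + 34L))
  want <- vapply(starts, function(s) {
    if (all(ac[s:(s + 34)] == bc[s:(s + 34)])) "conserved" else "variable"
  }, character(1))
  expect_equal(got, want)
})

test_that("coincidence test is deterministic and label-symmetric", {
  dp <- generate_diverged_pair(base_length = 20000, seed = 505)
  tr <- classify_conservation(dp$alignment)
  ct1 <- coincidence_test(dp$protospacers, tr, seed = 9)
  ct2 <- coincidence_test(dp$protospacers, tr, seed = 9)
  expect_equal(ct1$chi_square, ct2$chi_square)
  expect_equal(ct1$sim_conserved, ct2$sim_conserved)
  expect_equal(ct1$sim_conserved + ct1$sim_variable, 10000L)

  # chi-square invariant to swapping both class labels together
  chi_direct <- function(obs, sim) {
    e <- sum(obs) * sim / sum(sim)
    sum((obs - e)^2 / e)
  }
  obs <- c(ct1$obs_conserved, ct1$obs_variable)
  sim <- c(ct1$sim_conserved, ct1$sim_variable)
  expect_equal(ct1$chi_square, chi_direct(obs, sim))
  expect_equal(chi_direct(obs, sim), chi_direct(rev(obs), rev(sim)))

  # null case: observed split drawn from the simulated proportions
  expect_error(coincidence_test(dp$protospacers[0, ], tr), "at least one")
  same <- classify_conservation(c(dp$genome_a, dp$genome_a))
  expect_error(coincidence_test(dp$protospacers, same), "degenerate")
})

test_that("published-style counts give the expected chi-square", {
  # (22, 42) observed vs (5674, 4326) simulated: direct evaluation of
  # the scaled goodness-of-fit statistic
  e <- 64 * c(5674, 4326) / 10000
  chi <- sum((c(22, 42) - e)^2 / e)
  expect_equal(round(chi, 1), 13.0)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("genome coverage equals interval union", {
  expect_equal(genome_protospacer_coverage(
    data.frame(start = integer(0), end = integer(0)), 200), 0)
  h <- data.frame(start = c(0L, 25L), end = c(50L, 100L))
  expect_equal(genome_protospacer_coverage(h, 200), 0.5)
  # random hits vs per-base oracle
  set.seed(506)
  n <- 300
  starts <- sample(0:9960, n, replace = TRUE)
  h <- data.frame(start = starts, end = starts + sample(25:40, n,
                                                        replace = TRUE))
  covered <- logical(10000)
  for (i in seq_len(n)) covered[(h$start[i] + 1):h$end[i]] <- TRUE
  expect_equal(genome_protospacer_coverage(h, 10000), mean(covered))
  expect_error(genome_protospacer_coverage(
    data.frame(start = -1L, end = 10L), 100), "bounds")
})
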