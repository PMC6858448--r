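# Spacer-pair graph: construction, chimera filtering, path
# reconstruction, eccentricity, component correlation

test_that("pair graph aggregates multiplicities exactly", {
  g <- build_pair_graph(data.frame(first = c("a", "a", "b"),
                                   second = c("b", "b", "c")))
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_equal(g$edges$weight[g$edges$from == "a"], 2L)
  expect_equal(g$edges$weight[g$edges$from == "b"], 1L)
  # weight conservation
  expect_equal(sum(g$edges$weight), 3L)

  g0 <- build_pair_graph(data.frame(first = character(0),
                                    second = character(0)),
                         nodes = c("x", "y"))
  expect_equal(nrow(g0$edges), 0L)
  expect_setequal(g0$nodes, c("x", "y"))
})

test_that("the 5% rule removes weak edges against pre-filter sums", {
  # u has outgoing weights {100, 2}: the weight-2 edge is 1.9% of
  # S_out = 102 and (here) 100% of its head's S_in
  pairs <- data.frame(
    first = c(rep("u", 102), rep("x", 30)),
    second = c(rep("v", 100), rep("w", 2), rep("v", 30))
  )
  g <- build_pair_graph(pairs)
  # under "either": removed (below the outgoing sum)
  f1 <- filter_chimeric_edges(g, mode = "either")
  uw <- f1$report[f1$report$from == "u" & f1$report$to == "w", ]
  expect_true(uw$removed)
  expect_equal(uw$reason, "below_outgoing_sum")
  # under "both": kept, because it is 100% of w's incoming sum
  f2 <- filter_chimeric_edges(g, mode = "both")
  uw2 <- f2$report[f2$report$from == "u" & f2$report$to == "w", ]
  expect_false(uw2$removed)

  # a sole edge is 100% of both sums and survives either mode
  sole <- build_pair_graph(data.frame(first = "p", second = "q"))
  expect_false(any(filter_chimeric_edges(sole, mode = "either")$
                     report$removed))

  # report never removes an edge at or above the fraction of both sums
  rep1 <- f1$report
  safe <- rep1$weight >= 0.05 * rep1$s_out &
    rep1$weight >= 0.05 * rep1$s_in
  expect_false(any(rep1$removed & safe))
})

test_that("chimeric edges vanish in a simulated sample", {
  sim <- small_sim(seed = 301, depth = 2, chimera_rate = 0.01)
  ex <- extract_sim(sim)
  cl <- cluster_spacers(ex$spacers$sequence)
  sp2cl <- stats::setNames(cl$assignment[sim$community$spacers$sequence],
                           sim$community$spacers$spacer_id)
  g <- build_pair_graph(data.frame(
    first = unname(cl$assignment[ex$pairs$first]),
    second = unname(cl$assignment[ex$pairs$second])
  ), nodes = cl$clusters$cluster_id)
  filt <- filter_chimeric_edges(g)
  true_edges <- paste(sp2cl[sim$community$adjacency$first_id],
                      sp2cl[sim$community$adjacency$second_id])
  rep <- filt$report
  removed <- paste(rep$from[rep$removed], rep$to[rep$removed])
  kept <- paste(rep$from[!rep$removed], rep$to[!rep$removed])
  # no true edge removed; all graph edges not in the truth removed
  expect_equal(sum(removed %in% true_edges), 0L)
  expect_true(all(setdiff(c(kept, removed), true_edges) %in% removed))
  # chimera-free graph equals the observed adjacency set
  expect_true(all(kept %in% true_edges))
})

test_that("path reconstruction enumerates maximal source-sink paths", {
  chain <- build_pair_graph(data.frame(
    first = c("a", "b", "c", "d"), second = c("b", "c", "d", "e")
  ))
  p <- reconstruct_paths(chain)
  expect_length(p$paths, 1L)
  expect_equal(p$paths[[1]], c("a", "b", "c", "d", "e"))
  expect_equal(p$summary$length, 5L)
  expect_equal(p$summary$min_weight, 1L)

  fork <- build_pair_graph(data.frame(first = c("a", "a"),
                                      second = c("b", "c")))
  p <- reconstruct_paths(fork)
  expect_length(p$paths, 2L)
  expect_setequal(vapply(p$paths, paste, character(1), collapse = ","),
                  c("a,b", "a,c"))

  # isolated nodes come back as single-spacer paths
  iso <- build_pair_graph(data.frame(first = "a", second = "b"),
                          nodes = c("a", "b", "z"))
  p <- reconstruct_paths(iso)
  expect_true(list("z") %in% p$paths)

  # a cycle is broken at its lowest-weight edge and logged
  cyc <- build_pair_graph(data.frame(
    first = c(rep("a", 5), rep("b", 5), rep("c", 2)),
    second = c(rep("b", 5), rep("c", 5), rep("a", 2))
  ))
  p <- reconstruct_paths(cyc)
  expect_equal(nrow(p$cycle_edges_removed), 1L)
  expect_equal(p$cycle_edges_removed$from, "c")
  expect_equal(p$paths[[1]], c("a", "b", "c"))
})

test_that("eccentricity DP matches exhaustive path enumeration", {
  # fixed cases
  chain <- build_pair_graph(data.frame(
    first = c("a", "b", "c", "d"), second = c("b", "c", "d", "e")
  ))
  ecc <- node_eccentricity(chain)
  expect_equal(ecc$eccentricity[ecc$cluster_id == "c"], 5L)
  iso <- build_pair_graph(data.frame(first = "a", second = "b"),
                          nodes = c("a", "b", "z"))
  ecc <- node_eccentricity(iso)
  expect_equal(ecc$eccentricity[ecc$cluster_id == "z"], 1L)

  # random DAGs vs the exhaustive oracle
  set.seed(302)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    pairs <- random_dag(n, p = stats::runif(1, 0.15, 0.5))
    if (nrow(pairs) == 0) next
    g <- build_pair_graph(pairs)
    got <- node_eccentricity(g)
    want <- oracle_eccentricity(g$nodes, g$edges)
    expect_equal(got[order(got$cluster_id), ],
                 want[order(want$cluster_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("components with proportional abundances group together", {
  ab <- rbind(
    c1 = c(10, 100, 40), c2 = c(12, 110, 44),  # component 1
    c3 = c(5, 50, 20), c4 = c(6, 55, 22),      # component 2 (prop to 1)
    c5 = c(80, 8, 30), c6 = c(90, 6, 28)       # component 3 (different)
  )
  colnames(ab) <- c("s1", "s2", "s3")
  comp <- stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L), rownames(ab))
  out <- correlate_components(ab, comp, r_threshold = 0.95)
  grp <- stats::setNames(out$groups$group_id, out$groups$component_id)
  expect_equal(grp[["1"]], grp[["2"]])
  expect_false(grp[["1"]] == grp[["3"]])
  expect_error(correlate_components(ab[, 1, drop = FALSE], comp),
               "2 samples")
})
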