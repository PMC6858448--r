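# Semi-global identity, greedy clustering, diversity summaries

test_that("semi-global identity handles end gaps and substitutions", {
  x <- random_dna_fixed(40, 201)
  expect_equal(semi_global_identity(x, x), 1.0)
  # terminal gaps are free
  expect_equal(semi_global_identity("AAAAAAAAAA", "TTAAAAAAAAAATT"), 1.0)
  # five planted substitutions in a 35-mer: 30/35
  a <- random_dna_fixed(35, 202)
  b_chars <- strsplit(a, "", fixed = TRUE)[[1]]
  pos <- c(3, 9, 15, 21, 30)
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  b_chars[pos] <- flip[b_chars[pos]]
  b <- paste(b_chars, collapse = "")
  expect_equal(semi_global_identity(a, b), 30 / 35)
  expect_equal(semi_global_identity(b, a), 30 / 35)  # symmetric
  expect_error(semi_global_identity("", "ACGT"), "non-empty")
})

test_that("alignment scores agree with an independent aligner", {
  # same objective (unit match/mismatch, linear unit gap, free end gaps)
  # scored independently by Biostrings
  mat <- local({
    b <- c("A", "C", "G", "T")
    m <- matrix(-1, 4, 4, dimnames = list(b, b)); diag(m) <- 1; m
  })
  set.seed(203)
  for (i in 1:40) {
    la <- sample(25:60, 1); lb <- sample(25:60, 1)
    a <- random_dna(la)
    b <- if (i %% 2 == 0) {
      # related pair: mutate a few bases of a prefix/suffix of a
      bb <- strsplit(substr(a, 1, lb), "", fixed = TRUE)[[1]]
      k <- sample(0:4, 1)
      if (k > 0) {
        pos <- sample(seq_along(bb), k)
        bb[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      }
      paste(bb, collapse = "")
    } else random_dna(lb)
    ours <- crisprome:::.sg_pair_cpp(a, b)[["score"]]
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE
    )
    expect_equal(ours, max(ref, 0))
  }
})

test_that("greedy clustering respects the identity threshold", {
  # duplicates only: one cluster
  cl <- cluster_spacers(rep(random_dna_fixed(40, 204), 10))
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$total, 10L)

  # two 40-mers at ~70% identity: two clusters
  a <- random_dna_fixed(40, 205)
  b_chars <- strsplit(a, "", fixed = TRUE)[[1]]
  pos <- withr::with_seed(206, sample(40, 12))
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  b_chars[pos] <- flip[b_chars[pos]]
  b <- paste(b_chars, collapse = "")
  expect_lt(semi_global_identity(a, b), 0.85)
  cl <- cluster_spacers(c(rep(a, 3), rep(b, 2)))
  expect_equal(nrow(cl$clusters), 2L)
  # centroid of the larger cluster is the more abundant sequence
  expect_equal(cl$clusters$centroid[1], a)

  # planted families: intra-family identity >= 0.9, inter < 0.6
  set.seed(207)
  centers <- replicate(5, random_dna(40))
  seqs <- unlist(lapply(centers, function(ctr) {
    c(rep(ctr, 4), vapply(1:6, function(i) {
      cc <- strsplit(ctr, "", fixed = TRUE)[[1]]
      pos <- sample(40, sample(1:3, 1))
      cc[pos] <- vapply(cc[pos], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1)
      }, character(1))
      paste(cc, collapse = "")
    }, character(1)))
  }))
  cl <- cluster_spacers(seqs)
  expect_equal(nrow(cl$clusters), 5L)
  expect_setequal(cl$clusters$centroid, centers)
  # every member reaches the threshold against its centroid
  cent_of <- stats::setNames(cl$clusters$centroid,
                             cl$clusters$cluster_id)
  for (s in names(cl$assignment)) {
    expect_gte(semi_global_identity(s, cent_of[[cl$assignment[[s]]]]),
               0.85)
  }

  # deterministic under resampling order (input order must not matter)
  cl2 <- cluster_spacers(withr::with_seed(208, sample(seqs)))
  expect_equal(sort(cl2$clusters$centroid), sort(cl$clusters$centroid))
})

test_that("per-sample cluster abundances sum to the observations", {
  set.seed(209)
  seqs <- c(replicate(30, random_dna(35)))
  obs <- sample(seqs, 200, replace = TRUE)
  samples <- sample(c("s1", "s2"), 200, replace = TRUE)
  cl <- cluster_spacers(obs, samples)
  expect_equal(sum(cl$abundance), 200L)
  expect_equal(unname(colSums(cl$abundance)),
               as.integer(table(samples)))
  expect_equal(cl$clusters$total, as.integer(rowSums(cl$abundance)))
})

test_that("diversity summaries match their formulas", {
  expect_equal(goods_coverage(c(3, 5, 10)), 1.0)
  expect_equal(goods_coverage(rep(1, 7)), 0.0)
  expect_equal(goods_coverage(c(1, 2, 3, 10, 10)), 0.6)
  expect_error(goods_coverage(integer(0)), "empty")

  expect_equal(shannon_chao(5)$shannon_H, 0)
  expect_equal(shannon_chao(rep(4, 8))$shannon_H, log(8))
  expect_equal(shannon_chao(c(1, 1, 2, 3))$chao1, 4 + 4 / 2)

  expect_equal(loss_confidence(0, 50), 0)
  expect_equal(loss_confidence(1, 50), 0)
  expect_equal(loss_confidence(0.5, 100),
               stats::qnorm(0.975) * sqrt(0.25 / 100))
  expect_error(loss_confidence(0.5, 0), "N must be")

  # Shannon agrees with vegan on random count vectors
  set.seed(210)
  for (i in 1:5) {
    counts <- sample(1:50, 20, replace = TRUE)
    expect_equal(shannon_chao(counts)$shannon_H,
                 unname(vegan::diversity(counts, index = "shannon")))
  }
  # bias-corrected Chao1 (no doubletons) agrees with vegan's estimator
  counts <- c(1, 1, 1, 3, 4, 10)
  expect_equal(shannon_chao(counts)$chao1,
               unname(vegan::estimateR(counts)["S.chao1"]))
})

test_that("cross-type intersection finds shared spacers", {
  set.seed(211)
  a <- replicate(30, random_dna(38))
  b <- replicate(30, random_dna(38))
  # identical sets: full intersection
  m <- cross_type_intersection(list(A = a, B = a))
  expect_equal(m["A", "B"], 1.0)
  expect_equal(m["B", "A"], 1.0)
  # disjoint random sets: zero
  m <- cross_type_intersection(list(A = a, B = b))
  expect_equal(m["A", "B"], 0.0)
  # planted sharing: 6 of 30 type-A spacers present in B within 2
  # mismatches
  b2 <- b
  b2[1:6] <- vapply(a[1:6], function(s) {
    cc <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- sample(38, 2)
    cc[pos] <- vapply(cc[pos], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    paste(cc, collapse = "")
  }, character(1))
  m <- cross_type_intersection(list(A = a, B = b2))
  expect_equal(m["A", "B"], 6 / 30)
  expect_error(cross_type_intersection(list(A = a)), "two repeat types")
})
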