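# Running-sum enrichment: closed forms, oracle equivalence, permutation
# significance, leading edges, network and cross-comparison summaries.

test_that("closed-form enrichment scores match the hand computations", {
  rl <- ranked_list(letters[1:6], c(2, 1.5, 1, -0.5, -1, -2))
  top <- enrichment_score(rl, c("a", "b"), exponent = 0)
  expect_equal(top$es, 1.0)
  expect_equal(top$running_sum, c(0.5, 1, 0.75, 0.5, 0.25, 0))
  mid <- enrichment_score(rl, c("a", "c"), exponent = 0)
  expect_equal(mid$es, 0.75)
  expect_equal(mid$running_sum, c(0.5, 0.25, 0.75, 0.5, 0.25, 0))
  bottom <- enrichment_score(rl, c("e", "f"), exponent = 0)
  expect_equal(bottom$es, -1.0)
})

test_that("streaming and full scores equal the brute-force oracle exactly", {
  set.seed(11)
  for (i in 1:200) {
    N <- sample(5:20, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    k <- sample(1:(N - 1), 1)
    hits <- sort(sample(N, k))
    rl <- ranked_list(sprintf("f%02d", 1:N), scores)
    for (p in c(0, 1)) {
      expected <- oracle_es(scores, hits, p)
      full <- enrichment_score(rl, rl$feature[hits], exponent = p)
      expect_identical(full$es, expected)
      # the O(N_H) fast path agrees in magnitude always, and in sign
      # whenever the two extremes are not an exact tie
      w <- abs(scores)^p
      stream <- stromasig:::es_stream(hits, w[hits], N)
      expect_equal(abs(stream), abs(expected), tolerance = 1e-12)
      tie_gap <- abs(max(full$running_sum) + min(full$running_sum))
      if (tie_gap > 1e-9) expect_equal(stream, expected, tolerance = 1e-12)
      expect_true(abs(full$es) <= 1)
      expect_equal(abs(full$es), max(abs(full$running_sum)))
    }
  }
})

test_that("unweighted ES depends only on hit positions and is antisymmetric", {
  set.seed(12)
  scores <- sort(rnorm(10), decreasing = TRUE)
  rl1 <- ranked_list(letters[1:10], scores)
  rl2 <- ranked_list(letters[1:10], sort(rexp(10), decreasing = TRUE))
  hits <- c(2, 5, 6)
  expect_identical(enrichment_score(rl1, letters[hits], exponent = 0)$es,
                   enrichment_score(rl2, letters[hits], exponent = 0)$es)
  # reversing the list negates the unweighted ES
  rl_rev <- ranked_list(rev(letters[1:10]), -rev(scores))
  expect_equal(enrichment_score(rl_rev, letters[hits], exponent = 0)$es,
               -enrichment_score(rl1, letters[hits], exponent = 0)$es,
               tolerance = 1e-12)
})

test_that("weighted ES agrees with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  for (i in 1:50) {
    N <- sample(10:40, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    hits <- sort(sample(N, sample(2:8, 1)))
    rl <- ranked_list(sprintf("f%02d", 1:N), scores)
    ours <- enrichment_score(rl, rl$feature[hits], exponent = 1)$es
    ref <- fgsea::calcGseaStat(setNames(scores, rl$feature), hits,
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected or fall back as documented", {
  rl <- ranked_list(letters[1:6], c(2, 1.5, 1, -0.5, -1, -2))
  expect_error(enrichment_score(rl, c("z", "y")), "no set member")
  expect_error(enrichment_score(rl, letters[1:6]), "whole ranked universe")
  rl0 <- ranked_list(letters[1:6], c(0, 0, 0, 0, 0, 0))
  expect_warning(es0 <- enrichment_score(rl0, c("a", "b"), exponent = 1),
                 "unweighted")
  expect_equal(es0$es, 1.0)
})

test_that("permutation significance is seeded, bounded and order-invariant", {
  set.seed(14)
  scores <- sort(rnorm(100), decreasing = TRUE)
  rl <- ranked_list(sprintf("f%03d", 1:100), scores)
  coll <- list(top = rl$feature[1:8],
               rand = rl$feature[c(5, 20, 41, 66, 90)],
               broad = rl$feature[2:99])
  r1 <- permutation_significance(rl, coll, B = 199, seed = 3)
  r2 <- permutation_significance(rl, coll, B = 199, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 200 & r1$p <= 1))
  expect_lt(r1$p[r1$set == "top"], 0.02)
  # a set covering nearly the whole universe cannot be called significant:
  # every same-size random draw shares almost all its members
  broad <- r1[r1$set == "broad", ]
  expect_gt(broad$p, 0.2)
  # results do not depend on collection order (per-set substreams)
  r3 <- permutation_significance(rl, rev(coll), B = 199, seed = 3)
  expect_equal(r3[match(r1$set, r3$set), c("es", "nes", "p", "q")],
               r1[, c("es", "nes", "p", "q")], ignore_attr = TRUE)
  expect_error(permutation_significance(rl, coll, B = 50), "B must be")
})

test_that("set-permutation p-values are near-uniform on a null list", {
  set.seed(15)
  scores <- sort(rnorm(300), decreasing = TRUE)
  rl <- ranked_list(sprintf("f%03d", 1:300), scores)
  coll <- lapply(1:200, function(i) sample(rl$feature, 20))
  names(coll) <- paste0("S", 1:200)
  res <- permutation_significance(rl, coll, B = 199, seed = 4)
  # two-sided: fold the signed one-sided p back to a uniform scale
  u <- ifelse(res$es > 0, res$p / 2, 1 - res$p / 2)
  d <- suppressWarnings(ks.test(u, "punif")$statistic)
  expect_lt(unname(d), 0.1)
})

test_that("leading edges bracket the running-sum extremum", {
  rl <- ranked_list(letters[1:6], c(2, 1.5, 1, -0.5, -1, -2))
  top <- enrichment_score(rl, c("a", "b"), exponent = 0)
  expect_identical(leading_edge(top), c("a", "b"))
  mid <- enrichment_score(rl, c("a", "c"), exponent = 0)
  expect_identical(leading_edge(mid), c("a", "c"))  # extremum at position 3
  bottom <- enrichment_score(rl, c("e", "f"), exponent = 0)
  expect_identical(leading_edge(bottom), c("e", "f"))
  partial <- enrichment_score(rl, c("a", "f"), exponent = 0)
  expect_identical(leading_edge(partial), "a")
})

test_that("leading-edge intersection requires two results", {
  expect_identical(leading_edge_intersection(list(c("a", "b", "c"),
                                                  c("b", "c", "d"))),
                   c("b", "c"))
  expect_identical(leading_edge_intersection(list(c("a"), c("b"))),
                   character(0))
  expect_error(leading_edge_intersection(list(c("a", "b"))), "at least 2")
})

test_that("enrichment networks connect significant sets by shared members", {
  set.seed(16)
  scores <- sort(rnorm(60), decreasing = TRUE)
  rl <- ranked_list(sprintf("f%02d", 1:60), scores)
  coll <- list(A = rl$feature[1:7], B = rl$feature[c(1:4, 9:11)],
               C = rl$feature[c(5, 14, 23, 32, 41, 50, 59)],
               D = rl$feature[55:60])
  res <- permutation_significance(rl, coll, B = 199, seed = 5)
  net <- enrichment_network(res, min_shared = 1, p_cut = 0.05)
  expect_true(all(c("A", "B") %in% net$nodes$set))
  expect_equal(net$nodes$size[net$nodes$set == "A"], 7)
  ab <- net$edges[net$edges$source == "A" & net$edges$target == "B", ]
  if (nrow(ab)) expect_equal(ab$shared_count, 4)
  expect_false("C" %in% net$nodes$set)
})

test_that("cross-comparison summary applies the signed -log10 convention", {
  mk <- function(sets, es, p) {
    structure(data.frame(set = sets, size = 10, es = es, nes = es, p = p,
                         q = p, stringsAsFactors = FALSE),
              class = c("enrichment_result", "data.frame"))
  }
  res <- list(c1 = mk(c("S1", "S2"), c(1, -0.5), c(0.01, 0.04)),
              c2 = mk(c("S1", "S2"), c(1, 0.5), c(0.2, 0.2)),
              c3 = mk(c("S1", "S2"), c(1, 0.5), c(0.03, 0.6)))
  cc <- cross_comparison_summary(res, p_cut = 0.05, min_contrasts = 2)
  expect_identical(rownames(cc), "S1")  # S2 significant only once
  expect_equal(cc["S1", "c1"], 2)
  res$c1$es[1] <- -1
  cc2 <- cross_comparison_summary(res, p_cut = 0.05, min_contrasts = 2)
  expect_equal(cc2["S1", "c1"], -2)
})

test_that("phenotype permutation scheme runs and is seeded", {
  co <- small_cohort(seed = 21)
  de <- run_paired_de(co$genes, "CAF", "HPF")
  rl <- rank_features(de)
  coll <- small_collection(co$truth, seed = 22)
  r1 <- permutation_significance(rl, coll["PLANTED_SHARED_UP_1"], B = 99,
                                 scheme = "phenotype", seed = 6,
                                 em = co$genes, condition_a = "CAF",
                                 condition_b = "HPF")
  r2 <- permutation_significance(rl, coll["PLANTED_SHARED_UP_1"], B = 99,
                                 scheme = "phenotype", seed = 6,
                                 em = co$genes, condition_a = "CAF",
                                 condition_b = "HPF")
  expect_identical(r1, r2)
  expect_true(is.finite(r1$p))
  expect_error(permutation_significance(rl, coll[1], B = 99,
                                        scheme = "phenotype", seed = 6),
               "requires")
})
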