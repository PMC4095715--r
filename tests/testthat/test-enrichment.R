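test_that("relative weights reproduce the two-pathway hand case and average to 1", {
  coll <- make_collection(list(pwA = c("1", "2"), pwB = c("3", "4")))
  # 1-C member values {0.2,0.4} and {0.6,0.8}
  C <- stats::setNames(1 - c(0.2, 0.4, 0.6, 0.8), as.character(1:4))
  W <- pathway_relative_weight(coll, C)
  expect_equal(unname(W), c(0.6, 1.4), tolerance = 1e-12)
  expect_equal(unname(W["pwA"]^6), 0.046656, tolerance = 1e-12)
  # all C equal -> all W = 1
  W1 <- pathway_relative_weight(coll, stats::setNames(rep(0.3, 4),
                                                      as.character(1:4)))
  expect_equal(unname(W1), c(1, 1))
  # algebraic identity on random contexts
  for (s in 1:20) {
    set.seed(s)
    ids <- as.character(1:40)
    Cr <- stats::setNames(runif(40), ids)
    K <- sample(3:8, 1)
    sets <- lapply(seq_len(K), function(i) sample(ids, sample(3:10, 1)))
    names(sets) <- paste0("p", seq_len(K))
    Wr <- pathway_relative_weight(make_collection(sets), Cr)
    expect_equal(mean(Wr), 1, tolerance = 1e-9)
  }
  expect_error(pathway_relative_weight(
    coll, stats::setNames(rep(1, 4), as.character(1:4))), "vanish")
})

test_that("Wallenius p-value matches exact central and weighted-urn values", {
  expect_equal(wallenius_pvalue(0, 5, 3, 10, 2), 1)          # empty sum
  # central case N=8, m1=4, n=3, g=2: 28/56
  expect_equal(wallenius_pvalue(2, 3, 4, 8, 1, 1), 0.5, tolerance = 1e-8)
  # weighted sequential urn: N=6, m1=3, n=2, w1=2, g=2 -> (6/9)(4/7)
  expect_equal(wallenius_pvalue(2, 2, 3, 6, 2, 1), 8 / 21, tolerance = 1e-8)
  # census draw is degenerate
  expect_equal(wallenius_pvalue(3, 6, 4, 6, 3.7, 1), 1)
  # pmf sums to one
  expect_equal(sum(wallenius_pmf(7, 9, 25, 0.2)), 1, tolerance = 1e-9)
  expect_equal(sum(wallenius_pmf(12, 30, 200, 4)), 1, tolerance = 1e-9)
})

test_that("Wallenius p-value agrees with the urn dynamic-programming oracle", {
  set.seed(9)
  for (rep in 1:30) {
    N <- sample(5:40, 1)
    m1 <- sample(1:(N - 1), 1)
    n <- sample(1:min(N - 1, 12), 1)
    g <- sample(0:min(n, m1), 1)
    w1 <- exp(runif(1, -2, 2))
    expect_equal(wallenius_pvalue(g, n, m1, N, w1),
                 urn_exact_tail(g, n, m1, N, w1), tolerance = 1e-8)
  }
})

test_that("Wallenius p-value is monotone nondecreasing in w1", {
  ws <- exp(seq(log(1e-3), log(1e3), length.out = 60))
  for (case in list(c(3, 8, 10, 40), c(1, 5, 4, 30), c(5, 12, 20, 100))) {
    p <- vapply(ws, function(w) wallenius_pvalue(case[1], case[2], case[3],
                                                 case[4], w), 0)
    expect_true(all(diff(p) >= -1e-9))
  }
})

test_that("Wallenius argument validation names the offender", {
  expect_error(wallenius_pvalue(5, 3, 10, 20, 1), "invalid g")
  expect_error(wallenius_pvalue(1, 3, 25, 20, 1), "invalid m1")
  expect_error(wallenius_pvalue(1, 25, 10, 20, 1), "invalid n")
  expect_error(wallenius_pvalue(1, 3, 10, 20, 0), "invalid w1")
  expect_error(wallenius_pvalue(1, 3, 10, 20, 1, -1), "invalid w2")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_identical(order(adj, p), order(p, p))  # significance order kept
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("uniform CGNB reduces the pipeline to the central hypergeometric test", {
  cfg <- simulation_config(seed = 21, n_nodes = 80, n_pathways = 6,
                           bias_strength = 0.7)
  net <- simulate_network(cfg)
  gn <- compute_gn(compute_gcs(net))
  coll <- simulate_pathways(net, cfg, gn = gn)
  interesting <- simulate_interesting(net, coll, cfg, gn = gn)
  res <- run_mpinet(interesting, net, coll, weight_exponent = 0,
                    min_pathway_size = 3)
  N <- length(intersect(unique(unlist(coll$pathways)), net$nodes))
  n <- length(intersect(interesting, intersect(unique(unlist(coll$pathways)),
                                               net$nodes)))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$pvalue[i],
                 stats::phyper(res$g[i] - 1, res$m1[i], N - res$m1[i], n,
                               lower.tail = FALSE),
                 tolerance = 1e-8)
    expect_equal(res$w1[i], 1)
  }
})

test_that("of two pathways with identical counts, the high-CGNB one is more significant", {
  cfg <- simulation_config(seed = 5, n_nodes = 80, n_pathways = 2,
                           bias_base = 0.15, bias_strength = 0.7)
  net <- simulate_network(cfg)
  gn <- compute_gn(compute_gcs(net))
  ord <- names(sort(gn))
  pwA <- ord[1:6]                       # low GN -> high CGNB
  pwB <- ord[(length(ord) - 5):length(ord)]  # high GN -> low CGNB
  coll <- make_collection(list(pwA = sort(pwA), pwB = sort(pwB)))
  set.seed(99)
  others <- setdiff(names(sort(gn, decreasing = TRUE))[1:30], c(pwA, pwB))
  interesting <- c(pwA[1:2], pwB[1:2], sample(others, 8))
  res <- run_mpinet(interesting, net, coll, min_pathway_size = 2,
                    background = net$nodes)
  expect_equal(res$m1[res$pathway_id == "pwA"], res$m1[res$pathway_id == "pwB"])
  expect_equal(res$g[res$pathway_id == "pwA"], res$g[res$pathway_id == "pwB"])
  expect_lt(res$relative_weight[res$pathway_id == "pwA"],
            res$relative_weight[res$pathway_id == "pwB"])
  expect_lt(res$pvalue[res$pathway_id == "pwA"],
            res$pvalue[res$pathway_id == "pwB"])
})

test_that("pipeline output is deterministic and sorted by significance", {
  cfg <- simulation_config(seed = 13, n_nodes = 60, n_pathways = 5)
  net <- simulate_network(cfg)
  coll <- simulate_pathways(net, cfg)
  interesting <- simulate_interesting(net, coll, cfg)
  r1 <- run_mpinet(interesting, net, coll)
  r2 <- run_mpinet(interesting, net, coll)
  expect_identical(r1, r2)
  expect_true(!is.unsorted(r1$pvalue))
  expect_true(all(r1$fdr >= r1$pvalue))
  f <- tempfile(fileext = ".tsv")
  write_results(r1, f)
  expect_identical(readLines(f)[1],
                   paste("pathway_id", "pathway_name", "m1", "g",
                         "relative_weight", "w1", "pvalue", "fdr",
                         "interesting_members", sep = "\t"))
})

test_that("GN bias diagnostic gives exact tail probabilities and sane conventions", {
  set.seed(31)
  gn <- stats::setNames(sample(seq(0.01, 1, length.out = 20)),
                        as.character(1:20))
  top3 <- names(sort(gn, decreasing = TRUE))[1:3]
  coll <- make_collection(list(top = top3, all = names(gn)))
  p_one <- pathway_gn_bias_test(coll, gn, sides = "one")
  # enumeration oracle: rank sum of 3 member ranks among all C(20,3) subsets
  rks <- rank(gn)
  obs <- sum(rks[top3])
  combos <- combn(20, 3)
  p_exact <- mean(colSums(matrix(rks[combos], nrow = 3)) >= obs)
  expect_equal(unname(p_one["top"]), p_exact, tolerance = 1e-10)
  expect_equal(unname(p_one["all"]), 1)  # whole-network pathway convention
  p_two <- pathway_gn_bias_test(coll, gn, sides = "two")
  expect_equal(unname(p_two["top"]), min(1, 2 * p_exact), tolerance = 1e-10)
  coll_missing <- make_collection(list(gone = c("900", "901")))
  expect_warning(pathway_gn_bias_test(coll_missing, gn), "skipped")
})

test_that("crosstalk edges require cross-set connectivity above the global median", {
  # two disjoint components as two pathways: cross-set mean GCS is 0
  net <- build_network(data.frame(a = c("1", "3"), b = c("2", "4"),
                                  score = c(900L, 800L)))
  gcs <- compute_gcs(net, beta = 0.5, lmax = 4)
  coll <- make_collection(list(left = c("1", "2"), right = c("3", "4")))
  expect_equal(nrow(pathway_crosstalk(coll, gcs)), 0L)
  # duplicated pathway on a connected 5-node graph
  net5 <- random_network(5, p = 0.9, seed = 6)
  g5 <- compute_gcs(net5, beta = 0.5, lmax = 4)
  dup <- make_collection(list(a = net5$nodes[1:3], b = net5$nodes[1:3]))
  ct <- pathway_crosstalk(dup, g5)
  idx <- match(net5$nodes[1:3], g5$ids)
  internal_mean <- mean(g5$values[idx, idx])
  med <- stats::median(g5$values[upper.tri(g5$values)])
  if (internal_mean > med) {
    expect_equal(ct$mean_gcs, internal_mean)
  } else {
    expect_equal(nrow(ct), 0L)
  }
  expect_error(pathway_crosstalk(make_collection(list(a = "1")), g5),
               "at least 2")
})

test_that("pathway-list overlap significance follows the hypergeometric tail", {
  expect_equal(overlap_pvalue(paste0("a", 1:5), paste0("b", 1:5), 20), 1)
  u <- paste0("p", 1:10)
  expect_equal(overlap_pvalue(u, u, 10), 1)
  expect_equal(overlap_pvalue(paste0("p", 1:5), paste0("p", 1:5), 20),
               1 / choose(20, 5), tolerance = 1e-12)
  expect_error(overlap_pvalue(paste0("p", 1:30), paste0("p", 1:5), 20),
               "universe")
})
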