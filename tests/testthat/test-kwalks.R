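test_that("transition matrices are row-stochastic and proportional to weights", {
  set.seed(301)
  for (i in 1:10) {
    net <- random_small_network(sample(4:10, 1))
    tm <- transition_matrix(net)
    expect_equal(unname(rowSums(tm$P)), rep(1, nrow(tm$P)), tolerance = 1e-12)
    # each entry is weight / weighted degree
    w <- stats::setNames(rep(0, length(tm$nodes)), tm$nodes)
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges$gene_a[r]; b <- net$edges$gene_b[r]
      w[a] <- w[a] + net$edges$weight[r]
      w[b] <- w[b] + net$edges$weight[r]
    }
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges$gene_a[r]; b <- net$edges$gene_b[r]
      expect_equal(tm$P[a, b], unname(net$edges$weight[r] / w[a]),
                   tolerance = 1e-12)
      expect_equal(tm$P[b, a], unname(net$edges$weight[r] / w[b]),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero-weight nodes are dropped from the transition matrix", {
  net <- toy_network(cbind(c("A", "B", "C"), c("B", "C", "D")), c(1, 0, 0))
  tm <- transition_matrix(net)
  expect_setequal(tm$nodes, c("A", "B"))
  expect_setequal(tm$dropped, c("C", "D"))
})

test_that("the path-graph hand computation gives internal relevance exactly 1.5", {
  net <- toy_network(cbind(c("A", "B"), c("B", "C")), c(1, 1))
  tm <- transition_matrix(net)
  rel <- limited_kwalks(tm, c("A", "C"), L = 3L)
  # average over both start seeds of the expected number of visits to B
  expect_identical(unname(rel$node_relevance["B"]), 1.5)
  expect_identical(unname(rel$node_relevance["A"]), 0.5)
  expect_identical(unname(rel$node_relevance["C"]), 0.5)
  er <- rel$edge_relevance
  expect_equal(er$relevance[er$from == "A" & er$to == "B"], 0.75)
  expect_equal(er$relevance[er$from == "B" & er$to == "A"], 0.50)
})

test_that("node relevance equals the edge relevance flowing into each node", {
  set.seed(302)
  net <- random_small_network(8)
  tm <- transition_matrix(net)
  rel <- limited_kwalks(tm, c("N01", "N05", "N08"), L = 20L)
  er <- rel$edge_relevance
  in_flow <- tapply(er$relevance, er$to, sum)
  for (nm in names(rel$node_relevance)) {
    expect_equal(unname(rel$node_relevance[nm]),
                 if (nm %in% names(in_flow)) unname(in_flow[nm]) else 0,
                 tolerance = 1e-12)
  }
})

test_that("analytic expected passage counts match a Monte-Carlo simulation", {
  set.seed(303)
  for (g in 1:3) {
    net <- random_small_network(sample(5:8, 1))
    tm <- transition_matrix(net)
    seeds <- sample(tm$nodes, 2L)
    L <- 15L
    rel <- limited_kwalks(tm, seeds, L = L)
    mc <- mc_kwalks(tm, seeds, L, n_walk_total = 4e4L)
    er <- rel$edge_relevance
    key <- paste(er$from, er$to)
    for (r in seq_len(nrow(mc))) {
      analytic <- er$relevance[match(paste(mc$from[r], mc$to[r]), key)]
      if (is.na(analytic)) analytic <- 0
      expect_lt(abs(analytic - mc$mean[r]), 4 * mc$se[r] + 1e-9)
    }
  }
})

test_that("other seeds absorb walks: passage counts match the geometric closed form", {
  # On the path A-B-C with seeds {A, C}, the walk from A visits B, then with
  # probability 1/2 is absorbed at C and with probability 1/2 bounces back to
  # A. Expected visits to B: sum over 25 bounce cycles of (1/2)^k, i.e.
  # 2 * (1 - 2^-25) at L = 50. Without absorption the count would grow ~ L/2.
  net <- toy_network(cbind(c("A", "B"), c("B", "C")), c(1, 1))
  tm <- transition_matrix(net)
  rel <- limited_kwalks(tm, c("A", "C"), L = 50L)
  expect_equal(unname(rel$node_relevance["B"]), 2 * (1 - 2^-25),
               tolerance = 1e-12)
})

test_that("seeds without a reachable partner are skipped with a record", {
  net <- toy_network(cbind(c("A", "C"), c("B", "D")), c(1, 1))  # two components
  tm <- transition_matrix(net)
  rel <- limited_kwalks(tm, c("A", "B", "C"), L = 10L)
  expect_setequal(rel$seeds, c("A", "B"))
  expect_identical(rel$skipped_seeds, "C")
  expect_warning(res <- limited_kwalks(tm, c("A", "C"), L = 10L),
                 "no extension")
  expect_true(all(res$node_relevance == 0))
})

test_that("relevance is invariant to global weight rescaling", {
  set.seed(304)
  net <- random_small_network(7)
  net2 <- net
  net2$edges$weight <- net$edges$weight * 10
  seeds <- c("N02", "N06")
  r1 <- limited_kwalks(transition_matrix(net), seeds, L = 25L)
  r2 <- limited_kwalks(transition_matrix(net2), seeds, L = 25L)
  expect_equal(r1$node_relevance, r2$node_relevance, tolerance = 1e-12)
})

test_that("extension rules truncate the ranked candidates as specified", {
  set.seed(305)
  net <- random_small_network(10)
  tm <- transition_matrix(net)
  seeds <- c("N01", "N04", "N07")
  rel <- limited_kwalks(tm, seeds, L = 30L)
  sc <- extension_scores(rel, seeds, score = "seed_flow")
  expect_false(any(names(sc) %in% seeds))
  expect_true(all(diff(sc) <= 1e-12))

  top2 <- select_extension(rel, seeds, extension_rule("top_k", k = 2L))
  expect_length(top2, 2L)
  expect_setequal(top2, names(sc)[1:2])

  relall <- select_extension(rel, seeds,
                             extension_rule("relative", threshold = 0))
  expect_setequal(relall, names(sc)[sc > 0])
  relhigh <- select_extension(rel, seeds,
                              extension_rule("relative", threshold = 0.99))
  expect_true(all(relhigh %in% relall))
  expect_true(all(sc[relhigh] >= 0.99 * max(sc)))

  cum <- select_extension(rel, seeds,
                          extension_rule("cumulative_mass", threshold = 0.5,
                                         score = "passage"))
  ps <- extension_scores(rel, seeds, score = "passage")
  expect_gte(sum(ps[cum]), 0.5 * sum(ps) - 1e-12)
  expect_lt(sum(ps[cum[-length(cum)]]), 0.5 * sum(ps))

  # the cap bounds the extension at cap_factor x mapped seeds
  capped <- select_extension(rel, seeds,
                             extension_rule("relative", threshold = 0,
                                            cap_factor = 1))
  expect_lte(length(capped), length(seeds))
})

test_that("pathway extension unions case and control candidates with the seeds", {
  set.seed(306)
  net_case <- random_small_network(12)
  net_ctrl <- random_small_network(12)
  genes <- c("N01", "N05", "N09", "ZZZ")   # ZZZ absent from both networks
  ext <- extend_pathway(genes, net_case, net_ctrl, L = 30L,
                        rule = extension_rule("top_k", k = 2L))
  expect_s3_class(ext, "extended_pathway")
  expect_setequal(ext$mapped, c("N01", "N05", "N09"))
  expect_true(all(ext$mapped %in% ext$final))
  expect_setequal(ext$final,
                  union(ext$mapped, union(ext$extension_case,
                                          ext$extension_control)))
  expect_false("ZZZ" %in% ext$final)
  # seeds first, then added genes in sorted order
  expect_identical(ext$final,
                   c(ext$mapped, sort(setdiff(ext$final, ext$mapped))))
  expect_warning(extend_pathway(c("N01", "ZZZ"), net_case, net_ctrl),
                 "fewer than 2")
})

test_that("collection extension reports per-pathway bookkeeping", {
  set.seed(307)
  net_case <- random_small_network(12)
  net_ctrl <- random_small_network(12)
  coll <- pathway_collection(list(P1 = c("N01", "N02", "N03"),
                                  P2 = c("N07", "N10", "XX1")))
  res <- extend_collection(coll, net_case, net_ctrl, L = 30L,
                           rule = extension_rule("top_k", k = 2L))
  expect_s3_class(res$extended, "pathway_collection")
  expect_named(res$extended, c("P1", "P2"))
  rep <- res$report
  expect_equal(rep$pathway_id, c("P1", "P2"))
  expect_equal(rep$n_original, c(3L, 3L))
  expect_equal(rep$n_mapped, c(3L, 2L))
  expect_equal(rep$n_final,
               vapply(res$extended, length, integer(1)),
               ignore_attr = TRUE)
})
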