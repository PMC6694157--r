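test_that("hypergeometric upper tail matches explicit enumeration", {
  # oracle: sum the point probabilities by direct enumeration
  enum_tail <- function(N, M, n, k) {
    kk <- k:min(n, M)
    sum(choose(M, kk) * choose(N - M, n - kk)) / choose(N, n)
  }
  set.seed(401)
  for (i in 1:50) {
    N <- sample(5:25, 1)
    M <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, M), 1)
    expect_equal(hypergeom_pvalue(N, M, n, k), enum_tail(N, M, n, k),
                 tolerance = 1e-12)
  }
  expect_equal(hypergeom_pvalue(10, 3, 4, 0), 1)
  expect_error(hypergeom_pvalue(10, 11, 4, 0), "M")
  expect_error(hypergeom_pvalue(10, 3, 4, 5), "k")
})

test_that("Benjamini-Hochberg adjustment matches the textbook step-up", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(402)
  for (i in 1:20) {
    p <- stats::runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
  }
  expect_true(all(bh_adjust(c(0.01, 0.5)) >= c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential calls reproduce per-gene Welch t-tests", {
  set.seed(403)
  expr <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  expr["g1", 1:6] <- expr["g1", 1:6] + 3
  labels <- stats::setNames(rep(c("case", "control"), each = 6), paste0("s", 1:12))
  de <- call_de(expr, labels, alpha = 0.05)
  for (g in rownames(expr)) {
    tt <- stats::t.test(expr[g, 1:6], expr[g, 7:12])
    row <- de$table[de$table$gene == g, ]
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-12)
  }
  expect_equal(de$table$adjusted_p, bh_adjust(de$table$p_value))
  expect_true("g1" %in% de$de_genes)
  # constant genes: equal means are null, different means are certain calls
  expr2 <- rbind(flat = rep(1, 12), split = rep(c(0, 5), each = 6))
  colnames(expr2) <- paste0("s", 1:12)
  de2 <- call_de(expr2, labels)
  expect_equal(de2$table$p_value[de2$table$gene == "flat"], 1)
  expect_equal(de2$table$p_value[de2$table$gene == "split"], 0)
})

test_that("over-representation analysis matches a hand-computed example", {
  bg <- paste0("g", 1:20)
  de_genes <- paste0("g", 1:5)
  coll <- pathway_collection(list(
    HIT = c("g1", "g2", "g3", "g6"),     # k = 3 of n = 4
    MISS = c("g10", "g11", "g12", "g13"),# k = 0
    OFF = c("x1", "x2")))                # outside background: skipped
  res <- run_ora(coll, de_genes, bg)
  expect_equal(res$pathway_id, c("HIT", "MISS"))
  expect_equal(res$N, c(20, 20))
  expect_equal(res$M, c(5, 5))
  expect_equal(res$k[res$pathway_id == "HIT"], 3)
  p_hit <- sum(choose(5, 3:4) * choose(15, 4 - (3:4))) / choose(20, 4)
  expect_equal(res$p_value[res$pathway_id == "HIT"], p_hit, tolerance = 1e-12)
  expect_equal(res$adjusted_p, bh_adjust(res$p_value))
  expect_equal(res$rank, c(1L, 2L))
  expect_error(run_ora(coll, "zz", bg), "background")
})

test_that("dense ranks assign equal rank to tied adjusted p-values", {
  bg <- paste0("g", 1:30)
  coll <- pathway_collection(list(A = paste0("g", 1:4), B = paste0("g", 5:8),
                                  C = paste0("g", 9:12)))
  res <- run_ora(coll, character(0), bg)   # all k = 0 -> p = 1 everywhere
  expect_equal(res$rank, c(1L, 1L, 1L))
})

test_that("signal-to-noise ranking applies the sd floors and sorts descending", {
  set.seed(404)
  expr <- matrix(rnorm(4 * 10), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  labels <- stats::setNames(rep(c("case", "control"), each = 5), paste0("s", 1:10))
  rk <- gsea_rank(expr, labels)
  expect_true(all(diff(rk$score) <= 0))
  for (g in rownames(expr)) {
    m1 <- mean(expr[g, 1:5]); m2 <- mean(expr[g, 6:10])
    s1 <- max(stats::sd(expr[g, 1:5]), 0.2 * abs(m1), 0.2)
    s2 <- max(stats::sd(expr[g, 6:10]), 0.2 * abs(m2), 0.2)
    expect_equal(rk$score[rk$gene == g], (m1 - m2) / (s1 + s2),
                 tolerance = 1e-12)
  }
  # a constant gene hits the absolute floor 0.2 on both sds
  expr2 <- rbind(expr, flat = c(rep(1, 5), rep(0, 5)))
  rk2 <- gsea_rank(expr2, labels)
  expect_equal(rk2$score[rk2$gene == "flat"], 1 / (0.2 + 0.2 * 1),
               tolerance = 1e-12)
})

test_that("enrichment scores agree with an independent implementation", {
  set.seed(405)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(n))
    set_size <- sample(3:10, 1)
    gene_set <- sample(names(scores), set_size)
    mine <- gsea_es(scores, gene_set, weight_exponent = 1)
    oracle <- fgsea::calcGseaStat(scores, sort(match(gene_set, names(scores))),
                                  gseaParam = 1)
    expect_equal(mine$es, oracle, tolerance = 1e-10)
  }
})

test_that("classic Kolmogorov-Smirnov scoring matches a brute-force running sum", {
  set.seed(406)
  n <- 40
  scores <- sort(stats::rnorm(n), decreasing = TRUE)
  names(scores) <- paste0("g", seq_len(n))
  gene_set <- sample(names(scores), 6)
  mine <- gsea_es(scores, gene_set, weight_exponent = 0)
  hits <- names(scores) %in% gene_set
  run <- cumsum(ifelse(hits, 1 / sum(hits), -1 / (n - sum(hits))))
  expect_equal(mine$running, run, tolerance = 1e-12)
  expect_equal(mine$es, run[which.max(abs(run))], tolerance = 1e-12)
})

test_that("the sparse enrichment-score kernel agrees with the full profile", {
  set.seed(407)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    scores <- sort(stats::rnorm(n), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(n))
    gene_set <- sample(names(scores), sample(2:8, 1))
    full <- gsea_es(scores, gene_set)$es
    pos <- sort(match(gene_set, names(scores)))
    sparse <- pathext:::.es_core(n, pos, abs(scores[pos]))
    expect_equal(sparse, full, tolerance = 1e-12)
  }
  # degenerate: the whole list is the set
  expect_equal(pathext:::.es_core(5, 1:5, rep(0.5, 5)), 1)
})

test_that("permutation GSEA is reproducible and detects a planted set", {
  set.seed(408)
  n_genes <- 60
  expr <- matrix(rnorm(n_genes * 20), n_genes, 20,
                 dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:20)))
  expr[1:8, 1:10] <- expr[1:8, 1:10] + 2.5      # planted up-set in cases
  labels <- stats::setNames(rep(c("case", "control"), each = 10),
                            paste0("s", 1:20))
  coll <- pathway_collection(list(PLANT = paste0("g", 1:8),
                                  NULL1 = paste0("g", 21:28),
                                  NULL2 = paste0("g", 31:38),
                                  GONE = paste0("x", 1:5)))
  expect_warning(
    res <- gsea_significance(expr, labels, coll, n_perm = 200L, seed = 42L),
    "share no gene")
  expect_setequal(res$pathway_id, c("PLANT", "NULL1", "NULL2"))
  plant <- res[res$pathway_id == "PLANT", ]
  expect_gt(plant$ES, 0)
  expect_gt(plant$NES, 1)
  expect_lt(plant$FDR_q, 0.05)
  expect_equal(plant$rank, 1L)
  expect_true(all(res$nominal_p >= 0 & res$nominal_p <= 1))
  expect_true(all(res$FDR_q >= 0 & res$FDR_q <= 1))
  # identical seed, identical table; different seed perturbs the null stats
  res2 <- suppressWarnings(
    gsea_significance(expr, labels, coll, n_perm = 200L, seed = 42L))
  expect_identical(res, res2)
  res3 <- suppressWarnings(
    gsea_significance(expr, labels, coll, n_perm = 200L, seed = 43L))
  expect_equal(res3$ES, res$ES[match(res3$pathway_id, res$pathway_id)])
  expect_error(gsea_significance(expr, labels, coll, n_perm = 200L),
               "seed")
  small <- pathway_collection(list(PLANT = paste0("g", 1:8)))
  expect_warning(gsea_significance(expr, labels, small, n_perm = 10L, seed = 1L),
                 "fewer than 100")
})
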