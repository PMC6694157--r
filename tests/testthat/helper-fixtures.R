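# Shared helpers: tiny file writers, toy networks, and a Monte-Carlo
# random-walk simulator used as the independent oracle for the analytic
# expected-passage computation.

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

toy_expression_file <- function(path = tempfile(fileext = ".tsv")) {
  write_tsv_lines(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "A\t7\t0\t3\t1",
    "B\t2\t4\t6\t8",
    "C\t1\t1\t2\t3"), path)
}

toy_network <- function(edges, weights, phenotype = "case") {
  structure(list(phenotype = phenotype,
                 nodes = sort(unique(c(edges[, 1L], edges[, 2L]))),
                 edges = data.frame(gene_a = edges[, 1L],
                                    gene_b = edges[, 2L],
                                    weight = weights,
                                    stringsAsFactors = FALSE),
                 n_deleted = 0L, n_nonconverged = 0L),
            class = "weighted_network")
}

# random connected weighted network on n nodes (ring + random chords)
random_small_network <- function(n, extra = n) {
  nodes <- sprintf("N%02d", seq_len(n))
  a <- nodes[seq_len(n)]
  b <- nodes[c(seq_len(n)[-1L], 1L)]
  for (i in seq_len(extra)) {
    pair <- sample(nodes, 2L)
    a <- c(a, pair[1L])
    b <- c(b, pair[2L])
  }
  ed <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                   stringsAsFactors = FALSE)
  ed <- ed[ed$gene_a != ed$gene_b, ]
  ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b)), ]
  ed$weight <- stats::runif(nrow(ed), 0.1, 1)
  toy_network(as.matrix(ed[, 1:2]), ed$weight)
}

# Monte-Carlo oracle: simulate truncated absorbing walks and tally per-edge
# passage counts. Returns mean and standard error of the per-edge counts,
# averaged uniformly over start seeds (matching limited_kwalks()).
mc_kwalks <- function(tm, seeds, L, n_walk_total = 1e5L) {
  nodes <- tm$nodes
  n <- length(nodes)
  seeds <- intersect(seeds, nodes)
  n_walk <- ceiling(n_walk_total / length(seeds))
  edge_keys <- character(0)
  sums <- list()
  sqs <- list()
  for (s in seeds) {
    absorb_idx <- match(setdiff(seeds, s), nodes)
    cur <- rep(match(s, nodes), n_walk)
    walk_id <- seq_len(n_walk)
    active <- rep(TRUE, n_walk)
    trans_walk <- integer(0)
    trans_edge <- integer(0)
    for (t in seq_len(L)) {
      idx <- which(active)
      if (!length(idx)) break
      nxt <- integer(length(idx))
      for (st in unique(cur[idx])) {
        sel <- idx[cur[idx] == st]
        pr <- tm$P[st, ]
        nxt[match(sel, idx)] <- sample.int(n, length(sel), replace = TRUE,
                                           prob = pr)
      }
      trans_walk <- c(trans_walk, walk_id[idx])
      trans_edge <- c(trans_edge, (cur[idx] - 1L) * n + nxt)
      cur[idx] <- nxt
      active[idx] <- !(nxt %in% absorb_idx)
    }
    # per-(walk, edge) counts via run-length encoding of a combined key
    n2 <- n * n
    combined <- (trans_walk - 1) * n2 + trans_edge
    r <- rle(sort(combined))
    per_edge <- ((r$values - 1) %% n2) + 1
    per_count <- r$lengths
    s1 <- rowsum(as.numeric(per_count), per_edge)
    s2 <- rowsum(as.numeric(per_count)^2, per_edge)
    key <- rownames(s1)
    for (i in seq_along(key)) {
      k <- key[i]
      if (is.null(sums[[k]])) {
        sums[[k]] <- c(0, 0)
      }
      sums[[k]] <- sums[[k]] + c(s1[i, 1L], s2[i, 1L])
    }
    edge_keys <- union(edge_keys, key)
  }
  S <- length(seeds)
  res <- lapply(edge_keys, function(k) {
    s1 <- sums[[k]][1L]
    s2 <- sums[[k]][2L]
    # zero-count walks contribute zeros; totals are over S * n_walk walks,
    # but means/vars are per start seed then averaged
    mean_k <- s1 / (S * n_walk)
    var_within <- (s2 - s1^2 / (S * n_walk)) / (S * n_walk - 1)
    se <- sqrt(var_within / (S * n_walk))
    ei <- as.integer(k)
    c(from = ((ei - 1L) %/% n) + 1L, to = ((ei - 1L) %% n) + 1L,
      mean = mean_k, se = se)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$from <- nodes[out$from]
  out$to <- nodes[out$to]
  out
}

mini_bundle <- function(seed, dir = tempfile("fixtures")) {
  spec <- fixture_spec_mini(seed = seed)
  paths <- write_fixture_bundle(spec, dir)
  list(spec = spec, paths = paths, data = attr(paths, "data"))
}
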