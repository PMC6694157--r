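# Pathway extension by truncated absorbing random walks (limited kWalks).
# Walks start at one pathway gene (seed), move with probabilities
# P_ij = W_ij / sum_j W_ij, are absorbed on first arrival at any other seed,
# and are truncated after L steps. The relevance of a node/edge is the
# expected number of times such walks pass through it, averaged uniformly
# over start seeds.

#' Row-stochastic transition matrix of a weighted network
#'
#' Normalises each node's incident edge weights to transition probabilities,
#' `P_ij = W_ij / sum_j W_ij`. Nodes whose incident weights are all zero are
#' excluded (a walk cannot leave them) and reported via the `dropped`
#' element.
#'
#' @param net A `weighted_network`, or a data.frame with columns `gene_a`,
#'   `gene_b`, `weight`.
#' @return An object of class `transition_matrix`: list with `P` (dense
#'   row-stochastic matrix with gene dimnames), `nodes` and `dropped`.
#' @export
transition_matrix <- function(net) {
  ed <- if (inherits(net, "weighted_network")) net$edges else net
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% colnames(ed)))
  if (any(ed$weight < 0)) stop("edge weights must be non-negative", call. = FALSE)
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(ed$gene_a, nodes)
  ib <- match(ed$gene_b, nodes)
  W[cbind(ia, ib)] <- ed$weight
  W[cbind(ib, ia)] <- ed$weight
  rs <- rowSums(W)
  keep <- rs > 0
  dropped <- nodes[!keep]
  if (!any(keep)) stop("all nodes have zero incident weight", call. = FALSE)
  P <- W[keep, keep, drop = FALSE] / rs[keep]
  structure(list(P = P, nodes = nodes[keep], dropped = dropped),
            class = "transition_matrix")
}

#' Expected passage counts of limited random walks from pathway seeds
#'
#' For each start seed `s`, propagates forward probability mass through the
#' absorbing chain in which every *other* seed is absorbing: with
#' `alpha_0 = e_s`, step `t` moves mass `alpha_t(i) * P_ij` along edge
#' `(i, j)` for `t < L`. The expected passage count of an edge is the total
#' mass moved along it, the relevance of a node the total mass entering it.
#' Results are averaged uniformly over the start seeds. Nodes unreachable
#' within `L` steps keep relevance 0. Seeds whose graph component contains no
#' other seed cannot route any walk to an absorbing state and are skipped
#' (reported in `skipped_seeds`).
#'
#' @param tm A [transition_matrix()].
#' @param seeds Character vector of pathway genes (will be intersected with
#'   the network's nodes).
#' @param L Walk-length limit (>= 1).
#' @return An object of class `relevance_scores`: list with `node_relevance`
#'   (named numeric over all network nodes), `edge_relevance` (data.frame
#'   `from`, `to`, `relevance` for directed flows > 0), `seeds` (start seeds
#'   actually used), `skipped_seeds`, and `L`. When fewer than 2 usable seeds
#'   exist, relevances are all zero and a warning is raised.
#' @export
limited_kwalks <- function(tm, seeds, L = 50L) {
  stopifnot(inherits(tm, "transition_matrix"))
  L <- as.integer(L)
  if (L < 1L) stop("L must be at least 1", call. = FALSE)
  nodes <- tm$nodes
  n <- length(nodes)
  empty <- function(used, skipped) {
    structure(list(node_relevance = stats::setNames(numeric(n), nodes),
                   edge_relevance = data.frame(from = character(0),
                                               to = character(0),
                                               relevance = numeric(0)),
                   seeds = used, skipped_seeds = skipped, L = L),
              class = "relevance_scores")
  }
  mapped <- intersect(seeds, nodes)
  if (length(mapped) < 2L) {
    warning("fewer than 2 pathway genes mapped to the network; no extension",
            call. = FALSE)
    return(empty(character(0), mapped))
  }
  # drop seeds isolated from every other seed (different graph component)
  g <- igraph::graph_from_adjacency_matrix(tm$P > 0, mode = "max")
  comp <- igraph::components(g)$membership[match(mapped, nodes)]
  comp_size <- table(comp)
  usable <- mapped[comp_size[as.character(comp)] >= 2L]
  skipped <- setdiff(mapped, usable)
  if (length(usable) < 2L) {
    warning("no two pathway genes share a network component; no extension",
            call. = FALSE)
    return(empty(character(0), skipped))
  }
  node_acc <- numeric(n)
  edge_acc <- matrix(0, n, n)
  seed_idx <- match(usable, nodes)
  for (si in seed_idx) {
    absorb <- setdiff(seed_idx, si)
    Pp <- tm$P
    Pp[absorb, ] <- 0
    alpha <- numeric(n)
    alpha[si] <- 1
    for (t in seq_len(L)) {
      flow <- Pp * alpha          # row i scaled by alpha_t(i)
      alpha <- colSums(flow)
      edge_acc <- edge_acc + flow
      node_acc <- node_acc + alpha
      if (sum(alpha) < 1e-14) break
    }
  }
  node_rel <- stats::setNames(node_acc / length(usable), nodes)
  edge_acc <- edge_acc / length(usable)
  nz <- which(edge_acc > 0, arr.ind = TRUE)
  edge_rel <- data.frame(from = nodes[nz[, 1L]], to = nodes[nz[, 2L]],
                         relevance = edge_acc[nz], stringsAsFactors = FALSE)
  edge_rel <- edge_rel[order(-edge_rel$relevance, edge_rel$from, edge_rel$to), ]
  rownames(edge_rel) <- NULL
  structure(list(node_relevance = node_rel, edge_relevance = edge_rel,
                 seeds = usable, skipped_seeds = skipped, L = L),
            class = "relevance_scores")
}

#' Extension selection rule
#'
#' Configures how high-relevance neighbour genes are picked from
#' [limited_kwalks()] scores.
#'
#' Two relevance scores are available per non-seed gene:
#' * `seed_flow` (default): the expected number of times a walk is absorbed
#'   into a seed directly from the gene, i.e. the gene's share of the
#'   successful seed-to-seed connection flow. Raw passage counts reward
#'   high-degree hub genes that merely circulate unabsorbed walk mass;
#'   restricting to the flow that completes a connection scores genes by how
#'   much they actually link pathway members.
#' * `passage`: the raw expected passage count of the gene.
#'
#' Available truncation rules:
#' * `relative` (default): keep genes scoring at least `threshold` times the
#'   maximum non-seed score (default 0.5).
#' * `share`: keep genes holding at least `threshold` of the total non-seed
#'   score mass.
#' * `cumulative_mass`: keep the smallest top-ranked prefix whose cumulative
#'   score reaches `threshold` of the total non-seed score.
#' * `top_k`: keep the `k` highest-scoring genes.
#' * `quantile`: keep genes at or above the `q`-th quantile of the positive
#'   non-seed scores.
#'
#' Every rule is capped at `cap_factor` times the number of mapped seeds, and
#' ties are broken deterministically by (score descending, gene symbol
#' ascending).
#'
#' @param type Rule name.
#' @param threshold Fraction used by `relative` (of the maximum score),
#'   `share` (of the total score) and `cumulative_mass` rules.
#' @param k Number of genes for `top_k`.
#' @param q Quantile for `quantile`.
#' @param score Which relevance score drives the ranking, `"seed_flow"` or
#'   `"passage"`.
#' @param cap_factor Cap on the extension size as a multiple of the mapped
#'   pathway size.
#' @return A list of class `extension_rule`.
#' @export
extension_rule <- function(type = c("relative", "share", "cumulative_mass",
                                    "top_k", "quantile"),
                           threshold = 0.5, k = NULL, q = 0.9,
                           score = c("seed_flow", "passage"),
                           cap_factor = 3) {
  type <- match.arg(type)
  score <- match.arg(score)
  if (type == "top_k" && (is.null(k) || k < 0)) {
    stop("rule 'top_k' needs k >= 0", call. = FALSE)
  }
  if (type == "cumulative_mass" && missing(threshold)) threshold <- 0.95
  if (type == "share" && missing(threshold)) threshold <- 0.02
  if (!(threshold >= 0 && threshold <= 1)) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  if (!(q >= 0 && q <= 1)) stop("q must be in [0, 1]", call. = FALSE)
  if (cap_factor <= 0) stop("cap_factor must be positive", call. = FALSE)
  structure(list(type = type, threshold = threshold, k = k, q = q,
                 score = score, cap_factor = cap_factor),
            class = "extension_rule")
}

#' Relevance score of non-seed genes
#'
#' @param rel A [limited_kwalks()] result.
#' @param seeds The pathway's seed genes.
#' @param score `"seed_flow"` (direct absorption flow into seeds) or
#'   `"passage"` (raw expected passage counts); see [extension_rule()].
#' @return Named numeric vector over non-seed genes with positive score,
#'   sorted by (score descending, gene symbol ascending).
#' @export
extension_scores <- function(rel, seeds, score = c("seed_flow", "passage")) {
  score <- match.arg(score)
  non_seed <- setdiff(names(rel$node_relevance), seeds)
  if (score == "passage") {
    r <- rel$node_relevance[non_seed]
  } else {
    er <- rel$edge_relevance
    er <- er[er$to %in% seeds & er$from %in% non_seed, , drop = FALSE]
    agg <- tapply(er$relevance, er$from, sum)
    r <- stats::setNames(numeric(length(non_seed)), non_seed)
    r[names(agg)] <- agg
  }
  r <- r[r > 0]
  if (!length(r)) return(r)
  r[order(-r, names(r))]
}

#' Select extension genes from relevance scores
#'
#' Ranks non-seed genes by the rule's relevance score (ties broken by gene
#' symbol) and truncates according to the rule. Genes with zero score are
#' never selected. May return an empty set, in which case the pathway keeps
#' its original genes.
#'
#' @param rel A [limited_kwalks()] result.
#' @param seeds The pathway's seed genes (the mapped seed count drives the
#'   size cap).
#' @param rule An [extension_rule()].
#' @return Character vector of selected genes, in rank order.
#' @export
select_extension <- function(rel, seeds, rule = extension_rule()) {
  stopifnot(inherits(rel, "relevance_scores"), inherits(rule, "extension_rule"))
  r <- extension_scores(rel, seeds, rule$score)
  if (!length(r)) return(character(0))
  n_sel <- switch(rule$type,
    top_k = min(rule$k, length(r)),
    quantile = sum(r >= stats::quantile(r, rule$q)),
    relative = sum(r >= rule$threshold * r[1L]),
    share = sum(r / sum(r) >= rule$threshold),
    cumulative_mass = {
      cum <- cumsum(r) / sum(r)
      which(cum >= rule$threshold - 1e-12)[1L]
    })
  n_mapped <- length(intersect(seeds, names(rel$node_relevance)))
  cap <- max(1L, ceiling(rule$cap_factor * n_mapped))
  names(r)[seq_len(min(n_sel, cap))]
}

#' Extend one pathway in both phenotype-specific networks
#'
#' Runs [limited_kwalks()] and [select_extension()] on the case and control
#' networks, then unites the mapped original genes with both extension sets
#' into the final gene list.
#'
#' @param genes Character vector of the pathway's original genes.
#' @param net_case,net_control `weighted_network` or `transition_matrix`
#'   objects for the two phenotypes.
#' @param L Walk-length limit.
#' @param rule An [extension_rule()].
#' @param pathway_id Optional id carried along.
#' @return An object of class `extended_pathway`: list with `pathway_id`,
#'   `original_genes`, `mapped_genes`, `extension_case`, `extension_control`
#'   and `final_genes` (mapped genes first, then the sorted union of the two
#'   extensions).
#' @export
extend_pathway <- function(genes, net_case, net_control, L = 50L,
                           rule = extension_rule(), pathway_id = NA_character_) {
  as_tm <- function(x) if (inherits(x, "transition_matrix")) x else transition_matrix(x)
  tm_case <- as_tm(net_case)
  tm_ctrl <- as_tm(net_control)
  universe <- union(tm_case$nodes, tm_ctrl$nodes)
  mapped <- intersect(genes, universe)
  run_side <- function(tm) {
    seeds <- intersect(genes, tm$nodes)
    if (length(seeds) < 2L) return(character(0))
    rel <- limited_kwalks(tm, seeds, L = L)
    select_extension(rel, seeds, rule = rule)
  }
  if (length(mapped) < 2L) {
    warning("pathway '", pathway_id,
            "': fewer than 2 genes mapped to the networks; not extended",
            call. = FALSE)
    ext_case <- ext_ctrl <- character(0)
  } else {
    ext_case <- suppressWarnings(run_side(tm_case))
    ext_ctrl <- suppressWarnings(run_side(tm_ctrl))
  }
  final <- c(mapped, sort(setdiff(union(ext_case, ext_ctrl), mapped)))
  structure(list(pathway_id = pathway_id, original_genes = genes,
                 mapped_genes = mapped, extension_case = ext_case,
                 extension_control = ext_ctrl, final_genes = final),
            class = "extended_pathway")
}

#' @export
print.extended_pathway <- function(x, ...) {
  cat("extended_pathway ", x$pathway_id, ": ", length(x$original_genes),
      " original / ", length(x$mapped_genes), " mapped -> ",
      length(x$final_genes), " final (",
      length(x$extension_case), " case + ",
      length(x$extension_control), " control extension genes)\n", sep = "")
  invisible(x)
}

#' Extend every pathway of a collection
#'
#' Converts both networks to transition matrices once, extends each pathway
#' with [extend_pathway()], and assembles the extended collection, a
#' per-pathway report and the detailed results.
#'
#' @param collection A [pathway_collection()].
#' @param net_case,net_control `weighted_network` objects.
#' @param L Walk-length limit.
#' @param rule An [extension_rule()].
#' @return List with `extended` (a `pathway_collection` of final gene lists),
#'   `details` (list of `extended_pathway`) and `report` (data.frame with
#'   columns `pathway_id`, `n_original`, `n_mapped`, `n_extension_case`,
#'   `n_extension_control`, `n_final`).
#' @export
extend_collection <- function(collection, net_case, net_control, L = 50L,
                              rule = extension_rule()) {
  stopifnot(inherits(collection, "pathway_collection"))
  tm_case <- transition_matrix(net_case)
  tm_ctrl <- transition_matrix(net_control)
  details <- lapply(names(collection), function(id) {
    extend_pathway(collection[[id]], tm_case, tm_ctrl, L = L, rule = rule,
                   pathway_id = id)
  })
  names(details) <- names(collection)
  report <- do.call(rbind, lapply(details, function(d) {
    data.frame(pathway_id = d$pathway_id,
               n_original = length(d$original_genes),
               n_mapped = length(d$mapped_genes),
               n_extension_case = length(d$extension_case),
               n_extension_control = length(d$extension_control),
               n_final = length(d$final_genes),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  finals <- lapply(details, `[[`, "final_genes")
  nonempty <- lengths(finals) > 0L
  extended <- pathway_collection(finals[nonempty],
                                 attr(collection, "descriptions")[nonempty])
  list(extended = extended, details = details, report = report)
}

#' Write a relevance-annotated subnetwork edge list
#'
#' Emits the directed flows of a [limited_kwalks()] result as a TSV usable by
#' generic graph tools (for crosstalk-style visualisation).
#'
#' @param rel A `relevance_scores` object.
#' @param path Output path.
#' @param min_relevance Drop flows below this value.
#' @return The path, invisibly.
#' @export
write_relevance_edges <- function(rel, path, min_relevance = 0) {
  df <- rel$edge_relevance
  df <- df[df$relevance >= min_relevance, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
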