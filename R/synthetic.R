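# Fully in-silico input generator with planted structure: a scale-free
# background interactome, connected pathway seed sets, "bridge" genes wired
# into each pathway with coupled methylation/expression signal, and planted
# differential expression. Every stage of the pipeline is testable against
# the recorded ground truth, without any external download.

#' Specification of a synthetic multi-omics study
#'
#' The defaults describe the reference study conditions used throughout the
#' package's validation: 200 genes, 5 disjoint pathways of 15 genes, 3 planted
#' bridge genes per pathway, methylation/expression coupling 0.8 on planted
#' structure, and 35 samples per phenotype class (the cohort sizes typical of
#' matched tumour/normal multi-omics studies).
#'
#' @param n_genes Number of genes in the universe.
#' @param probes_per_gene Integer range (min, max) of CpG probes per gene.
#' @param n_samples_per_class Samples per phenotype class.
#' @param n_pathways Number of planted pathways.
#' @param pathway_size Integer range (min, max) of pathway sizes.
#' @param n_bridges_per_pathway Planted bridge genes per pathway.
#' @param coupling Correlation strength, in \[0, 1), of the shared latent
#'   signal that couples methylation PCs and expression across planted edges
#'   (methylation is anticorrelated with expression, the promoter
#'   convention).
#' @param de_effect Expression shift (log2 scale) added to planted DE genes
#'   in case samples.
#' @param frac_pathway_de Fraction of each pathway's genes planted as DE.
#' @param background_de_rate Fraction of background genes planted as DE.
#' @param noise_sd Standard deviation of the i.i.d. expression noise.
#' @param seed RNG seed (mandatory; the generator is bit-reproducible).
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200L, probes_per_gene = c(2L, 8L),
                         n_samples_per_class = 35L, n_pathways = 5L,
                         pathway_size = c(15L, 15L),
                         n_bridges_per_pathway = 3L, coupling = 0.8,
                         de_effect = 1.5, frac_pathway_de = 0.3,
                         background_de_rate = 0.02, noise_sd = 0.3, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed > 2147483600) {
    stop("seed must be a non-negative integer below 2^31", call. = FALSE)
  }
  seed <- as.integer(seed)
  spec <- list(n_genes = as.integer(n_genes),
               probes_per_gene = as.integer(probes_per_gene),
               n_samples_per_class = as.integer(n_samples_per_class),
               n_pathways = as.integer(n_pathways),
               pathway_size = as.integer(pathway_size),
               n_bridges_per_pathway = as.integer(n_bridges_per_pathway),
               coupling = coupling, de_effect = de_effect,
               frac_pathway_de = frac_pathway_de,
               background_de_rate = background_de_rate,
               noise_sd = noise_sd, seed = seed)
  with(spec, {
    if (n_genes < 10L || n_samples_per_class < 3L || n_pathways < 1L ||
        n_bridges_per_pathway < 0L) {
      stop("all counts must be positive (and the universe non-trivial)",
           call. = FALSE)
    }
    if (any(probes_per_gene < 1L) || probes_per_gene[1L] > probes_per_gene[2L]) {
      stop("probes_per_gene must be an increasing range of positive counts",
           call. = FALSE)
    }
    if (!(coupling >= 0 && coupling < 1)) {
      stop("coupling must lie in [0, 1)", call. = FALSE)
    }
    if (noise_sd < 0 || de_effect < 0) {
      stop("noise_sd and de_effect must be non-negative", call. = FALSE)
    }
    need <- n_pathways * (pathway_size[2L] + n_bridges_per_pathway)
    if (need > n_genes) {
      stop("pathways and bridges (", need,
           " genes) do not fit into a universe of ", n_genes, call. = FALSE)
    }
  })
  structure(spec, class = "fixture_spec")
}

#' Small preset of the synthetic study for fast tests
#'
#' @param seed RNG seed.
#' @param ... Overrides passed on to [fixture_spec()].
#' @return A `fixture_spec` with 80 genes, 3 pathways of 8 genes, 2 bridges
#'   each and 20 samples per class.
#' @export
fixture_spec_mini <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_genes = 80L, probes_per_gene = c(1L, 4L),
         n_samples_per_class = 20L, n_pathways = 3L,
         pathway_size = c(8L, 8L), n_bridges_per_pathway = 2L, seed = seed),
    list(...))
  do.call(fixture_spec, args)
}

#' Generate the interactome, pathways and planted truth
#'
#' Draws a preferential-attachment background graph (realistic degree skew),
#' carves out disjoint connected pathway gene sets (adding an edge whenever a
#' growing set would otherwise disconnect, so connectedness holds by
#' construction), and wires each planted bridge gene to 2-3 genes of its
#' pathway. Also fixes the planted DE gene set: every bridge, a fraction of
#' each pathway, and a thin background rate.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture_structure` with `edges` (data.frame
#'   `gene_a`, `gene_b`), `pathways` (a [pathway_collection()]), and `truth`
#'   (list with `bridges` per pathway, `membership`, `de_genes`).
#' @export
generate_network_and_pathways <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  g <- igraph::sample_pa(n, power = 1, m = 2, directed = FALSE)
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  extra_a <- integer(0)
  extra_b <- integer(0)

  membership <- integer(n)              # 0 = background
  pathways <- vector("list", spec$n_pathways)
  for (pw in seq_len(spec$n_pathways)) {
    size <- if (spec$pathway_size[1L] == spec$pathway_size[2L]) {
      spec$pathway_size[1L]
    } else {
      sample(spec$pathway_size[1L]:spec$pathway_size[2L], 1L)
    }
    avail <- which(membership == 0L)
    start <- sample(avail, 1L)
    members <- start
    while (length(members) < size) {
      nb <- setdiff(intersect(unlist(adj[members]), avail), members)
      if (length(nb)) {
        nxt <- if (length(nb) == 1L) nb else sample(nb, 1L)
      } else {
        # no free neighbour: adopt a random free gene and wire it in
        free <- setdiff(avail, members)
        nxt <- if (length(free) == 1L) free else sample(free, 1L)
        anchor <- if (length(members) == 1L) members else sample(members, 1L)
        extra_a <- c(extra_a, anchor)
        extra_b <- c(extra_b, nxt)
        adj[[anchor]] <- union(adj[[anchor]], nxt)
        adj[[nxt]] <- union(adj[[nxt]], anchor)
      }
      members <- c(members, nxt)
    }
    membership[members] <- pw
    pathways[[pw]] <- genes[sort(members)]
  }

  bridges <- vector("list", spec$n_pathways)
  for (pw in seq_len(spec$n_pathways)) {
    if (spec$n_bridges_per_pathway == 0L) {
      bridges[[pw]] <- character(0)
      next
    }
    avail <- which(membership == 0L)
    br <- sample(avail, spec$n_bridges_per_pathway)
    targets_pool <- which(membership == pw)
    for (b in br) {
      k <- sample(2:3, 1L)
      tg <- sample(targets_pool, min(k, length(targets_pool)))
      extra_a <- c(extra_a, rep(b, length(tg)))
      extra_b <- c(extra_b, tg)
    }
    membership[br] <- pw
    bridges[[pw]] <- genes[sort(br)]
  }

  base <- igraph::as_edgelist(g, names = FALSE)
  ea <- c(base[, 1L], extra_a)
  eb <- c(base[, 2L], extra_b)
  a <- pmin(genes[ea], genes[eb])
  b <- pmax(genes[ea], genes[eb])
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL

  ids <- sprintf("PW%02d", seq_len(spec$n_pathways))
  names(pathways) <- ids
  names(bridges) <- ids
  pathway_members <- lapply(seq_len(spec$n_pathways), function(pw) {
    setdiff(genes[membership == pw], bridges[[pw]])
  })
  de <- unlist(bridges, use.names = FALSE)
  for (pw in seq_len(spec$n_pathways)) {
    pg <- pathway_members[[pw]]
    n_de <- round(spec$frac_pathway_de * length(pg))
    if (n_de > 0L) de <- c(de, sample(pg, n_de))
  }
  bg <- genes[membership == 0L]
  n_bg_de <- round(spec$background_de_rate * length(bg))
  if (n_bg_de > 0L) de <- c(de, sample(bg, n_bg_de))

  structure(list(edges = edges,
                 pathways = pathway_collection(pathways),
                 truth = list(bridges = bridges,
                              membership = stats::setNames(membership, genes),
                              de_genes = sort(unique(de)))),
            class = "fixture_structure")
}

#' Generate a synthetic two-phenotype multi-omics cohort
#'
#' Each gene carries a latent signal shared across its planted pathway
#' (strength `sqrt(coupling)`); expression follows the latent positively and
#' CpG beta values follow it negatively on the logit scale, so planted edges
#' show coupled methylation/expression signal of correlation `coupling` while
#' background edges are null. Planted DE genes get `de_effect` added in case
#' samples. Bit-reproducible given the specification's seed.
#'
#' @param spec A [fixture_spec()].
#' @param structure Optional [generate_network_and_pathways()] result; when
#'   omitted it is regenerated from the specification (same seed, same structure).
#' @return A list with `expression` (genes x samples), `methylation`
#'   (probes x samples beta values), `probe_map`, `labels`, and the
#'   `structure` used.
#' @export
generate_cohort <- function(spec, structure = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(structure)) structure <- generate_network_and_pathways(spec)
  set.seed(spec$seed + 1L)
  n <- spec$n_genes
  genes <- names(structure$truth$membership)
  member <- unname(structure$truth$membership)
  ns <- 2L * spec$n_samples_per_class
  samples <- c(sprintf("case_%03d", seq_len(spec$n_samples_per_class)),
               sprintf("ctrl_%03d", seq_len(spec$n_samples_per_class)))
  labels <- stats::setNames(rep(c("case", "control"),
                                each = spec$n_samples_per_class), samples)

  rho <- spec$coupling
  sr <- sqrt(rho)
  sq <- sqrt(1 - rho)
  f_path <- matrix(stats::rnorm(ns * spec$n_pathways), ns)
  own <- matrix(stats::rnorm(ns * n), ns)
  latent <- own
  in_pw <- member > 0L
  latent[, in_pw] <- f_path[, member[in_pw], drop = FALSE]
  z_expr <- sr * latent + sq * matrix(stats::rnorm(ns * n), ns)
  z_meth <- -(sr * latent + sq * matrix(stats::rnorm(ns * n), ns))

  mu <- stats::rnorm(n, mean = 8, sd = 2)
  expr <- t(z_expr + spec$noise_sd * matrix(stats::rnorm(ns * n), ns)) + mu
  dimnames(expr) <- list(genes, samples)
  de_idx <- match(structure$truth$de_genes, genes)
  expr[de_idx, labels == "case"] <- expr[de_idx, labels == "case"] +
    spec$de_effect

  n_probes <- sample(spec$probes_per_gene[1L]:spec$probes_per_gene[2L], n,
                     replace = TRUE)
  if (spec$probes_per_gene[1L] == spec$probes_per_gene[2L]) {
    n_probes <- rep(spec$probes_per_gene[1L], n)
  }
  total <- sum(n_probes)
  probe_ids <- sprintf("cg%07d", seq_len(total))
  probe_gene <- rep(genes, n_probes)
  base_level <- stats::rnorm(total, 0, 1.5)
  meth <- matrix(NA_real_, total, ns, dimnames = list(probe_ids, samples))
  gene_of <- rep(seq_len(n), n_probes)
  for (j in seq_len(total)) {
    logit <- base_level[j] + 1.5 * z_meth[, gene_of[j]] +
      0.5 * stats::rnorm(ns)
    meth[j, ] <- pmin(1, pmax(0, stats::plogis(logit)))
  }
  list(expression = expr, methylation = meth,
       probe_map = data.frame(probe_id = probe_ids, gene = probe_gene,
                              stringsAsFactors = FALSE),
       labels = labels, structure = structure)
}

#' Write a complete synthetic input bundle to disk
#'
#' Produces every file the pipeline reads (expression.tsv, methylation.tsv,
#' probe_map.tsv, edges.tsv, pathways.gmt, phenotypes.tsv) plus truth.json
#' with the planted ground truth for recovery scoring.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly; the
#'   generated objects are attached as the `data` attribute.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure_obj <- generate_network_and_pathways(spec)
  cohort <- generate_cohort(spec, structure_obj)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    edges = file.path(dir, "edges.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths[["expression"]])
  write_methylation(cohort$methylation, paths[["methylation"]])
  write_probe_map(cohort$probe_map, paths[["probe_map"]])
  write_edge_list(structure_obj$edges, paths[["edges"]])
  write_gmt(structure_obj$pathways, paths[["pathways"]])
  write_phenotypes(cohort$labels, paths[["phenotypes"]])
  jsonlite::write_json(structure_obj$truth, paths[["truth"]], auto_unbox = FALSE)
  out <- paths
  attr(out, "data") <- c(cohort, list(edges = structure_obj$edges,
                                      pathways = structure_obj$pathways))
  invisible(out)
}

#' Score extension recovery against the planted truth
#'
#' Pools true positives over pathways: a selected extension gene counts as
#' correct when it is a planted bridge of that pathway.
#'
#' @param extensions Named list (by pathway id) of selected extension gene
#'   sets, e.g. the union of case and control extensions per pathway.
#' @param truth The `truth` element of a [generate_network_and_pathways()]
#'   result.
#' @return List with `precision`, `recall`, `tp`, `n_selected`, `n_planted`.
#' @export
extension_recovery <- function(extensions, truth) {
  ids <- names(truth$bridges)
  tp <- 0L
  n_sel <- 0L
  n_pl <- 0L
  for (id in ids) {
    sel <- unique(extensions[[id]])
    br <- truth$bridges[[id]]
    tp <- tp + length(intersect(sel, br))
    n_sel <- n_sel + length(sel)
    n_pl <- n_pl + length(br)
  }
  list(precision = if (n_sel) tp / n_sel else NA_real_,
       recall = if (n_pl) tp / n_pl else NA_real_,
       tp = tp, n_selected = n_sel, n_planted = n_pl)
}
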