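# Per-gene feature construction: principal components of a gene's CpG beta
# values merged with its expression into one samples x (s + 1) block.

#' Reduce a gene's CpG probes to principal components
#'
#' Runs a centred (unscaled) PCA on the samples-by-probes beta submatrix of
#' one gene and retains the smallest number of components `s` whose cumulative
#' explained variance reaches `variance_target` (always at least one). Beta
#' values share a scale, so columns are centred but not rescaled. For
#' determinism each component is sign-fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param beta Numeric matrix, samples x probes (>= 1 probe, >= 3 samples),
#'   no missing values.
#' @param variance_target Fraction of variance to retain, in (0, 1].
#' @param gene Optional gene symbol carried along for reporting.
#' @return An object of class `methylation_block`: a list with `gene`,
#'   `scores` (samples x s, zero column means), `loadings` (probes x s),
#'   `explained_variance` (all component fractions, non-increasing), `s`,
#'   `n_probes`, and `zero_variance` (TRUE when the submatrix is constant).
#' @export
reduce_cpg <- function(beta, variance_target = 0.8, gene = NA_character_) {
  beta <- as.matrix(beta)
  if (ncol(beta) < 1L) stop("need at least one probe", call. = FALSE)
  if (nrow(beta) < 3L) stop("need at least 3 samples for PCA", call. = FALSE)
  if (anyNA(beta)) stop("missing beta values must be imputed or dropped before PCA",
                        call. = FALSE)
  if (!(variance_target > 0 && variance_target <= 1)) {
    stop("variance_target must be in (0, 1]", call. = FALSE)
  }
  centred <- scale(beta, center = TRUE, scale = FALSE)
  total_var <- sum(centred^2)
  if (total_var < 1e-24) {
    scores <- matrix(0, nrow(beta), 1L,
                     dimnames = list(rownames(beta), "PC1"))
    loadings <- matrix(c(1, rep(0, ncol(beta) - 1L)), ncol(beta), 1L,
                       dimnames = list(colnames(beta), "PC1"))
    return(structure(list(gene = gene, scores = scores, loadings = loadings,
                          explained_variance = 1, s = 1L,
                          n_probes = ncol(beta), zero_variance = TRUE),
                     class = "methylation_block"))
  }
  pc <- stats::prcomp(beta, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  s <- which(cumsum(ev) >= variance_target - 1e-12)[1L]
  if (is.na(s)) s <- length(ev)
  s <- max(1L, s)
  scores <- pc$x[, seq_len(s), drop = FALSE]
  loadings <- pc$rotation[, seq_len(s), drop = FALSE]
  for (j in seq_len(s)) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(s))
  rownames(scores) <- rownames(beta)
  structure(list(gene = gene, scores = scores, loadings = loadings,
                 explained_variance = ev, s = s, n_probes = ncol(beta),
                 zero_variance = FALSE),
            class = "methylation_block")
}

#' @export
print.methylation_block <- function(x, ...) {
  cat("methylation_block:", x$gene, "-", x$n_probes, "probes ->", x$s,
      "PCs (", round(100 * sum(x$explained_variance[seq_len(x$s)]), 1),
      "% variance )\n")
  invisible(x)
}

#' Merge methylation principal components with expression
#'
#' Builds the per-gene feature block: the retained PC score columns followed by
#' one expression column, giving `p = s + 1` features. When `block` is `NULL`
#' (a gene without mapped CpG probes) the result is an expression-only block
#' with `p = 1`, flagged via the `expr_only` attribute.
#'
#' @param block A [reduce_cpg()] result, or `NULL`.
#' @param expr_values Named numeric vector of the gene's expression, names in
#'   the same sample order as the block's score rows.
#' @param gene Optional gene symbol.
#' @return A samples x p numeric matrix with attributes `gene`, `p` and
#'   `expr_only`, of class `gene_feature_block`.
#' @export
merge_features <- function(block, expr_values, gene = NA_character_) {
  if (is.null(names(expr_values))) {
    stop("expression vector must carry sample names", call. = FALSE)
  }
  if (is.null(block)) {
    m <- matrix(unname(expr_values), ncol = 1L,
                dimnames = list(names(expr_values), "expr"))
    return(structure(m, gene = gene, p = 1L, expr_only = TRUE,
                     class = c("gene_feature_block", "matrix", "array")))
  }
  if (!identical(rownames(block$scores), names(expr_values))) {
    stop("sample order of methylation PCs and expression differ for gene '",
         gene, "'", call. = FALSE)
  }
  m <- cbind(block$scores, expr = unname(expr_values))
  structure(m, gene = gene, p = ncol(m), expr_only = FALSE,
            class = c("gene_feature_block", "matrix", "array"))
}

#' Build per-gene feature blocks for one phenotype
#'
#' For every gene in the expression matrix, collects its CpG probes (via the
#' probe map), drops probes missing in more than `max_missing` of the given
#' samples, mean-imputes the remaining missing betas within those samples,
#' reduces the probes to principal components and merges them with the gene's
#' expression. Blocks are built on exactly the `samples` given, so calling this
#' per phenotype yields phenotype-specific features.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meth Methylation matrix (probes x samples), `NA` allowed.
#' @param probe_map Data.frame with columns `probe_id`, `gene`.
#' @param samples Character vector of sample ids to use (subset of both
#'   matrices' columns).
#' @param variance_target Passed to [reduce_cpg()].
#' @param max_missing Maximum tolerated fraction of missing betas per probe.
#' @param include_expr_only Keep genes without usable probes as
#'   expression-only blocks (`TRUE`, default) or drop them.
#' @return Named list of `gene_feature_block` matrices.
#' @export
build_feature_blocks <- function(expr, meth, probe_map, samples,
                                 variance_target = 0.8, max_missing = 0.2,
                                 include_expr_only = TRUE) {
  if (!all(samples %in% colnames(expr)) || !all(samples %in% colnames(meth))) {
    stop("requested samples missing from the expression or methylation matrix",
         call. = FALSE)
  }
  ex <- expr[, samples, drop = FALSE]
  me <- meth[, samples, drop = FALSE]
  probes_by_gene <- split(probe_map$probe_id, probe_map$gene)
  blocks <- vector("list", nrow(ex))
  names(blocks) <- rownames(ex)
  for (g in rownames(ex)) {
    probes <- intersect(probes_by_gene[[g]], rownames(me))
    sub <- NULL
    if (length(probes)) {
      sub <- t(me[probes, , drop = FALSE])
      miss <- colMeans(is.na(sub))
      sub <- sub[, miss <= max_missing, drop = FALSE]
      if (ncol(sub)) {
        for (j in seq_len(ncol(sub))) {
          nas <- is.na(sub[, j])
          if (any(nas)) sub[nas, j] <- mean(sub[!nas, j])
        }
      } else {
        sub <- NULL
      }
    }
    if (is.null(sub)) {
      if (include_expr_only) {
        blocks[[g]] <- merge_features(NULL, ex[g, ], gene = g)
      }
    } else {
      mb <- reduce_cpg(sub, variance_target = variance_target, gene = g)
      blocks[[g]] <- merge_features(mb, ex[g, ], gene = g)
    }
  }
  blocks[!vapply(blocks, is.null, logical(1L))]
}
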