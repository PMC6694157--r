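# Identification of altered pathways over original or extended gene lists:
# hypergeometric over-representation analysis with Benjamini-Hochberg
# correction, and gene set enrichment analysis with a signal-to-noise ranking,
# weighted Kolmogorov-Smirnov enrichment score, and phenotype-label
# permutations for NES, nominal p and FDR q.

#' Upper-tail hypergeometric p-value for over-representation
#'
#' Probability of drawing at least `k` differentially expressed genes when `n`
#' pathway genes are drawn without replacement from a background of `N` genes
#' of which `M` are differentially expressed:
#' `P = 1 - sum_{i=0}^{k-1} C(M, i) C(N - M, n - i) / C(N, n)`.
#'
#' @param N Background size.
#' @param M Number of differentially expressed genes in the background.
#' @param n Pathway size within the background.
#' @param k Differentially expressed genes within the pathway.
#' @return The upper-tail probability `P(X >= k)`.
#' @export
hypergeom_pvalue <- function(N, M, n, k) {
  if (any(c(N, M, n, k) < 0) || M > N || n > N || k > min(M, n)) {
    stop("require 0 <= M <= N, 0 <= n <= N, 0 <= k <= min(M, n)", call. = FALSE)
  }
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output positions correspond to input positions.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes between two phenotypes
#'
#' Per-gene two-sample Welch t-test (two-sided), Benjamini-Hochberg
#' correction, and a DE set at the adjusted-p threshold `alpha`. Genes that
#' are constant within both classes get p = 1 when the class means are equal
#' and p = 0 otherwise.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Named phenotype vector covering the matrix columns.
#' @param alpha Adjusted-p threshold for the DE set.
#' @return An object of class `de_result`: list with `table` (data.frame
#'   `gene`, `statistic`, `p_value`, `adjusted_p`), `de_genes` and `alpha`.
#' @export
call_de <- function(expr, labels, alpha = 0.05) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("every sample needs a phenotype label", call. = FALSE)
  case_idx <- which(labels == "case")
  ctrl_idx <- which(labels == "control")
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  stat <- p <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, case_idx]
    y <- expr[i, ctrl_idx]
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
      d <- mean(x) - mean(y)
      stat[i] <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
      p[i] <- if (abs(d) < 1e-12) 1 else 0
    } else {
      tt <- stats::t.test(x, y)
      stat[i] <- unname(tt$statistic)
      p[i] <- tt$p.value
    }
  }
  adj <- bh_adjust(p)
  tab <- data.frame(gene = rownames(expr), statistic = stat, p_value = p,
                    adjusted_p = adj, stringsAsFactors = FALSE)
  structure(list(table = tab, de_genes = tab$gene[adj <= alpha], alpha = alpha),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", length(x$de_genes), "of", nrow(x$table),
      "genes at adjusted p <=", x$alpha, "\n")
  invisible(x)
}

#' Over-representation analysis across a pathway collection
#'
#' Tests each pathway's overlap with the DE gene set against the
#' hypergeometric null, adjusts across the tested collection with
#' Benjamini-Hochberg, and assigns dense ranks by adjusted p. Pathways with no
#' gene in the background are skipped.
#'
#' @param collection A [pathway_collection()] (original or extended).
#' @param de A [call_de()] result, or a character vector of DE genes.
#' @param background Character vector: the gene universe (must contain every
#'   DE gene).
#' @return A data.frame with columns `pathway_id`, `pathway_name`, `N`, `M`,
#'   `n`, `k`, `p_value`, `adjusted_p`, `rank`, ordered by adjusted p then id.
#' @export
run_ora <- function(collection, de, background) {
  stopifnot(inherits(collection, "pathway_collection"))
  de_genes <- if (inherits(de, "de_result")) de$de_genes else as.character(de)
  background <- unique(background)
  if (!length(background)) stop("background gene set is empty", call. = FALSE)
  if (!all(de_genes %in% background)) {
    stop("every DE gene must be part of the background", call. = FALSE)
  }
  N <- length(background)
  M <- length(intersect(de_genes, background))
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(id) {
    genes_bg <- intersect(collection[[id]], background)
    n <- length(genes_bg)
    if (n == 0L) return(NULL)
    k <- length(intersect(genes_bg, de_genes))
    data.frame(pathway_id = id, pathway_name = unname(desc[id]),
               N = N, M = M, n = n, k = k,
               p_value = hypergeom_pvalue(N, M, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway overlaps the background", call. = FALSE)
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- out[order(out$adjusted_p, out$pathway_id), ]
  out$rank <- match(out$adjusted_p, sort(unique(out$adjusted_p)))
  rownames(out) <- NULL
  out
}

# vectorised signal-to-noise statistic with the standard sd floors
#' @keywords internal
.signal_to_noise <- function(expr, case_idx, ctrl_idx) {
  row_sd <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(pmax(0, (rowSums(m^2) - n * mu^2) / (n - 1)))
  }
  m1 <- rowMeans(expr[, case_idx, drop = FALSE])
  m2 <- rowMeans(expr[, ctrl_idx, drop = FALSE])
  s1 <- pmax(row_sd(expr[, case_idx, drop = FALSE]), 0.2 * abs(m1), 0.2)
  s2 <- pmax(row_sd(expr[, ctrl_idx, drop = FALSE]), 0.2 * abs(m2), 0.2)
  (m1 - m2) / (s1 + s2)
}

#' Rank genes by signal-to-noise ratio
#'
#' Computes `(mean_case - mean_control) / (sd_case + sd_control)` per gene,
#' with each sd floored at `max(sd, 0.2 |mean|, 0.2)` to stabilise
#' low-variance genes, and sorts descending (ties broken by gene symbol).
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Named phenotype vector covering the matrix columns.
#' @return A data.frame with columns `gene` and `score`, sorted for GSEA.
#' @export
gsea_rank <- function(expr, labels) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("every sample needs a phenotype label", call. = FALSE)
  case_idx <- which(labels == "case")
  ctrl_idx <- which(labels == "control")
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  s <- .signal_to_noise(expr, case_idx, ctrl_idx)
  ord <- order(-s, rownames(expr))
  data.frame(gene = rownames(expr)[ord], score = s[ord],
             stringsAsFactors = FALSE)
}

# Enrichment score from hit positions in the sorted ranking, O(|set|).
# pos must be sorted ascending; w are the matching |score|^exponent weights.
#' @keywords internal
.es_core <- function(n_total, pos, w) {
  n_hit <- length(pos)
  W <- sum(w)
  if (W <= 0) {
    w <- rep(1, n_hit)
    W <- n_hit
  }
  hitcum <- cumsum(w) / W
  if (n_hit == n_total) return(1)
  miss_at <- (pos - seq_len(n_hit)) / (n_total - n_hit)
  r_at <- hitcum - miss_at
  r_before <- r_at - w / W
  mx <- max(r_at)
  mn <- min(r_before)
  # near-ties (within rounding noise) resolve to the positive peak
  if (mx >= -mn - 1e-12) mx else mn
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked gene list, incrementing a running sum at set members
#' in proportion to `|score|^weight_exponent` (normalised over the set) and
#' decrementing by `1 / (N - N_hit)` at non-members. The enrichment score is
#' the signed maximum deviation from zero.
#'
#' @param ranked A [gsea_rank()] data.frame, or a named numeric vector of
#'   scores sorted in ranking order.
#' @param gene_set Character vector of set members.
#' @param weight_exponent Power applied to the scores (1 = standard weighted
#'   scheme, 0 = classic Kolmogorov-Smirnov).
#' @return List with `es` and `running` (the length-N running-sum profile).
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1) {
  if (is.data.frame(ranked)) {
    scores <- stats::setNames(ranked$score, ranked$gene)
  } else {
    scores <- ranked
  }
  if (is.null(names(scores))) stop("ranked scores must be named by gene", call. = FALSE)
  hits <- names(scores) %in% gene_set
  if (!any(hits)) {
    stop("gene set shares no gene with the ranked list", call. = FALSE)
  }
  n <- length(scores)
  n_hit <- sum(hits)
  w <- abs(scores)^weight_exponent
  w_hit <- w * hits
  W <- sum(w_hit)
  if (W <= 0) {
    w_hit <- as.numeric(hits)
    W <- n_hit
  }
  miss_step <- if (n_hit == n) 0 else 1 / (n - n_hit)
  running <- unname(cumsum(w_hit / W - (!hits) * miss_step))
  mx <- max(running)
  mn <- min(running)
  es <- if (mx >= -mn - 1e-12) mx else mn  # near-ties resolve to the positive peak
  list(es = es, running = running)
}

#' GSEA with phenotype-label permutations
#'
#' Computes the observed signal-to-noise ranking and enrichment score for each
#' gene set, then regenerates both under `n_perm` random phenotype
#' permutations. The normalised enrichment score (NES) divides each ES by the
#' mean magnitude of the same-sign permutation ESs of the same set; the
#' nominal p-value is the same-sign permutation tail; FDR q compares the
#' pooled permutation NES distribution with the observed NES values (the
#' standard phenotype-permutation procedure).
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Named phenotype vector covering the matrix columns.
#' @param collection A [pathway_collection()]; sets are restricted to genes
#'   present in `expr`, and sets with no overlap are dropped with a warning.
#' @param n_perm Number of phenotype permutations (>= 1).
#' @param seed RNG seed (required: permutations must be reproducible).
#' @param weight_exponent Passed to the enrichment score.
#' @return A data.frame with columns `pathway_id`, `pathway_name`, `size`,
#'   `ES`, `NES`, `nominal_p`, `FDR_q`, `rank`, ordered by FDR then id.
#' @export
gsea_significance <- function(expr, labels, collection, n_perm = 1000L,
                              seed, weight_exponent = 1) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible permutations", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  if (n_perm < 100L) {
    warning("fewer than 100 permutations: FDR resolution will be coarse",
            call. = FALSE)
  }
  labels <- labels[colnames(expr)]
  case_n <- sum(labels == "case")
  genes <- rownames(expr)
  set_idx <- lapply(collection, function(s) which(genes %in% s))
  keep <- lengths(set_idx) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " gene set(s) share no gene with the expression matrix",
            call. = FALSE)
  }
  set_idx <- set_idx[keep]
  ids <- names(collection)[keep]
  desc <- attr(collection, "descriptions")[keep]
  n_sets <- length(set_idx)
  if (!n_sets) stop("no gene set overlaps the expression matrix", call. = FALSE)

  es_for_scores <- function(scores) {
    ord <- order(-scores, genes)
    inv <- integer(length(genes))
    inv[ord] <- seq_along(genes)
    sorted <- scores[ord]
    vapply(set_idx, function(idx) {
      pos <- sort(inv[idx])
      .es_core(length(genes), pos, abs(sorted[pos])^weight_exponent)
    }, numeric(1L))
  }

  obs_scores <- .signal_to_noise(expr, which(labels == "case"),
                                 which(labels == "control"))
  es_obs <- es_for_scores(obs_scores)

  set.seed(seed)
  es_perm <- matrix(NA_real_, n_sets, n_perm)
  n_samples <- ncol(expr)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_samples)
    es_perm[, b] <- es_for_scores(
      .signal_to_noise(expr, perm[seq_len(case_n)], perm[-seq_len(case_n)]))
  }

  nes_obs <- numeric(n_sets)
  nominal_p <- numeric(n_sets)
  nes_perm <- matrix(NA_real_, n_sets, n_perm)
  for (s in seq_len(n_sets)) {
    ep <- es_perm[s, ]
    mean_pos <- mean(ep[ep > 0])
    mean_neg <- mean(abs(ep[ep < 0]))
    norm_one <- function(e) {
      if (e >= 0) {
        if (is.finite(mean_pos)) e / mean_pos else 0
      } else {
        if (is.finite(mean_neg)) e / mean_neg else 0
      }
    }
    nes_obs[s] <- norm_one(es_obs[s])
    nes_perm[s, ] <- vapply(ep, norm_one, numeric(1L))
    if (es_obs[s] >= 0) {
      same <- ep[ep >= 0]
      nominal_p[s] <- if (length(same)) mean(same >= es_obs[s]) else 1
    } else {
      same <- ep[ep < 0]
      nominal_p[s] <- if (length(same)) mean(same <= es_obs[s]) else 1
    }
  }

  pool <- as.vector(nes_perm)
  pool <- pool[is.finite(pool)]
  fdr_q <- vapply(seq_len(n_sets), function(s) {
    v <- nes_obs[s]
    if (v >= 0) {
      denom_pool <- sum(pool >= 0)
      num <- if (denom_pool) sum(pool >= v) / denom_pool else 0
      den <- sum(nes_obs >= v) / max(1L, sum(nes_obs >= 0))
    } else {
      denom_pool <- sum(pool < 0)
      num <- if (denom_pool) sum(pool <= v) / denom_pool else 0
      den <- sum(nes_obs <= v) / max(1L, sum(nes_obs < 0))
    }
    if (den <= 0) return(1)
    min(1, num / den)
  }, numeric(1L))

  out <- data.frame(pathway_id = ids, pathway_name = unname(desc),
                    size = lengths(set_idx), ES = es_obs, NES = nes_obs,
                    nominal_p = nominal_p, FDR_q = fdr_q,
                    stringsAsFactors = FALSE)
  out <- out[order(out$FDR_q, out$pathway_id), ]
  out$rank <- match(out$FDR_q, sort(unique(out$FDR_q)))
  rownames(out) <- NULL
  out
}
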