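# Sparse canonical correlation analysis (rank-1 penalized matrix
# decomposition) used to weight every surviving edge of the interaction
# network, per phenotype. The alternating soft-threshold solver and the
# bisection for the L1 bound are self-contained and fully deterministic.

# Maximise z'v over unit-L2 vectors v with ||v||_1 <= c_bound, via
# soft-thresholding with the threshold found by bisection. A unit-L2 vector
# always satisfies ||v||_1 >= 1, so callers must pass c_bound >= 1.
#' @keywords internal
.l1_unit_project <- function(z, c_bound) {
  nz <- sqrt(sum(z^2))
  if (nz < 1e-300) return(numeric(length(z)))
  v <- z / nz
  if (sum(abs(v)) <= c_bound + 1e-10) return(v)
  lo <- 0
  hi <- max(abs(z))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    s <- sign(z) * pmax(abs(z) - mid, 0)
    ns <- sqrt(sum(s^2))
    if (ns < 1e-300) {
      hi <- mid
    } else if (sum(abs(s)) / ns > c_bound) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  s <- sign(z) * pmax(abs(z) - hi, 0)
  ns <- sqrt(sum(s^2))
  if (ns < 1e-300) {
    # threshold collapsed everything: fall back to the single largest entry
    k <- which.max(abs(z))
    v <- numeric(length(z))
    v[k] <- sign(z[k])
    return(v)
  }
  s / ns
}

#' @keywords internal
.standardize_cols <- function(m) {
  m <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(m, 2L, stats::sd)
  ok <- sds > 1e-12
  m[, ok] <- sweep(m[, ok, drop = FALSE], 2L, sds[ok], "/")
  m
}

#' Sparse CCA weight for one gene pair
#'
#' Computes the rank-1 penalized-matrix-decomposition solution of the sparse
#' CCA problem: maximise `a' X' Y b` subject to `||a||_2 <= 1`,
#' `||b||_2 <= 1`, `||a||_1 <= c1 * sqrt(p)` and `||b||_1 <= c2 * sqrt(q)`
#' (each L1 bound floored at 1, the smallest attainable L1 norm of a unit-L2
#' vector). The solver alternates soft-thresholded updates of `a` and `b`,
#' each normalised with the threshold chosen by bisection, starting from the
#' leading right singular vector of `X' Y` (deterministic). The edge weight is
#' the Pearson correlation of the canonical variates `X a` and `Y b`.
#'
#' Columns are centred and unit-scaled internally (methylation PCs and
#' expression live on different scales).
#'
#' @param X,Y Numeric matrices, samples x p and samples x q, same row order.
#' @param c1,c2 Sparsity parameters in (0, 1).
#' @param tol Convergence tolerance on the change of the loading vectors.
#' @param max_iter Maximum number of alternations.
#' @return An object of class `scca_result`: list with loadings `a`, `b`, the
#'   canonical correlation `weight`, `iterations`, `converged`,
#'   `zero_variance` and the per-iteration `objective` trace (non-decreasing).
#' @export
scca_pair <- function(X, Y, c1 = 0.7, c2 = 0.7, tol = 1e-6, max_iter = 100L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same samples", call. = FALSE)
  if (nrow(X) < 4L) {
    stop("fewer than 4 samples in this phenotype; refusing to fit unstable weights",
         call. = FALSE)
  }
  if (!(c1 > 0 && c1 < 1 && c2 > 0 && c2 < 1)) {
    stop("c1 and c2 must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- ncol(X)
  q <- ncol(Y)
  Xs <- .standardize_cols(X)
  Ys <- .standardize_cols(Y)
  cb1 <- max(1, c1 * sqrt(p))
  cb2 <- max(1, c2 * sqrt(q))
  Z <- crossprod(Xs, Ys)
  if (max(abs(Z)) < 1e-12) {
    return(structure(list(a = numeric(p), b = numeric(q), weight = 0,
                          iterations = 0L, converged = TRUE,
                          zero_variance = TRUE, objective = numeric(0)),
                     class = "scca_result"))
  }
  b <- svd(Z, nu = 0L, nv = 1L)$v[, 1L]
  k <- which.max(abs(b))
  if (b[k] < 0) b <- -b
  b <- .l1_unit_project(b, cb2)   # warm start must satisfy the L1 bound
  a <- numeric(p)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a_old <- a
    b_old <- b
    a <- .l1_unit_project(drop(Z %*% b), cb1)
    objective <- c(objective, drop(crossprod(a, Z %*% b)))
    b <- .l1_unit_project(drop(crossprod(Z, a)), cb2)
    objective <- c(objective, drop(crossprod(a, Z %*% b)))
    if (max(abs(a - a_old)) < tol && max(abs(b - b_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  u <- drop(Xs %*% a)
  v <- drop(Ys %*% b)
  zero_var <- stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12
  weight <- if (zero_var) 0 else stats::cor(u, v)
  structure(list(a = a, b = b, weight = weight, iterations = iter,
                 converged = converged, zero_variance = zero_var,
                 objective = objective),
            class = "scca_result")
}

#' @export
print.scca_result <- function(x, ...) {
  cat("scca_result: weight =", format(x$weight, digits = 4),
      "| iterations =", x$iterations,
      "| converged =", x$converged, "\n")
  invisible(x)
}

#' Build a phenotype-specific weighted gene network
#'
#' Weights every edge of the interaction list whose two endpoints both have a
#' feature block, with the absolute sparse-CCA canonical correlation of the
#' two blocks (absolute value so the downstream random-walk transition matrix
#' is well defined). Edges with a missing endpoint are deleted, matching the
#' rule that a gene without data removes its edges.
#'
#' @param blocks Named list of `gene_feature_block` matrices for one
#'   phenotype (see [build_feature_blocks()]).
#' @param edges Edge list data.frame with columns `gene_a`, `gene_b`.
#' @param c1,c2,tol,max_iter Passed to [scca_pair()].
#' @param phenotype Label stored on the network, `"case"` or `"control"`.
#' @return An object of class `weighted_network`: list with `phenotype`,
#'   `nodes`, `edges` (data.frame `gene_a`, `gene_b`, `weight` in \[0, 1\]),
#'   and counts `n_deleted` / `n_nonconverged`.
#' @export
build_weighted_network <- function(blocks, edges, c1 = 0.7, c2 = 0.7,
                                   tol = 1e-6, max_iter = 100L,
                                   phenotype = c("case", "control")) {
  phenotype <- match.arg(phenotype)
  have <- edges$gene_a %in% names(blocks) & edges$gene_b %in% names(blocks)
  n_deleted <- sum(!have)
  kept <- edges[have, , drop = FALSE]
  if (!nrow(kept)) {
    stop("no edge has feature data at both endpoints; cannot build the ",
         phenotype, " network", call. = FALSE)
  }
  w <- numeric(nrow(kept))
  nonconv <- 0L
  for (i in seq_len(nrow(kept))) {
    fit <- scca_pair(blocks[[kept$gene_a[i]]], blocks[[kept$gene_b[i]]],
                     c1 = c1, c2 = c2, tol = tol, max_iter = max_iter)
    if (!fit$converged) nonconv <- nonconv + 1L
    w[i] <- min(1, abs(fit$weight))
  }
  out <- data.frame(gene_a = kept$gene_a, gene_b = kept$gene_b, weight = w,
                    stringsAsFactors = FALSE)
  structure(list(phenotype = phenotype,
                 nodes = sort(unique(c(out$gene_a, out$gene_b))),
                 edges = out,
                 n_deleted = n_deleted,
                 n_nonconverged = nonconv),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network (", x$phenotype, "): ", length(x$nodes), " genes, ",
      nrow(x$edges), " edges (", x$n_deleted, " deleted for missing data)\n",
      sep = "")
  invisible(x)
}

#' Write a weighted network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `weight`, `phenotype`.
#'
#' @param net A `weighted_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  df <- net$edges
  df$phenotype <- net$phenotype
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted network written by [write_network()]
#'
#' @param path Path to the edge-list TSV.
#' @return A `weighted_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "character"))
  need <- c("gene_a", "gene_b", "weight", "phenotype")
  if (!all(need %in% colnames(df))) {
    stop("network file '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$weight)) || any(df$weight < 0 | df$weight > 1)) {
    stop("network file '", path, "' has weights outside [0, 1]", call. = FALSE)
  }
  pheno <- unique(df$phenotype)
  if (length(pheno) != 1L || !pheno %in% c("case", "control")) {
    stop("network file '", path, "' must carry one phenotype, 'case' or 'control'",
         call. = FALSE)
  }
  structure(list(phenotype = pheno,
                 nodes = sort(unique(c(df$gene_a, df$gene_b))),
                 edges = df[, c("gene_a", "gene_b", "weight")],
                 n_deleted = NA_integer_,
                 n_nonconverged = NA_integer_),
            class = "weighted_network")
}
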