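# Readers and writers for every external representation the pipeline touches.
# All files are UTF-8, tab-delimited. Readers validate strictly and report the
# offending line/cell; writers produce output the readers round-trip.

#' @keywords internal
.read_matrix_tsv <- function(path, what = "matrix", allow_na = FALSE) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("malformed ", what, " file '", path,
         "': need a header row of sample ids and at least one data row",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id '", samples[duplicated(samples)][1L],
         "' in header of ", path, call. = FALSE)
  }
  if (any(!nzchar(samples))) {
    stop("empty sample id in header of ", path, call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  na_token <- is.na(vals) |
    toupper(trimws(vals)) %in% c("NA", "NAN") | !nzchar(trimws(vals))
  bad <- which(is.na(num) & !na_token)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(num))
    stop(sprintf("non-numeric value '%s' in %s file '%s' (line %d, sample '%s')",
                 vals[bad[1L]], what, path, rc[1L, 1L] + 1L, samples[rc[1L, 2L]]),
         call. = FALSE)
  }
  if (!allow_na && anyNA(num)) {
    rc <- arrayInd(which(is.na(num))[1L], dim(num))
    stop(sprintf("missing value in %s file '%s' (line %d, sample '%s'); missing values are not allowed here",
                 what, path, rc[1L, 1L] + 1L, samples[rc[1L, 2L]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, samples)
  num
}

#' @keywords internal
.write_matrix_tsv <- function(mat, path, id_col) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a gene expression matrix
#'
#' Reads a genes-by-samples TSV (first column gene symbols, header row sample
#' ids). Duplicate gene rows are collapsed by their mean, which is the usual
#' convention for array-style data where one gene is measured by several
#' reporters.
#'
#' @param path Path to a tab-delimited file.
#' @param transform Either `"none"` or `"log2_plus1"`; the latter applies
#'   `log2(x + 1)` as done for raw count-scale data.
#' @return A numeric matrix (genes x samples) with unique row and column names.
#' @export
read_expression <- function(path, transform = c("none", "log2_plus1")) {
  transform <- match.arg(transform)
  m <- .read_matrix_tsv(path, what = "expression", allow_na = FALSE)
  if (any(!nzchar(rownames(m)))) {
    stop("empty gene symbol in expression file '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  if (transform == "log2_plus1") {
    if (any(m < 0)) {
      stop("negative expression value; log2(x + 1) requires non-negative input",
           call. = FALSE)
    }
    m <- log2(m + 1)
  }
  if (!all(is.finite(m))) {
    stop("non-finite expression value after transformation", call. = FALSE)
  }
  m
}

#' Write a gene expression matrix
#'
#' @param mat Numeric matrix, genes x samples.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(mat, path) {
  .write_matrix_tsv(mat, path, "gene_id")
}

#' Read a DNA methylation beta matrix
#'
#' Reads a CpG-probes-by-samples TSV of beta values. Beta values must lie in
#' \[0, 1\]; cells given as `NA` (or left empty) are recorded as missing.
#'
#' @param path Path to a tab-delimited file, first column probe ids.
#' @return A numeric matrix (probes x samples), possibly containing `NA`.
#' @export
read_methylation <- function(path) {
  m <- .read_matrix_tsv(path, what = "methylation", allow_na = TRUE)
  if (anyDuplicated(rownames(m))) {
    stop("duplicate probe id '", rownames(m)[duplicated(rownames(m))][1L],
         "' in methylation file '", path, "'", call. = FALSE)
  }
  out <- which(m < 0 | m > 1)
  if (length(out)) {
    rc <- arrayInd(out[1L], dim(m))
    stop(sprintf("beta value %g outside [0, 1] for probe '%s', sample '%s'",
                 m[out[1L]], rownames(m)[rc[1L, 1L]], colnames(m)[rc[1L, 2L]]),
         call. = FALSE)
  }
  m
}

#' Write a DNA methylation beta matrix
#'
#' @param mat Numeric matrix, probes x samples; `NA` allowed.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_methylation <- function(mat, path) {
  .write_matrix_tsv(mat, path, "probe_id")
}

#' Read a CpG probe to gene annotation table
#'
#' Expects columns `probe_id` and `gene` (450k-manifest style, reduced to the
#' two columns this pipeline needs). A probe annotated to several genes may
#' appear on several rows; the probe then contributes to each mapped gene.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A data.frame with character columns `probe_id` and `gene`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "gene")
  if (!all(need %in% colnames(df))) {
    stop("probe map file '", path, "' must have columns 'probe_id' and 'gene'",
         call. = FALSE)
  }
  df <- df[, need]
  if (any(!nzchar(trimws(df$gene))) || any(!nzchar(trimws(df$probe_id)))) {
    stop("empty probe id or gene symbol in probe map file '", path, "'",
         call. = FALSE)
  }
  if (anyDuplicated(df)) {
    stop("duplicate (probe_id, gene) row in probe map file '", path, "'",
         call. = FALSE)
  }
  df
}

#' Write a probe to gene annotation table
#' @param map Data.frame with columns `probe_id`, `gene`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_probe_map <- function(map, path) {
  utils::write.table(map[, c("probe_id", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-gene interaction edge list
#'
#' Expects columns `gene_a`, `gene_b` and optionally `source`. Edges are
#' undirected; each row is canonicalised so that `gene_a < gene_b`. Self-loops
#' and duplicate unordered pairs are rejected.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A data.frame with columns `gene_a`, `gene_b` (and `source` if
#'   present in the file).
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("gene_a", "gene_b") %in% colnames(df))) {
    stop("edge list file '", path, "' must have columns 'gene_a' and 'gene_b'",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("edge list file '", path, "' has no edges", call. = FALSE)
  }
  loop <- df$gene_a == df$gene_b
  if (any(loop)) {
    stop("self-loop on gene '", df$gene_a[loop][1L], "' in edge list '", path,
         "' (line ", which(loop)[1L] + 1L, ")", call. = FALSE)
  }
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate edge ", a[d], " - ", b[d], " in edge list '", path,
         "' (line ", d + 1L, ")", call. = FALSE)
  }
  out <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  if ("source" %in% colnames(df)) out$source <- df$source
  out
}

#' Write a gene-gene interaction edge list
#' @param edges Data.frame with columns `gene_a`, `gene_b` (optional `source`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  keep <- intersect(c("gene_a", "gene_b", "source"), colnames(edges))
  utils::write.table(edges[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a pathway collection
#'
#' @param sets Named list of character vectors (gene symbols) keyed by
#'   pathway id.
#' @param descriptions Optional character vector of pathway names, same length
#'   and order as `sets`; defaults to the ids.
#' @return An object of class `pathway_collection`: the named list of gene
#'   sets, with a `description` attribute.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every pathway needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate pathway id '", names(sets)[duplicated(names(sets))][1L],
         "'", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("pathway '", names(sets)[lengths(sets) == 0L][1L],
         "' has an empty gene set", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- names(sets)
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(lapply(sets, as.character), descriptions = descriptions,
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x), "gene sets,",
      "sizes", min(lengths(x)), "-", max(lengths(x)), "\n")
  invisible(x)
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Gene order is preserved as
#' read; duplicate genes within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file '", path, "' is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], " in '", path,
         "' has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id '", ids[duplicated(ids)][1L], "' in GMT file '",
         path, "'", call. = FALSE)
  }
  desc <- vapply(parts, `[[`, character(1L), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  pathway_collection(sets, descriptions = desc)
}

#' Write pathway gene sets in GMT format
#'
#' @param collection A [pathway_collection].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- names(collection)
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[[i]], collection[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read phenotype labels
#'
#' Expects a TSV with columns `sample_id` and `label`, where every label is
#' `case` or `control`.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A named character vector (names = sample ids, values in
#'   `c("case", "control")`).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df))) {
    stop("phenotype file '", path,
         "' must have columns 'sample_id' and 'label'", call. = FALSE)
  }
  bad <- !df$label %in% c("case", "control")
  if (any(bad)) {
    stop("invalid phenotype label '", df$label[bad][1L], "' in '", path,
         "' (line ", which(bad)[1L] + 1L, "); expected 'case' or 'control'",
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id '", df$sample_id[duplicated(df$sample_id)][1L],
         "' in phenotype file '", path, "'", call. = FALSE)
  }
  stats::setNames(df$label, df$sample_id)
}

#' Write phenotype labels
#' @param labels Named character vector of `case`/`control` labels.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a cohort to samples measured on both platforms
#'
#' Keeps only the samples present in the expression matrix, the methylation
#' matrix and the phenotype labels, and puts all three objects into one
#' canonical (sorted) sample order. Idempotent.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meth Methylation matrix (probes x samples).
#' @param labels Named phenotype vector.
#' @return A list with elements `expression`, `methylation`, `labels`.
#' @export
intersect_cohort <- function(expr, meth, labels) {
  common <- Reduce(intersect,
                   list(colnames(expr), colnames(meth), names(labels)))
  common <- sort(common)
  if (!length(common)) {
    stop("no samples have expression, methylation and a phenotype label",
         call. = FALSE)
  }
  lab <- labels[common]
  n_by_class <- table(factor(lab, levels = c("case", "control")))
  if (any(n_by_class < 2L)) {
    stop("phenotype class '",
         names(n_by_class)[n_by_class < 2L][1L],
         "' has fewer than 2 samples after intersecting the cohort",
         call. = FALSE)
  }
  list(expression = expr[, common, drop = FALSE],
       methylation = meth[, common, drop = FALSE],
       labels = lab)
}
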