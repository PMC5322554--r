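# Expression analysis: 0-6 binning, two-class hierarchical clustering
# (Pearson correlation distance, complete linkage), cross-species
# concordance of expression classes, reference-gene normalization, pooled
# tissue PCA and tissue fold-change ANOVA.

#' Bin expression values onto a 0-6 scale
#'
#' Maps abundances to the seven-level ordinal scale (0 = very low/no
#' expression ... 6 = extremely high expression) using 7 ordered breakpoint
#' intervals covering [0, Inf): a value in `[breakpoints[i], breakpoints[i+1])`
#' gets bin `i - 1`; values at or above the last breakpoint get 6. Binning
#' is monotone. The default breakpoints are log-spaced; they are a
#' configurable convention, not a published calibration.
#'
#' @param matrix Non-negative numeric matrix (genes x conditions).
#' @param breakpoints Strictly increasing vector of 7 interval lower
#'   edges, the first equal to 0.
#' @return Integer matrix of bins in 0..6, same dimnames.
#' @export
bin_expression <- function(matrix, breakpoints = c(0, 1, 4, 16, 64, 256, 1024)) {
  if (length(breakpoints) != 7 || is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be 7 strictly increasing values", call. = FALSE)
  }
  if (breakpoints[1] != 0) {
    stop("breakpoints must cover [0, Inf): first breakpoint must be 0",
         call. = FALSE)
  }
  out <- findInterval(matrix, breakpoints) - 1L
  dim(out) <- dim(matrix)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Two-class expression clustering
#'
#' Agglomerative clustering of gene expression profiles with distance
#' `1 - Pearson r` and complete linkage, cut into exactly two clusters. The
#' cluster with the higher grand-mean raw expression is labelled `"high"`
#' (ties toward `"low"`). Zero-variance profiles have no defined Pearson
#' distance; they are assigned directly to the `"low"` class and recorded
#' in the `"zero_variance"` attribute.
#'
#' @param matrix Numeric matrix, genes x stages (>= 2 of each).
#' @param transform Profile transform before correlation: `"log10"`
#'   (default; `log10(x + pseudocount)`), `"raw"`, or `"binned"` (0-6 bins).
#' @param pseudocount Pseudocount for the log transform.
#' @return Named character vector of labels (`"high"`/`"low"`), with the
#'   `hclust` tree in attribute `"tree"` and zero-variance gene ids in
#'   attribute `"zero_variance"`.
#' @export
cluster_two_class <- function(matrix, transform = c("log10", "raw", "binned"),
                              pseudocount = 0.01) {
  transform <- match.arg(transform)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("cluster_two_class: need at least 2 genes and 2 stages", call. = FALSE)
  }
  x <- switch(transform,
              log10 = log10(matrix + pseudocount),
              raw = matrix,
              binned = bin_expression(matrix))
  sds <- apply(x, 1, stats::sd)
  flat <- sds == 0
  labels <- stats::setNames(rep(NA_character_, nrow(matrix)), rownames(matrix))
  labels[flat] <- "low"
  tree <- NULL
  if (sum(!flat) >= 2) {
    xv <- x[!flat, , drop = FALSE]
    d <- stats::as.dist(1 - stats::cor(t(xv)))
    tree <- stats::hclust(d, method = "complete")
    cl <- stats::cutree(tree, k = 2)
    gm <- vapply(1:2, function(k) mean(matrix[!flat, , drop = FALSE][cl == k, ]),
                 numeric(1))
    high_cluster <- if (gm[1] > gm[2]) 1L else 2L  # tie -> cluster 2 = "low"
    labels[!flat] <- ifelse(cl == high_cluster, "high", "low")
  } else if (sum(!flat) == 1) {
    labels[!flat] <- "low"
  }
  attr(labels, "tree") <- tree
  attr(labels, "zero_variance") <- rownames(matrix)[flat]
  labels
}

#' Cross-species concordance of expression classes
#'
#' Counts ortholog pairs whose two members share the same expression class
#' in both species, with breakdowns of the concordant set by class and of
#' the discordant set by functional category.
#'
#' @param labels_a,labels_b Named label vectors from [cluster_two_class()].
#' @param ortholog_map Data frame with columns `gene_a`, `gene_b` pairing
#'   genes of the two species.
#' @param categories Optional named character vector mapping `gene_a` ids to
#'   functional categories, used for the discordant-set breakdown.
#' @return List with `n_same`, `n_diff` (summing to `nrow(ortholog_map)`),
#'   `same_by_class` (high/high and low/low counts) and `diff_by_category`.
#' @export
concordance <- function(labels_a, labels_b, ortholog_map, categories = NULL) {
  la <- labels_a[ortholog_map$gene_a]
  lb <- labels_b[ortholog_map$gene_b]
  if (anyNA(la) || anyNA(lb)) {
    stop("concordance: unlabeled gene in ortholog map", call. = FALSE)
  }
  same <- la == lb
  same_by_class <- c(high = sum(same & la == "high"),
                     low = sum(same & la == "low"))
  diff_by_category <- NULL
  if (!is.null(categories)) {
    cats <- categories[ortholog_map$gene_a[!same]]
    diff_by_category <- table(cats, useNA = "ifany")
  }
  list(n_same = sum(same), n_diff = sum(!same),
       same_by_class = same_by_class, diff_by_category = diff_by_category)
}

#' Normalize expression to a reference gene
#'
#' Converts each value to a log10 ratio against the reference gene's
#' expression in the same condition:
#' `log10((value + pseudocount) / (ref + pseudocount))`. The reference row
#' maps to all zeros. Scaling a whole condition leaves the ratios
#' unchanged.
#'
#' @param matrix Non-negative matrix, genes x conditions.
#' @param ref_gene Reference gene id (must be a row).
#' @param pseudocount Added to numerator and denominator; with
#'   `pseudocount = 0` the reference must be positive in every condition.
#' @return Matrix of log10 ratios, same dimnames.
#' @export
normalize_to_reference <- function(matrix, ref_gene, pseudocount = 0.01) {
  if (!ref_gene %in% rownames(matrix)) {
    stop("reference gene '", ref_gene, "' absent from matrix", call. = FALSE)
  }
  ref <- matrix[ref_gene, ]
  if (pseudocount == 0 && any(ref == 0)) {
    stop("reference gene has zero expression in a condition and no ",
         "pseudocount was given", call. = FALSE)
  }
  log10(sweep(matrix + pseudocount, 2, ref + pseudocount, "/"))
}

#' Pooled two-species tissue PCA
#'
#' Stacks the two species' gene-by-tissue matrices (rows tagged by
#' species), column-centers, and decomposes with `prcomp`. Variance
#' fractions come from the squared singular values; columns are not scaled
#' unless requested.
#'
#' @param matrix_a,matrix_b Matrices sharing the same tissue columns
#'   (>= 2 tissues).
#' @param scale Scale columns to unit variance before decomposition.
#' @return List of class `"pca_result"`: `var_fractions` (non-negative,
#'   descending, summing to 1), `loadings` (tissues x components),
#'   `scores` (genes x components, rownames species-tagged).
#' @export
pca_tissue <- function(matrix_a, matrix_b, scale = FALSE) {
  if (!identical(colnames(matrix_a), colnames(matrix_b))) {
    stop("pca_tissue: the two matrices must share tissue columns", call. = FALSE)
  }
  if (ncol(matrix_a) < 2) stop("pca_tissue: need at least 2 tissues", call. = FALSE)
  rownames_a <- paste0("spA:", rownames(matrix_a))
  rownames_b <- paste0("spB:", rownames(matrix_b))
  x <- rbind(matrix_a, matrix_b)
  rownames(x) <- c(rownames_a, rownames_b)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  v <- pc$sdev^2
  structure(list(var_fractions = v / sum(v), loadings = pc$rotation,
                 scores = pc$x), class = "pca_result")
}

#' Per-tissue expression fold-change with one-way ANOVA
#'
#' For every ortholog pair and tissue, computes
#' `log10((a + pseudocount) / (b + pseudocount))`, reports per-tissue mean
#' fold-changes, and tests whether mean fold-change differs across tissues
#' with a one-way ANOVA over the per-pair values.
#'
#' @param matrix_a,matrix_b Matrices sharing tissue columns; rows indexed
#'   by the genes of the respective species.
#' @param ortholog_map Data frame with columns `gene_a`, `gene_b`.
#' @param pseudocount Pseudocount; with 0, zero denominators are an error.
#' @return List with `means` (named per-tissue mean log10 fold-change),
#'   `p_value`, `anova` (the `aov` summary) and `fold_changes` (pairs x
#'   tissues matrix).
#' @export
tissue_fold_change_anova <- function(matrix_a, matrix_b, ortholog_map,
                                     pseudocount = 0.01) {
  if (!identical(colnames(matrix_a), colnames(matrix_b))) {
    stop("matrices must share tissue columns", call. = FALSE)
  }
  if (ncol(matrix_a) < 2 || nrow(ortholog_map) < 2) {
    stop("need >= 2 tissues and >= 2 ortholog pairs", call. = FALSE)
  }
  a <- matrix_a[ortholog_map$gene_a, , drop = FALSE]
  b <- matrix_b[ortholog_map$gene_b, , drop = FALSE]
  if (pseudocount == 0 && any(b == 0)) {
    stop("zero denominator without pseudocount", call. = FALSE)
  }
  fc <- log10((a + pseudocount) / (b + pseudocount))
  rownames(fc) <- ortholog_map$gene_a
  long <- data.frame(
    lfc = as.vector(fc),
    tissue = factor(rep(colnames(fc), each = nrow(fc))))
  if (stats::var(long$lfc) == 0) {
    # no variation at all: trivially no tissue effect
    return(list(means = colMeans(fc), p_value = 1, anova = NULL,
                fold_changes = fc))
  }
  fit <- stats::aov(lfc ~ tissue, data = long)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(means = colMeans(fc), p_value = p, anova = summary(fit),
       fold_changes = fc)
}
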