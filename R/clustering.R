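## Joint hierarchical clustering of genes and accessions on relative
## expression, reproducing a pheatmap-style stratification: agglomerative
## trees on rows and on columns, cut at a user-chosen k on each axis.
## Cluster ids are assigned by decreasing cluster size so that "cluster 1"
## is always the largest (the reference-like group downstream).

#' Hierarchically bicluster genes and accessions
#'
#' Runs agglomerative hierarchical clustering independently on genes (rows)
#' and accessions (columns) of a relative expression matrix and cuts each
#' tree at the requested number of clusters.  Defaults (euclidean distance,
#' complete linkage) mirror the pheatmap defaults.  k is always supplied by
#' the caller; the package never auto-selects it.
#'
#' @param expr an [expression_matrix()] on the `relative` scale.
#' @param k_genes,k_accessions number of clusters on each axis (>= 2, at
#'   most the number of items).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson).
#' @param linkage `"complete"`, `"average"` or `"ward"` (ward.D2).
#' @return List with elements `genes` and `accessions`, each a [grouping()]
#'   (ids by decreasing cluster size), plus the two `hclust` trees.
#' @export
hierarchical_bicluster <- function(expr, k_genes, k_accessions,
                                   distance = c("euclidean", "correlation"),
                                   linkage = c("complete", "average", "ward")) {
  gk_assert(inherits(expr, "expression_matrix") && expr$scale == "relative",
            "expr must be a relative-scale expression_matrix")
  gk_assert(!anyNA(expr$values), "expression matrix contains missing values")
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  method <- c(complete = "complete", average = "average", ward = "ward.D2")[linkage]
  cut_axis <- function(m, k) {
    gk_assert(k >= 2 && k <= nrow(m),
              sprintf("k = %d outside 2..%d", k, nrow(m)))
    d <- if (distance == "euclidean") dist(m) else as.dist(1 - cor(t(m)))
    tree <- hclust(d, method = method)
    raw <- cutree(tree, k = k)
    ## relabel by decreasing size; ties broken by first appearance
    sizes <- tabulate(raw, k)
    ord <- order(-sizes, seq_len(k))
    relab <- match(raw, ord)
    list(grouping = grouping(setNames(relab, rownames(m)), k), tree = tree)
  }
  g <- cut_axis(expr$values, k_genes)
  a <- cut_axis(t(expr$values), k_accessions)
  list(genes = g$grouping, accessions = a$grouping,
       gene_tree = g$tree, accession_tree = a$tree)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting contingency table.  1 means identical
#' partitions; ~0 means chance-level agreement.
#'
#' @param labels_a,labels_b named vectors labeling exactly the same items.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  gk_assert(!is.null(names(labels_a)) && !is.null(names(labels_b)),
            "labelings must be named by item")
  gk_assert(setequal(names(labels_a), names(labels_b)) &&
              length(labels_a) == length(labels_b),
            "labelings must cover the same items")
  b <- labels_b[names(labels_a)]
  tab <- table(labels_a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  index <- sum_comb(tab)
  exp_index <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_index <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (max_index == exp_index) return(0)     # degenerate partitions
  (index - exp_index) / (max_index - exp_index)
}
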