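## Graphical Gaussian model inference for one accession group.
##
## Edges are partial correlations estimated from a shrunken correlation
## matrix (Schaefer-Strimmer optimal shrinkage toward the identity target),
## and tested against the analytic null density of a partial correlation
## under kappa degrees of freedom,
##   f0(r; kappa) = (1 - r^2)^((kappa-3)/2) / Beta(1/2, (kappa-1)/2),
## with kappa fitted to the observed edge distribution by maximum
## likelihood under the assumption that the bulk of edges is null.

#' Optimal shrinkage intensity for the correlation matrix
#'
#' Schaefer-Strimmer analytic shrinkage toward the identity correlation
#' target: `lambda* = sum Var(r_ij) / sum r_ij^2` over off-diagonal pairs,
#' clipped to \[0, 1\]. `Var(r_ij)` is the unbiased estimate of the sampling
#' variance of each empirical correlation computed from standardized data.
#'
#' @param data an `expression_matrix` (genes x accessions) or a plain
#'   numeric matrix with genes as rows.
#' @return Shrinkage intensity in \[0, 1\].
#' @export
shrinkage_intensity <- function(data) {
  x <- expr_values(data)            # genes x samples
  n <- ncol(x)
  p <- nrow(x)
  gk_assert(n >= 3, "need at least 3 samples to estimate shrinkage")
  gk_assert(p >= 2, "need at least 2 genes")
  sds <- apply(x, 1, sd)
  if (any(sds == 0))
    gk_stop(paste("constant gene(s):",
                  paste(rownames(x)[sds == 0], collapse = ", ")),
            "glknet_constant_gene")
  z <- (x - rowMeans(x)) / sds      # standardized, sd denominator n-1
  ## w_kij = z_ik z_jk ; r_ij = sum_k w_kij / (n-1)
  r <- tcrossprod(z) / (n - 1)
  ## Var-hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2, where
  ## sum_k w_kij = (n-1) r_ij, so the centered sum of squares is
  ## sum_k w^2 - (n-1)^2 r^2 / n.
  sw <- tcrossprod(z^2)
  varsum <- n / (n - 1)^3 * (sw - (n - 1)^2 * r^2 / n)
  off <- upper.tri(r)
  lam <- sum(varsum[off]) / sum(r[off]^2)
  min(1, max(0, lam))
}

## internal: pull the genes x samples numeric matrix out of either container
expr_values <- function(data) {
  if (inherits(data, "expression_matrix")) data$values
  else if (is.matrix(data)) data
  else gk_stop("data must be an expression_matrix or matrix", "glknet_invalid")
}

#' Partial correlations from a correlation matrix
#'
#' Shrinks `R* = lambda I + (1 - lambda) R`, inverts, and standardizes the
#' precision matrix: `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`, with
#' unit diagonal.
#'
#' @param R correlation matrix.
#' @param lambda shrinkage intensity in \[0, 1\].
#' @return Symmetric partial-correlation matrix with unit diagonal.
#' @export
pcor_from_correlation <- function(R, lambda = 0) {
  gk_assert(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  p <- nrow(R)
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1        # identity target only affects the off-diagonal
  omega <- tryCatch(solve(Rs), error = function(e)
    gk_stop("correlation matrix is singular; use lambda > 0",
            "glknet_singular"))
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(R)
  (pc + t(pc)) / 2
}

#' Shrinkage partial correlations from expression data
#'
#' @inheritParams shrinkage_intensity
#' @param lambda shrinkage intensity; see [shrinkage_intensity()].
#' @return Symmetric partial-correlation matrix (genes x genes).
#' @export
partial_correlations <- function(data, lambda) {
  x <- expr_values(data)
  pcor_from_correlation(cor(t(x)), lambda)
}

#' Fit the null degrees of freedom of the edge distribution
#'
#' Maximizes the likelihood of `f0(r; kappa)` over the observed off-diagonal
#' partial correlations, assuming the bulk is null. The search is bounded on
#' `kappa` in `(3, 1e7]`; samples concentrated at 0 push the fit to the
#' upper bound (near-degenerate null, flagged with a message).
#'
#' @param pcors numeric vector of off-diagonal partial correlations.
#' @param lower,upper bounds of the kappa search.  The default upper bound
#'   grows with the concentration of the observed distribution (the ML
#'   estimate behaves like `1/var(r)` for concentrated nulls, which heavy
#'   shrinkage can push far beyond any fixed bound).
#' @return Fitted kappa (scalar).
#' @export
estimate_null_kappa <- function(pcors, lower = 3 + 1e-8, upper = NULL) {
  pcors <- pcors[!is.na(pcors)]
  gk_assert(length(pcors) >= 10, "need at least 10 partial correlations")
  gk_assert(all(abs(pcors) < 1), "partial correlations must lie in (-1, 1)")
  if (is.null(upper))
    upper <- max(1e7, 100 / max(mean(pcors^2), 1e-300))
  negll <- function(logk) {
    k <- exp(logk)
    -sum((k - 3) / 2 * log1p(-pcors^2) - lbeta(0.5, (k - 1) / 2))
  }
  opt <- optimize(negll, interval = log(c(lower, upper)), tol = 1e-10)
  kap <- exp(opt$minimum)
  if (kap > 0.99 * upper)
    message("estimate_null_kappa: fit at upper bound (near-degenerate null)")
  kap
}

#' Edge p-values under the analytic null
#'
#' Two-sided `p_ij = P(|R| >= |pcor_ij|)` under `f0(r; kappa)`; since
#' `R^2 ~ Beta(1/2, (kappa-1)/2)` under the null, the tail is the
#' regularized incomplete beta function.
#'
#' @param pcor symmetric partial-correlation matrix.
#' @param kappa null degrees of freedom, `> 3`.
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
edge_pvalues <- function(pcor, kappa) {
  gk_assert(kappa > 3, "kappa must exceed 3")
  p <- pbeta(pcor^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(pcor)
  p
}

#' Build a graphical Gaussian network for one accession group
#'
#' Restricts the expression matrix to a gene panel, estimates the shrinkage
#' intensity, partial correlations, the null kappa and edge p-values, and
#' collects the significant edge list.
#'
#' @param data an `expression_matrix` (genes x accessions; normalized scale).
#' @param panel character vector of panel gene ids (default: all genes).
#' @param alpha edge significance level on the raw p-value (default 0.05,
#'   no multiplicity correction: edges are screened, not certified).
#' @return An object of class `ggm_network` with elements `genes`, `pcor`,
#'   `lambda`, `kappa`, `p_values` and `edges` (data.frame `gene_i`,
#'   `gene_j`, `pcor`, `p`, sorted by ascending p then descending |pcor|).
#' @export
build_network <- function(data, panel = NULL, alpha = 0.05) {
  x <- expr_values(data)
  if (is.null(panel)) panel <- rownames(x)
  missing <- setdiff(panel, rownames(x))
  if (length(missing) > 0)
    gk_stop(paste("panel genes absent from data:",
                  paste(missing, collapse = ", ")), "glknet_missing_gene")
  x <- x[panel, , drop = FALSE]
  ## cap shrinkage strictly below 1: at the saturation point (typical for
  ## signal-free panels) all partial correlations collapse to exactly zero
  ## and the edge ordering (and its null fit) becomes undefined; the cap
  ## preserves the ordering, and the kappa fit absorbs the overall scale.
  lambda <- min(shrinkage_intensity(x), 1 - 1e-3)
  pc <- partial_correlations(x, lambda)
  off <- pc[upper.tri(pc)]
  kappa <- estimate_null_kappa(off)
  pv <- edge_pvalues(pc, kappa)
  idx <- which(upper.tri(pv) & pv < alpha, arr.ind = TRUE)
  edges <- data.frame(
    gene_i = panel[idx[, 1]],
    gene_j = panel[idx[, 2]],
    pcor   = pc[idx],
    p      = pv[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$p, -abs(edges$pcor), edges$gene_i, edges$gene_j), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = panel, pcor = pc, lambda = lambda, kappa = kappa,
                 p_values = pv, alpha = alpha, edges = edges),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf(
    "<ggm_network> %d genes, %d edges at alpha=%g (lambda=%.3f, kappa=%.1f)\n",
    length(x$genes), nrow(x$edges), x$alpha, x$lambda, x$kappa))
  invisible(x)
}
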