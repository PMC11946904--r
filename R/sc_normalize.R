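#' Log-normalize a TPM expression matrix
#'
#' Applies `E = log2(TPM/10 + 1)` elementwise. The division by 10 reflects an
#' assumed library complexity of ~100,000 transcripts rather than the one
#' million implied by the TPM unit, so a TPM of 10 maps to one log2 unit.
#'
#' @param x Genes x cells numeric matrix on the TPM scale, or a `glioma_sim`
#'   object from [sim_expression()] (its `$tpm` is used).
#' @return Matrix of normalized expression `E`, with attribute
#'   `centred = FALSE`.
#' @export
normalize_tpm <- function(x) {
  if (inherits(x, "glioma_sim")) x <- x$tpm
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (any(x < 0)) stop("TPM values must be non-negative")
  e <- log2(x / 10 + 1)
  attr(e, "centred") <- FALSE
  e
}

#' Centre each gene across all cells
#'
#' Subtracts the per-gene mean across cells, the centring step that precedes
#' principal component analysis.
#'
#' @param m Normalized genes x cells matrix.
#' @return Matrix with every gene-row mean 0 and attribute `centred = TRUE`.
#' @export
center_genes <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  out <- m - rowMeans(m)
  attr(out, "centred") <- TRUE
  out
}

#' Retain the genes with highest mean expression
#'
#' Keeps the `n` genes of highest mean expression across all cells (means
#' taken on the matrix as given, i.e. before centring), the gene-selection
#' step preceding dimensionality reduction. Ties at the cut-off are broken
#' lexicographically by gene id.
#'
#' @param m Normalized genes x cells matrix with rownames.
#' @param n Number of genes to keep (default 7000).
#' @return The filtered matrix, rows ordered by (mean desc, gene id asc).
#' @export
select_top_genes <- function(m, n = 7000L) {
  if (!is.matrix(m) || is.null(rownames(m))) {
    stop("`m` must be a matrix with gene rownames")
  }
  n <- assert_count(n, "n")
  if (n > nrow(m)) {
    warning(sprintf("n = %d exceeds the %d genes available; keeping all", n,
                    nrow(m)))
    n <- nrow(m)
  }
  means <- rowMeans(m)
  ord <- order(-means, rownames(m))
  out <- m[ord[seq_len(n)], , drop = FALSE]
  attr(out, "centred") <- attr(m, "centred")
  out
}

#' Principal-component embedding of cells
#'
#' Computes per-cell scores on the top principal components of a gene-centred
#' matrix and a 2-D embedding of those scores. The 2-D step is plumbing
#' delegated to a standard routine: UMAP (via uwot) by default, or the first
#' two PCs with `method = "pca"` (useful for very small inputs).
#'
#' @param m Centred genes x cells matrix (see [center_genes()]).
#' @param n_components Number of principal components (default 100, capped
#'   by data rank at validation: must not exceed `min(dim(m))`).
#' @param method 2-D embedding method, `"umap"` or `"pca"`.
#' @param seed Seed for the stochastic embedding.
#' @return A `glioma_embedding` list: `scores` (cells x components),
#'   `embedding` (cells x 2), `sdev`, `var_explained`.
#' @export
pca_embed <- function(m, n_components = 100L, method = c("umap", "pca"),
                      seed = 0L) {
  method <- match.arg(method)
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (!isTRUE(attr(m, "centred"))) {
    stop("`m` must be gene-centred; call center_genes() first")
  }
  n_components <- assert_count(n_components, "n_components")
  if (n_components > min(dim(m))) {
    stop(sprintf("n_components = %d exceeds min(genes, cells) = %d",
                 n_components, min(dim(m))))
  }
  pc <- stats::prcomp(t(m), center = FALSE, scale. = FALSE,
                      rank. = n_components)
  scores <- pc$x
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  emb <- if (method == "pca" || ncol(scores) < 2) {
    s <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
    if (ncol(s) < 2) s <- cbind(s, 0)
    s
  } else {
    nn <- max(2L, min(15L, nrow(scores) - 1L))
    with_seed(seed, uwot::umap(scores, n_neighbors = nn, n_threads = 1))
  }
  emb <- emb[, 1:2, drop = FALSE]
  dimnames(emb) <- list(rownames(scores), c("dim1", "dim2"))
  structure(
    list(scores = scores, embedding = emb, sdev = pc$sdev,
         var_explained = var_explained, loadings = pc$rotation),
    class = "glioma_embedding"
  )
}
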