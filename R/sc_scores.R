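#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene ids.
#' @return A `gene_signature` list.
#' @export
gene_signature <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("a gene signature must contain at least one gene")
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_signature")
}

# Equal-count expression bins over per-gene means; first-occurrence rank
# break makes bin assignment deterministic under tied means.
expression_bins <- function(means, n_bins) {
  r <- rank(means, ties.method = "first")
  as.integer(ceiling(r / length(means) * n_bins))
}

#' Signature module score with bin-matched control gene sets
#'
#' Scores each cell for a gene set as the mean normalized expression of the
#' signature genes minus the mean expression of control genes: all genes are
#' placed into `n_bins` equal-count bins of average expression across cells,
#' and each signature gene contributes `n_control` control genes drawn (with
#' replacement) from its own bin. This is the bin-matched control-set scheme
#' used for scoring GABAergic synapse signatures in glioma single cells.
#'
#' @param m Normalized genes x cells matrix with gene rownames (not centred;
#'   binning uses average expression levels).
#' @param signature A [gene_signature()] or character vector of gene ids.
#'   Signature genes absent from the matrix are dropped with a warning.
#' @param n_bins Number of expression bins (default 25); the matrix must
#'   contain at least `n_bins` genes.
#' @param n_control Control genes drawn per signature gene (default 100).
#' @param seed Integer seed making the control draw deterministic.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(m, signature, n_bins = 25L, n_control = 100L,
                         seed = 0L) {
  if (!is.matrix(m) || is.null(rownames(m))) {
    stop("`m` must be a matrix with gene rownames")
  }
  if (is.character(signature)) signature <- gene_signature("signature", signature)
  stopifnot(inherits(signature, "gene_signature"))
  n_bins <- assert_count(n_bins, "n_bins")
  n_control <- assert_count(n_control, "n_control")
  if (nrow(m) < n_bins) {
    stop(sprintf("matrix has %d genes but %d bins were requested", nrow(m),
                 n_bins))
  }
  present <- signature$genes %in% rownames(m)
  if (!all(present)) {
    warning(sprintf("dropping %d signature gene(s) absent from the matrix: %s",
                    sum(!present),
                    paste(signature$genes[!present], collapse = ", ")))
  }
  sig <- signature$genes[present]
  if (!length(sig)) {
    stop(sprintf("signature '%s' has no genes present in the matrix",
                 signature$name))
  }
  means <- rowMeans(m)
  bins <- expression_bins(means, n_bins)
  bin_members <- split(seq_len(nrow(m)), bins)
  sig_idx <- match(sig, rownames(m))
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(sig_idx, function(i) {
      members <- bin_members[[as.character(bins[i])]]
      members[sample.int(length(members), n_control, replace = TRUE)]
    }), use.names = FALSE)
  })
  sig_mean <- colMeans(m[sig_idx, , drop = FALSE])
  ctrl_mean <- colMeans(m[ctrl_idx, , drop = FALSE])
  score <- sig_mean - ctrl_mean
  names(score) <- colnames(m)
  score
}

#' Score cells for the three glioma lineage programs
#'
#' Runs [module_score()] for OPC-like, OC-like and AC-like signatures with
#' shared binning (same matrix, bins and control counts) and a deterministic
#' per-signature seed schedule (`seed`, `seed + 1`, `seed + 2`).
#'
#' @param m Normalized genes x cells matrix.
#' @param opc_sig,oc_sig,ac_sig [gene_signature()]s for the three lineages.
#' @param n_bins,n_control,seed Scoring parameters, see [module_score()].
#' @return A `score_table` data.frame with columns `cell_id`, `OPC_score`,
#'   `OC_score`, `AC_score`.
#' @export
lineage_scores <- function(m, opc_sig, oc_sig, ac_sig, n_bins = 25L,
                           n_control = 100L, seed = 0L) {
  out <- data.frame(
    cell_id = colnames(m),
    OPC_score = unname(module_score(m, opc_sig, n_bins, n_control, seed)),
    OC_score = unname(module_score(m, oc_sig, n_bins, n_control, seed + 1)),
    AC_score = unname(module_score(m, ac_sig, n_bins, n_control, seed + 2)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  out
}

#' Stemness and differentiation scores from lineage scores
#'
#' Implements the lineage-axis rules for malignant glioma cells:
#' * stemness = OPC score minus the higher of the OC and AC scores;
#' * differentiation = the maximum of the OC and AC scores, multiplied by -1
#'   when the AC score is the higher of the two;
#' * when both OC and AC scores are negative, differentiation is set to 0
#'   plus a small seeded uniform jitter on `[-jitter_sd, +jitter_sd]`.
#'
#' @param scores A `score_table` with `OPC_score`, `OC_score`, `AC_score`
#'   columns (see [lineage_scores()]).
#' @param jitter_sd Half-width of the uniform jitter for doubly-negative
#'   cells (default 0.01).
#' @param seed Integer seed for the jitter.
#' @return The input with `stemness_score` and `differentiation_score`
#'   columns added.
#' @export
stemness_differentiation <- function(scores, jitter_sd = 0.01, seed = 0L) {
  need <- c("OPC_score", "OC_score", "AC_score")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    stop("missing lineage score column(s): ", paste(missing, collapse = ", "))
  }
  assert_scalar_num(jitter_sd, "jitter_sd", 0)
  opc <- scores$OPC_score
  oc <- scores$OC_score
  ac <- scores$AC_score
  hi <- pmax(oc, ac)
  stemness <- opc - hi
  diff <- ifelse(ac > oc, -hi, hi)
  both_neg <- oc < 0 & ac < 0
  if (any(both_neg)) {
    jit <- with_seed(seed, stats::runif(sum(both_neg), -jitter_sd, jitter_sd))
    diff[both_neg] <- jit
  }
  scores$stemness_score <- stemness
  scores$differentiation_score <- diff
  scores
}

#' Order cells by a per-cell score
#'
#' Stable sort on score descending, used for the sorted left-to-right cell
#' display of signature expression.
#'
#' @param score Named numeric vector of per-cell scores.
#' @return Character vector of cell ids in display order.
#' @export
order_cells_by_score <- function(score) {
  if (is.null(names(score))) stop("`score` must be named by cell id")
  names(score)[order(-score, seq_along(score))]
}
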