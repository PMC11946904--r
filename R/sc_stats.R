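#' Pseudobulk per-sample means
#'
#' Aggregates single cells to one value per sample by arithmetic mean: the
#' per-sample average expression (for a genes x cells matrix) or average
#' score (for a per-cell vector) used before sample-level group comparisons.
#'
#' @param x Genes x cells numeric matrix, or a per-cell numeric vector.
#' @param samples Character/factor vector of sample labels, one per cell.
#' @return For matrix input, a genes x samples matrix; for vector input, a
#'   data.frame with columns `sample` and `mean`.
#' @export
pseudobulk_means <- function(x, samples) {
  samples <- as.character(samples)
  if (is.matrix(x)) {
    if (length(samples) != ncol(x)) {
      stop("`samples` must have one label per cell (matrix column)")
    }
    groups <- split(seq_along(samples), samples)
    out <- vapply(groups, function(idx) rowMeans(x[, idx, drop = FALSE]),
                  numeric(nrow(x)))
    if (nrow(x) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(x), names(groups)))
    out
  } else if (is.numeric(x)) {
    if (length(samples) != length(x)) {
      stop("`samples` must have one label per cell")
    }
    means <- tapply(x, samples, mean)
    data.frame(sample = names(means), mean = as.numeric(means),
               stringsAsFactors = FALSE)
  } else {
    stop("`x` must be a numeric matrix or vector")
  }
}

# Exact two-group rank-sum permutation distribution over the pooled midranks.
# Enumerates all choose(n, n_a) assignments; correct under ties because the
# observed midranks themselves are permuted.
ranksum_enumeration_p <- function(ranks, n_a, w_obs,
                                  alternative = "two.sided") {
  combs <- utils::combn(length(ranks), n_a)
  sums <- colSums(matrix(ranks[combs], nrow = n_a))
  eps <- 1e-9
  switch(alternative,
    two.sided = {
      mu <- n_a * mean(ranks)
      mean(abs(sums - mu) >= abs(w_obs - mu) - eps)
    },
    greater = mean(sums >= w_obs - eps),
    less = mean(sums <= w_obs + eps)
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midranks for ties. For small samples
#' (`n_a + n_b <= exact_max_n`) the p-value is exact, computed by complete
#' enumeration of the rank-sum permutation distribution over the pooled
#' midranks; otherwise a normal approximation with tie correction and
#' continuity correction is used. The reported statistic is the rank sum of
#' the first group.
#'
#' @param a,b Numeric vectors of observations; both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (location of `a` relative to `b`).
#' @param exact_max_n Largest combined sample size for the exact enumeration
#'   path (default 12).
#' @return A list with `statistic` (rank sum of `a`), `p.value`, and
#'   `method` (`"exact enumeration"` or `"normal approximation"`).
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two.sided", "greater",
                                                    "less"),
                              exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  n_a <- length(a)
  n_b <- length(b)
  n <- n_a + n_b
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(n_a)])
  if (n <= exact_max_n) {
    p <- ranksum_enumeration_p(ranks, n_a, w, alternative)
    method <- "exact enumeration"
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z_of <- function(dev) dev / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm(z_of(abs(w - mu) - 0.5),
                                     lower.tail = FALSE),
        greater = stats::pnorm(z_of(w - mu - 0.5), lower.tail = FALSE),
        less = stats::pnorm(z_of(w - mu + 0.5))
      )
      p <- min(1, max(0, p))
    }
    method <- "normal approximation"
  }
  list(statistic = w, p.value = p, method = method)
}
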