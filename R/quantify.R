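#' Pooled proliferation (or labelling) index
#'
#' Total positive cells divided by total cells counted across all fields --
#' the pooled ratio, not the mean of per-field ratios. This matches how
#' Ki67+/HNA+ and EdU+/DAPI+ proliferation indices are computed across
#' quantified areas.
#'
#' @param table Data.frame with columns `total` and `positive` (non-negative
#'   integers, `positive <= total` per field).
#' @return Pooled index in `[0, 1]`.
#' @export
pooled_index <- function(table) {
  if (!all(c("total", "positive") %in% names(table))) {
    stop("`table` needs columns total and positive")
  }
  tot <- table$total
  pos <- table$positive
  if (any(tot < 0) || any(pos < 0) || any(pos > tot) ||
      any(tot != round(tot)) || any(pos != round(pos))) {
    stop("counts must be non-negative integers with positive <= total")
  }
  if (sum(tot) == 0) stop("total cell count is zero; index undefined")
  sum(pos) / sum(tot)
}

#' Fraction of puncta with a partner within a search radius
#'
#' For each channel-A punctum (e.g. postsynaptic gephyrin), checks whether
#' any channel-B punctum (e.g. presynaptic VGAT) lies within `radius_um`
#' (3-D Euclidean); each A punctum is counted once. The fraction is of the
#' first argument's puncta, so the operation is intentionally asymmetric.
#'
#' @param a,b Matrices or data.frames of 3-D centroid coordinates (um),
#'   columns x, y, z. `a` must be non-empty.
#' @param radius_um Search radius (um), positive.
#' @return Fraction of `a` puncta with at least one `b` punctum in range.
#' @export
colocalization_fraction <- function(a, b, radius_um) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) == 0) stop("channel-A puncta set is empty; fraction undefined")
  if (ncol(a) != 3 || (nrow(b) > 0 && ncol(b) != 3)) {
    stop("puncta must have 3 coordinate columns")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("puncta coordinates must be finite")
  }
  assert_scalar_num(radius_um, "radius_um", 0, strict_lower = TRUE)
  if (nrow(b) == 0) return(0)
  r2 <- radius_um^2
  tb <- t(b)
  hits <- vapply(seq_len(nrow(a)), function(i) {
    min(colSums((tb - a[i, ])^2)) <= r2
  }, logical(1))
  mean(hits)
}

#' Optical-fractionator population estimate
#'
#' Unbiased stereological estimate of a total cell number from systematic
#' section sampling: `N_hat = sum(Q) / (ssf * asf)`, where `sum(Q)` is the
#' total number of cells counted in the dissector frames, `ssf` the section
#' sampling fraction (e.g. 1/6 for a 1-in-6 series) and `asf` the area
#' sampling fraction (counting-frame area over sampling-grid area, e.g.
#' (100 x 100) / (250 x 250) = 0.16).
#'
#' @param q Integer vector of cells counted per sampled section.
#' @param ssf Section sampling fraction in `(0, 1]`.
#' @param asf Area sampling fraction in `(0, 1]`.
#' @return Estimated total number of cells.
#' @export
fractionator_estimate <- function(q, ssf, asf) {
  if (any(q < 0) || any(q != round(q))) {
    stop("per-section counts must be non-negative integers")
  }
  assert_scalar_num(ssf, "ssf", 0, 1, strict_lower = TRUE)
  assert_scalar_num(asf, "asf", 0, 1, strict_lower = TRUE)
  sum(q) / (ssf * asf)
}

#' Gundersen (m = 1) coefficient of error for systematic section counts
#'
#' Smoothness-class m = 1 estimator: with `A = sum(q_i^2)`,
#' `B = sum(q_i q_(i+1))`, `C = sum(q_i q_(i+2))`, the systematic-sampling
#' variance is `(3 (A - sum(Q)) - 4 B + C) / 240` and
#' `CE = sqrt(sum(Q) + Var_SRS) / sum(Q)`, combining a Poisson counting-noise
#' term with the between-section trend term. A stereological sampling design
#' is conventionally accepted when this CE is below 0.1.
#'
#' @param q Integer vector of cells counted per section, in serial order; at
#'   least 3 sections.
#' @param m Smoothness class; only the m = 1 estimator is provided.
#' @return The coefficient of error (dimensionless).
#' @export
gundersen_ce <- function(q, m = 1) {
  if (m != 1) stop("only the m = 1 estimator is implemented")
  if (length(q) < 3) stop("at least 3 sections are required")
  if (any(q < 0) || any(q != round(q))) {
    stop("per-section counts must be non-negative integers")
  }
  n <- length(q)
  total <- sum(q)
  if (total == 0) stop("no cells counted; CE undefined")
  A <- sum(q^2)
  B <- sum(q[-n] * q[-1])
  C <- sum(q[seq_len(n - 2)] * q[-(1:2)])
  var_srs <- (3 * (A - total) - 4 * B + C) / 240
  sqrt(total + var_srs) / total
}

#' Tumour-burden fold change from bioluminescence flux
#'
#' Normalizes each animal's follow-up total flux to its own baseline.
#'
#' @param series Data.frame with columns `baseline` and `followup`
#'   (photons/s); baselines must be positive. An optional `animal` column is
#'   carried through.
#' @return The input data.frame with a `fold_change` column added.
#' @export
burden_fold_change <- function(series) {
  if (!all(c("baseline", "followup") %in% names(series))) {
    stop("`series` needs columns baseline and followup")
  }
  if (any(series$baseline <= 0)) stop("baseline flux must be positive")
  series$fold_change <- series$followup / series$baseline
  series
}
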