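---
title: "Methods: quantifying GABAergic neuron-to-glioma signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GABAergic neuron-to-glioma signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabaglioma)
```

# Scope

H3K27M-altered diffuse midline glioma (DMG) cells receive depolarizing
GABAergic synaptic input from interneurons. Establishing that claim
quantitatively requires four largely independent analyses, all implemented
here: (1) scoring GABAergic synapse gene signatures in single-cell RNA-seq
of malignant cells, with lineage (OPC-like / OC-like / AC-like) and
stemness scores; (2) inferring intracellular chloride from GABA~A~
current–voltage relations via the Nernst equation; (3) measuring evoked
postsynaptic current (PSC) kinetics — amplitude, 10–90% rise time,
monoexponential decay constant, synaptic latency; and (4) microscopy count
statistics — pooled proliferation indices, 3-D gephyrin/VGAT puncta
colocalization, optical-fractionator stereology with the Gundersen
coefficient of error, and bioluminescence fold change. Every analysis has a
matching seeded synthetic generator, so the full pipeline is exercised and
validated without any external download.

# Single-cell signature scoring

## Normalization and gene selection

TPM values are transformed as $E = \log_2(\mathrm{TPM}/10 + 1)$; the
division by 10 reflects an assumed true library complexity near 100,000
transcripts rather than the nominal one million of the TPM unit. Before
dimensionality reduction, genes are ranked by mean $E$ across all cells and
the top 7,000 retained (`select_top_genes()`, ties broken lexicographically
so the selection is deterministic), then each gene is centred to mean zero
(`center_genes()`). Per-cell scores on the top 100 principal components
feed a 2-D embedding; the embedding itself is plumbing delegated to UMAP
(uwot), with a pure-PCA fallback for tiny inputs.

## Module scores with bin-matched controls

`module_score()` scores a gene set per cell as

$$s_c = \frac{1}{|G|}\sum_{g \in G} E_{gc}
      \;-\; \frac{1}{|G| \cdot k}\sum_{g \in G}\sum_{j=1}^{k} E_{r_j(g),c},$$

where each signature gene $g$ contributes $k = 100$ control genes
$r_j(g)$ drawn with replacement from the expression bin of $g$: all genes
are placed into 25 bins of average expression across cells. Two details are
deliberate conventions, since the scheme is not fully pinned down by its
usual one-sentence description:

* **Binning is equal-count (quantile) rather than equal-width.** Gene mean
  expression is heavily right-skewed; equal-width bins would leave most
  bins nearly empty and the top bin enormous, making "bin-matched" controls
  meaningless for highly expressed genes.
* **Controls are drawn per signature gene, with replacement, and pooled.**
  This is the most direct reading of "100 randomly chosen control gene
  sets"; with replacement keeps the draw well-defined for small bins.

Two consequences are worth knowing. On a degenerate matrix where every gene
has the same value within each cell, controls equal the signature exactly
and the score is identically zero (this is asserted in the tests). And
because controls are matched on *overall* mean expression, an enrichment
applied uniformly to every cell is absorbed into the binning — module
scores are relative across the cells of the matrix, so population contrasts
require the populations to share one matrix.

## Lineage, stemness, and differentiation

`lineage_scores()` applies `module_score()` to OPC-like, OC-like and
AC-like signatures with a shared binning and a fixed per-signature seed
schedule. The OPC/OC/AC gene sets themselves are user inputs (the published
lineage signatures are external); the tests use synthetic stand-ins whose
enrichment is injected by the generator. From the three scores,
`stemness_differentiation()` applies the rules:

* stemness $= \mathrm{OPC} - \max(\mathrm{OC}, \mathrm{AC})$;
* differentiation $= \max(\mathrm{OC}, \mathrm{AC})$, multiplied by $-1$
  when AC exceeds OC (so astrocytic differentiation is plotted negative);
* when OC and AC are both negative the cell is considered undifferentiated
  and differentiation is set to $0$ plus uniform jitter on
  $[-0.01, +0.01]$ (seeded). The jitter magnitude is unspecified in the
  source description ("some added jitter"); 0.01 is small relative to
  typical score spreads and exists only to avoid overplotting at zero.

## Pseudobulk comparison

Group comparisons are run at the sample level: `pseudobulk_means()`
averages cells per sample, and `wilcoxon_rank_sum()` compares groups. The
test uses midranks for ties; for combined samples of at most 12 the p-value
is exact, by complete enumeration of the rank-sum permutation distribution
over the pooled midranks (this enumeration is also exact under ties, which
is why identical groups give exactly $p = 1$); larger samples use the
normal approximation with tie and continuity corrections. The exact path is
validated against the closed-form Mann–Whitney distribution on every
untied split of small vectors, the approximate path against the exact
p-value at $n = 10$ vs $10$.

# Electrophysiology and chloride inference

## Solutions and the Nernst equation

`free_chloride()` sums concentration × chloride stoichiometry over fully
dissociating salts (NaCl/KCl/CsCl → 1; MgCl~2~/CaCl~2~ → 2; buffers,
sugars, nucleotides → 0). The packaged recording ACSF gives
$125 + 2.5 + 2 \times 1 + 2 \times 2 = 133.5$ mM. Concentrations, not
activities, enter the Nernst relation — consistent with how the reported
chloride values are derived. For chloride ($z = -1$):

$$E_{\mathrm{GABA}} = \frac{RT}{F}\,
  \ln\!\frac{[\mathrm{Cl}^-]_{in}}{[\mathrm{Cl}^-]_{out}}, \qquad
  [\mathrm{Cl}^-]_{in} = [\mathrm{Cl}^-]_{out}\,
  e^{E_{\mathrm{GABA}} F / RT}.$$

The two functions are exact inverses (tested to $10^{-9}$). The default
bath temperature is 29 °C, the midpoint of the stated 28–30 °C recording
range; across that range the chloride inferred from $E = -25$ mV moves by
less than 0.3 mM, so the choice is immaterial at the reported precision.
`reversal_from_iv()` fits ordinary least squares $I = mV + b$ and returns
the x-intercept $-b/m$ (with an explicit error when the slope is
indistinguishable from zero); `estimate_chloride_per_cell()` composes
regression → Nernst per cell and then averages across cells (mean ±
s.e.m.), rather than pooling all points into one regression. An optional
additive offset on the fitted reversal potentials is exposed for junction
potential corrections and defaults to 0, since no correction is assumed.

## Synthetic PSC and kinetics estimators

`sim_evoked_trace()` builds baseline + Gaussian noise plus a
difference-of-exponentials kernel
$s(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$ starting at
stimulus onset + stimulus duration + latency, scaled so the signed
noiseless peak equals the requested amplitude. Defaults are the study
conditions: 10 kHz sampling, 0.5 ms stimulus, latency 4.8 ms, decay
constant 106.6 ms, amplitude −100 pA, and $\tau_r$ solved numerically
(`rise_tau_for_rise_time()`) so the analytic 10–90% rise time of the
noiseless kernel equals 18.5 ms. The generator refuses windows shorter
than five decay constants after onset, where a decay fit would be
ill-posed.

Estimator choices, and their known biases:

* **Rise time** (`rise_time_10_90()`): first crossings of 10% and 90% of
  the peak deflection with linear interpolation. A 1-ms centred boxcar is
  applied before measurement (configurable, `smooth_ms = 0` disables it):
  kinetics are conventionally measured on averaged responses, and on a
  single noisy sweep the raw peak is inflated by noise, which distorts both
  thresholds. The boxcar's own bias on a noiseless kernel is under 0.01 ms.
* **Decay** (`fit_monoexp_decay()`): nonlinear least squares of
  $A e^{-t/\tau}$ from the peak to the window end (Levenberg–Marquardt,
  log-linear initialization). Because the rise exponential has not fully
  decayed at the peak, fitting from the peak overestimates $\tau$ slightly
  (about 5% at the default kinetics, noiselessly); this is inherent to the
  standard fit-from-peak convention and is well inside the 10% recovery
  tolerance used in validation. Degenerate inputs (pure noise, tiny fitted
  amplitude, $\tau$ outside $(0, 10\times\text{window}]$) raise errors
  rather than returning numbers.
* **Latency** (`synaptic_latency()`): from the end of the stimulus to
  response onset. "Visually discernible beginning" is operationalized as a
  3×baseline-SD deflection sustained for 5 consecutive samples, after which
  the onset is refined by backtracking to the last sample at or below
  baseline. The backtrack removes most of the threshold-height bias (a
  plain sustained-crossing detector is ~30% late at 5% noise) but a
  residual ~0.5 ms late bias remains at that noise level; on noiseless
  traces the procedure reduces exactly to the first deviating sample.

# Count statistics

* `pooled_index()` divides summed positives by summed totals across fields
  — the pooled ratio, which is invariant to how fields partition the same
  counts and differs from the mean of per-field ratios on unbalanced
  fields.
* `colocalization_fraction()` reports the fraction of channel-A puncta
  with at least one channel-B punctum within a 3-D Euclidean radius. The
  original colocalization criterion (a commercial 3-D rendering package's)
  is not published; distance thresholding with an explicit radius is used
  instead, with 1 µm as the working value in validation. The fraction is
  of the first argument's puncta, so the measure is intentionally
  asymmetric. The implementation is exact (all-pairs); the synthetic
  generator constructs exactly $\mathrm{round}(n f)$ colocalized pairs
  within 0.5 µm and rejects non-colocalized placements closer than 2 µm to
  any partner, so a search radius between those bounds recovers $f$
  exactly.
* `fractionator_estimate()` is the optical fractionator
  $\hat N = \Sigma Q \cdot (1/\mathrm{ssf}) \cdot (1/\mathrm{asf})$; with
  the 1-in-6 section series and the 100×100 µm frame on a 250×250 µm grid,
  $\mathrm{ssf} = 1/6$ and $\mathrm{asf} = 0.16$. Monte-Carlo simulation of
  systematic sampling from synthetic point fields confirms unbiasedness
  within 2%.
* `gundersen_ce()` implements the smoothness-class $m = 1$ estimator with
  the $1/240$ coefficient and a Poisson noise term:
  $\mathrm{Var} = (3(A - \Sigma Q) - 4B + C)/240$,
  $\mathrm{CE} = \sqrt{\Sigma Q + \mathrm{Var}}/\Sigma Q$, where
  $A = \sum q_i^2$, $B = \sum q_i q_{i+1}$, $C = \sum q_i q_{i+2}$. Only
  the name of the estimator is given in typical methods sections; this is
  the standard published form of it.
* `burden_fold_change()` normalizes each animal's follow-up flux to its
  own baseline.

# Synthetic data: what it emulates, and what it does not

The expression generator reproduces the *statistical structure* the scoring
pipeline assumes — TPM columns summing to exactly $10^6$ (log-normal gene
means, per-cell log-normal biological noise, multinomial resampling of one
million transcripts), subpopulations with lineage identities, a designated
gene set multiplicatively enriched in chosen populations before dropout and
renormalization, and Bernoulli dropout (default rate 0.3). It does not
attempt amplification artefacts, batch effects, doublets, or realistic
gene–gene correlation; passing tests demonstrate that the *operations* are
correct and calibrated, not that real tumour data will show any particular
effect size. Default population sizes are desk-scale (a few hundred cells)
rather than the thousands in the real datasets; all Monte-Carlo test sizes
(100 seeds for the null-score calibration, 500 for count and fractionator
calibration, 1,000 for reversal-potential recovery) were chosen so each
suite runs in seconds while leaving standard errors well under the asserted
tolerances.

Trace, I–V, puncta and count generators carry their ground truth with the
data, so every estimator is validated as parameter recovery. Noise is
additive Gaussian everywhere — the simplest model sufficient for recovery
testing — and colocalized puncta counts are constructed exactly rather than
sampled, so fraction recovery is exact rather than approximate.

# Reproducibility and interfaces

Every stochastic function takes an integer seed and restores the caller's
RNG state, so identical inputs and seeds give bit-identical outputs.
`run_pipeline()` chains simulate → normalize → score → pseudobulk →
compare, writing CSV/JSON plus a manifest with md5 checksums;
`verify_manifest()` detects any post-hoc modification. Expression matrices
travel as Matrix Market + TSV sidecars or dense TSV, signatures as
one-gene-per-line text or GMT, solutions as YAML, traces and I–V series as
CSV with JSON metadata. The exported functions are the package's interface;
`scripts/acceptance.R` is the runnable entry point that regenerates the
headline parameter-recovery numbers.

# Known limitations

* Lineage gene sets are not bundled; results depend on the signatures
  supplied.
* The latency estimator retains a small late bias at high noise (see
  above); with averaged sweeps (lower effective noise) the bias shrinks
  accordingly.
* The Wilcoxon exact path enumerates $\binom{n}{n_a}$ splits and is
  restricted to $n \le 12$ by default.
* No junction-potential or series-resistance corrections are applied to
  recorded potentials; no multi-ion (GHK) modelling — the chloride
  inference assumes a pure chloride conductance.
* Colocalization uses centroid distance, not surface contact; the radius
  must be stated with any reported fraction.
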