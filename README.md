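# gabaglioma

Quantitative analytics for GABAergic neuron-to-glioma signalling in
H3K27M-altered diffuse midline glioma (DMG).

DMG cells, like the oligodendrocyte precursor cells they resemble, receive
depolarizing GABAergic synaptic input: their intracellular chloride is high,
so GABA_A receptor opening depolarizes rather than inhibits them. Testing
that claim rests on four kinds of desk-side quantification, and this package
implements all of them for analysts working with single-cell expression
matrices, patch-clamp recordings, and microscopy count tables:

1. **Single-cell signature scoring** — TPM normalization
   `E = log2(TPM/10 + 1)`, top-mean gene selection, PCA/UMAP embedding
   inputs, and module scores computed as the mean signature expression
   minus the mean of 100 control genes drawn per signature gene from 25
   expression bins. Lineage (OPC/OC/AC), stemness
   (`OPC − max(OC, AC)`) and signed differentiation scores; pseudobulk
   per-sample means and a Wilcoxon rank-sum test (exact by enumeration for
   small samples, tie-corrected normal approximation otherwise).
2. **Chloride inference from electrophysiology** — solution chloride
   accounting (the standard recording ACSF works out to 133.5 mM free
   Cl⁻), OLS x-intercept of the GABA current–voltage relation
   (`E_GABA = −b/m`), and the Nernst equation
   `Cl_in = Cl_out · exp(E·F/RT)` for chloride (z = −1), composed per cell
   and averaged.
3. **Evoked PSC kinetics** — signed peak amplitude, 10–90% rise time with
   linear interpolation, monoexponential decay constant by
   Levenberg–Marquardt fit from the peak, and synaptic latency from
   stimulus end to a sustained 3-SD onset with baseline backtracking.
4. **Microscopy count statistics** — pooled proliferation indices
   (Σpositive/Σtotal), 3-D puncta colocalization fractions
   (gephyrin/VGAT-style), the optical fractionator
   `N̂ = ΣQ/(ssf·asf)` with the Gundersen m = 1 coefficient of error, and
   bioluminescence fold change.

Each stage has a seeded synthetic generator (`sim_expression()`,
`sim_evoked_trace()`, `sim_iv_series()`, `sim_puncta_field()`,
`sim_count_fields()`) that emits ground truth alongside the data, so every
estimator is validated by parameter recovery without downloading anything.
Packaged fixtures include the GABA_A receptor subunit gene lists (6 α, 3 β,
3 γ, 19 total receptor, 24 total synapse-related genes) and the recording
ACSF / pipette solution recipes.

## Worked example

```r
library(gabaglioma)

## chloride inference from a synthetic current-voltage series
sols <- load_fixture_solutions()
free_chloride(sols$acsf)
#> [1] 133.5
iv <- sim_iv_series(iv_sim_params(e_rev_true_mV = -25, conductance_nS = 1.2,
                                  noise_sd_pA = 4, seed = 42))
fit <- reversal_from_iv(iv)
fit$e_rev_mV                                  # x-intercept of the I-V line
#> [1] -26.3
nernst_concentration(fit$e_rev_mV, 133.5, 29) # intracellular chloride, mM
#> [1] 48.6
```

A fitted reversal potential of −26.3 mV (true value −25 mV, recovered from
six noisy holding potentials, r² = 0.997) maps to ~49 mM intracellular
chloride — far above the ~5–10 mM of mature neurons, which is what makes
GABA depolarizing in these cells.

```r
## kinetics of a synthetic evoked PSC (truth: rise 18.5, decay 106.6,
## latency 4.8 ms; noise 5% of the 100 pA peak)
tr <- sim_evoked_trace(trace_sim_params(noise_sd_pA = 5, seed = 42))
unlist(kinetics_summary(tr)[c("amplitude_pA", "rise_time_ms",
                              "decay_tau_ms", "latency_ms")])
#> amplitude_pA rise_time_ms decay_tau_ms   latency_ms
#>       -115.0         18.2        109.8          5.4

## signature scoring on a simulated two-population tumour
sigs <- load_fixture_signatures()
sim <- sim_expression(expr_sim_config(
  n_genes = 2000,
  populations = list(
    list(name = "OPC-like", n_cells = 120, lineage = "OPC-like"),
    list(name = "AC-like",  n_cells = 80,  lineage = "AC-like")),
  signature_genes = sigs$synapse_total$genes,
  signature_effect = c("OPC-like" = 3), seed = 1))
e <- normalize_tpm(sim$tpm)
score <- module_score(e, sigs$synapse_total, n_bins = 25, n_control = 100,
                      seed = 1)
pseudobulk_means(score, sim$cells$sample)
#>     sample   mean
#> 1  AC-like -0.736
#> 2 OPC-like  0.422
wilcoxon_rank_sum(score[sim$cells$population == "OPC-like"],
                  score[sim$cells$population == "AC-like"])$p.value
#> [1] 2.96e-23
```

The OPC-like population, simulated with a 3× enrichment of the 24-gene
GABAergic synapse signature, scores ~1.2 bin-matched log2 units above the
unenriched AC-like population, and the difference is overwhelming at the
single-cell level (per-sample pseudobulk means are what one would feed a
sample-level comparison).

`run_pipeline()` chains simulate → normalize → score → pseudobulk →
compare and writes CSVs, JSON and a checksummed manifest
(`verify_manifest()` audits a finished run).

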