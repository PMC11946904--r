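# Shared fixture builders for the test suite.

# Null TPM matrix: one population, no designated enrichment.
null_sim <- function(n_genes = 500L, n_cells = 60L, seed = 1L,
                     dropout_rate = 0.3) {
  sim_expression(expr_sim_config(
    n_genes = n_genes,
    populations = list(list(name = "P1", n_cells = n_cells,
                            lineage = "OPC-like")),
    dropout_rate = dropout_rate,
    seed = seed
  ))
}

# Sweep trace holding a pure monoexponential decay starting at the stimulus
# end (step onset): the textbook case for the decay fitter.
pure_exponential_trace <- function(tau_ms = 100, amplitude_pA = -100,
                                   baseline_pA = 0, noise_sd = 0,
                                   duration_ms = 600, dt_ms = 0.1,
                                   seed = 1L) {
  t <- seq(0, duration_ms, by = dt_ms)
  onset <- 55
  cur <- rep(baseline_pA, length(t))
  after <- t >= onset
  cur[after] <- baseline_pA + amplitude_pA * exp(-(t[after] - onset) / tau_ms)
  if (noise_sd > 0) {
    set.seed(seed)
    cur <- cur + rnorm(length(t), 0, noise_sd)
  }
  sweep_trace(t, cur, stim_onset_ms = 50, stim_duration_ms = 5,
              baseline_window = c(0, 50))
}

# Exact Mann-Whitney two-sided p for untied data, via the base-R exact
# distribution -- an oracle independent of the package's enumeration.
oracle_exact_p <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  u <- sum(rank(c(a, b))[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  lo <- stats::pwilcox(min(u, 2 * mu - u), n_a, n_b)
  min(1, 2 * lo)
}
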