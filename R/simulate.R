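#' Configuration for the synthetic single-cell expression generator
#'
#' Describes a synthetic glioma single-cell experiment: a gene universe, a set
#' of malignant subpopulations (OPC-like / AC-like / OC-like lineages, the
#' compartments described for H3K27M+ diffuse midline glioma), and an optional
#' designated gene set whose mean expression is multiplicatively enriched in
#' chosen populations. TPM columns are produced by per-cell multinomial
#' resampling so every cell sums to exactly 1e6 before dropout.
#'
#' @param n_genes Number of genes in the universe (must cover
#'   `signature_genes`).
#' @param populations List of populations, each a list with `name`, `n_cells`
#'   and `lineage` (one of `"OPC-like"`, `"AC-like"`, `"OC-like"`).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters (natural
#'   log) of the per-gene baseline mean TPM.
#' @param signature_genes Character vector of gene ids forming the designated
#'   enriched set; these are inserted into the gene universe. `NULL` for none.
#' @param signature_effect Named numeric vector of multiplicative enrichment
#'   factors, one entry per population name; unnamed populations default to 1
#'   (no effect).
#' @param dropout_rate Probability that an individual TPM entry is zeroed
#'   before final renormalization, in `[0, 1)`.
#' @param cell_noise_sd Log-normal SD of per-cell, per-gene biological noise
#'   multiplying the gene mean.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 2000L,
                            populations = list(
                              list(name = "OPC-like", n_cells = 120L, lineage = "OPC-like"),
                              list(name = "AC-like", n_cells = 60L, lineage = "AC-like"),
                              list(name = "OC-like", n_cells = 20L, lineage = "OC-like")
                            ),
                            baseline_log_mean = 1,
                            baseline_log_sd = 1,
                            signature_genes = NULL,
                            signature_effect = NULL,
                            dropout_rate = 0.3,
                            cell_noise_sd = 0.4,
                            seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  if (!length(populations)) stop("at least one population is required")
  lineages <- c("OPC-like", "AC-like", "OC-like")
  pop_names <- vapply(populations, function(p) p$name, character(1))
  if (anyDuplicated(pop_names)) stop("population names must be unique")
  for (p in populations) {
    assert_count(p$n_cells, paste0("n_cells[", p$name, "]"))
    if (!p$lineage %in% lineages) {
      stop(sprintf("lineage '%s' must be one of %s", p$lineage,
                   paste(lineages, collapse = ", ")))
    }
  }
  if (!is.null(signature_genes)) {
    signature_genes <- as.character(signature_genes)
    if (anyDuplicated(signature_genes)) stop("signature_genes must be unique")
    if (length(signature_genes) > n_genes) {
      stop("designated gene set is larger than the gene universe (n_genes)")
    }
  }
  effect <- stats::setNames(rep(1, length(pop_names)), pop_names)
  if (!is.null(signature_effect)) {
    if (is.null(names(signature_effect)) ||
        !all(names(signature_effect) %in% pop_names)) {
      stop("signature_effect names must match population names")
    }
    if (any(signature_effect < 0)) stop("signature_effect must be >= 0")
    effect[names(signature_effect)] <- signature_effect
  }
  assert_scalar_num(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  if (dropout_rate >= 1) stop("dropout_rate must be < 1")
  assert_scalar_num(cell_noise_sd, "cell_noise_sd", lower = 0)
  structure(
    list(
      n_genes = n_genes, populations = populations,
      baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
      signature_genes = signature_genes, signature_effect = effect,
      dropout_rate = dropout_rate, cell_noise_sd = cell_noise_sd,
      seed = as.integer(seed)
    ),
    class = "expr_sim_config"
  )
}

#' Simulate a TPM-scale single-cell expression matrix with known structure
#'
#' Draws per-gene baseline means from a log-normal distribution, multiplies
#' the designated gene set by each population's enrichment factor, adds
#' per-cell log-normal biological noise, resamples each cell's transcriptome
#' as a multinomial of size 1e6 (exact TPM semantics), applies dropout, and
#' rescales every surviving column back to 1e6. Ground-truth population
#' labels and effects travel with the matrix so downstream recovery error is
#' computable.
#'
#' @param config An [expr_sim_config()].
#' @return A `glioma_sim` list with elements `tpm` (genes x cells matrix,
#'   columns summing to 1e6), `cells` (data.frame of `cell_id`, `population`,
#'   `lineage`, `sample`, `tumour_type`, `malignant`), and `truth` (the
#'   config plus the realized gene means).
#' @export
sim_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  with_seed(config$seed, {
    n_sig <- length(config$signature_genes)
    filler <- sprintf("G%05d", seq_len(config$n_genes - n_sig))
    gene_ids <- c(config$signature_genes, filler)
    base_mean <- stats::rlnorm(config$n_genes, config$baseline_log_mean,
                               config$baseline_log_sd)
    names(base_mean) <- gene_ids
    sig_idx <- seq_len(n_sig)

    cols <- list()
    ann <- list()
    for (p in config$populations) {
      eff <- config$signature_effect[[p$name]]
      mu <- base_mean
      if (n_sig) mu[sig_idx] <- mu[sig_idx] * eff
      mat <- matrix(0, nrow = config$n_genes, ncol = p$n_cells)
      for (j in seq_len(p$n_cells)) {
        lambda <- mu * stats::rlnorm(config$n_genes, 0, config$cell_noise_sd)
        counts <- as.numeric(stats::rmultinom(1, 1e6, lambda))
        if (config$dropout_rate > 0) {
          counts[stats::runif(config$n_genes) < config$dropout_rate] <- 0
        }
        s <- sum(counts)
        if (s == 0) stop("dropout removed an entire cell; lower dropout_rate")
        mat[, j] <- counts / s * 1e6
      }
      cols[[p$name]] <- mat
      ann[[p$name]] <- data.frame(
        population = rep(p$name, p$n_cells),
        lineage = rep(p$lineage, p$n_cells),
        stringsAsFactors = FALSE
      )
    }
    tpm <- do.call(cbind, cols)
    cells <- do.call(rbind, ann)
    rownames(cells) <- NULL
    cells$cell_id <- sprintf("C%05d", seq_len(nrow(cells)))
    cells$sample <- cells$population
    cells$tumour_type <- "synthetic"
    cells$malignant <- TRUE
    cells <- cells[c("cell_id", "population", "lineage", "sample",
                     "tumour_type", "malignant")]
    dimnames(tpm) <- list(gene_ids, cells$cell_id)
    structure(
      list(tpm = tpm, cells = cells,
           truth = list(config = config, gene_means = base_mean)),
      class = "glioma_sim"
    )
  })
}

#' Parameters for the synthetic evoked postsynaptic current generator
#'
#' Defaults mirror a GABAergic postsynaptic current in an H3K27M+ DMG cell:
#' 10 kHz sampling, a 0.5 ms electrical stimulus, 4.8 ms synaptic latency, a
#' 106.6 ms monoexponential decay constant, and a rise time constant solved
#' so the noiseless 10-90% rise time equals 18.5 ms. Inward currents are
#' negative.
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param duration_ms Total sweep length (ms); must leave at least five decay
#'   constants after response onset.
#' @param stim_onset_ms,stim_duration_ms Stimulus timing (ms).
#' @param latency_ms True synaptic latency from stimulus end to response
#'   onset (ms).
#' @param rise_tau_ms,decay_tau_ms Time constants of the
#'   difference-of-exponentials kernel (ms); `decay_tau_ms > rise_tau_ms > 0`.
#' @param amplitude_pA Signed true peak amplitude relative to baseline (pA).
#' @param baseline_pA Holding-current baseline (pA).
#' @param noise_sd_pA SD of additive Gaussian noise (pA).
#' @param holding_mV Holding potential recorded in metadata (mV).
#' @param seed Integer seed.
#' @return A `trace_sim_params` list.
#' @export
trace_sim_params <- function(sampling_rate_hz = 10000,
                             duration_ms = 700,
                             stim_onset_ms = 50,
                             stim_duration_ms = 0.5,
                             latency_ms = 4.8,
                             rise_tau_ms = NULL,
                             decay_tau_ms = 106.6,
                             amplitude_pA = -100,
                             baseline_pA = 0,
                             noise_sd_pA = 0,
                             holding_mV = -70,
                             seed = 1L) {
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", 0, strict_lower = TRUE)
  assert_scalar_num(stim_duration_ms, "stim_duration_ms", 0, strict_lower = TRUE)
  assert_scalar_num(decay_tau_ms, "decay_tau_ms", 0, strict_lower = TRUE)
  assert_scalar_num(latency_ms, "latency_ms", 0)
  assert_scalar_num(noise_sd_pA, "noise_sd_pA", 0)
  if (is.null(rise_tau_ms)) {
    rise_tau_ms <- rise_tau_for_rise_time(18.5, decay_tau_ms)
  }
  assert_scalar_num(rise_tau_ms, "rise_tau_ms", 0, strict_lower = TRUE)
  if (decay_tau_ms <= rise_tau_ms) stop("decay_tau_ms must exceed rise_tau_ms")
  structure(
    list(sampling_rate_hz = sampling_rate_hz, duration_ms = duration_ms,
         stim_onset_ms = stim_onset_ms, stim_duration_ms = stim_duration_ms,
         latency_ms = latency_ms, rise_tau_ms = rise_tau_ms,
         decay_tau_ms = decay_tau_ms, amplitude_pA = amplitude_pA,
         baseline_pA = baseline_pA, noise_sd_pA = noise_sd_pA,
         holding_mV = holding_mV, seed = as.integer(seed)),
    class = "trace_sim_params"
  )
}

# Peak time of the unit difference-of-exponentials kernel
# s(t) = exp(-t/decay) - exp(-t/rise).
psc_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

psc_kernel <- function(t, rise_tau, decay_tau) {
  s <- exp(-t / decay_tau) - exp(-t / rise_tau)
  s[t < 0] <- 0
  s
}

#' Analytic 10-90% rise time of the noiseless PSC kernel
#'
#' Root-finds the first upward crossings of 10% and 90% of the kernel peak on
#' the rising phase; used both to parameterize the generator against a target
#' rise time and as an oracle for the sampled-trace estimator.
#'
#' @param rise_tau,decay_tau Kernel time constants (ms).
#' @return Rise time in ms.
#' @export
psc_rise_time <- function(rise_tau, decay_tau) {
  t_pk <- psc_peak_time(rise_tau, decay_tau)
  s_pk <- psc_kernel(t_pk, rise_tau, decay_tau)
  crossing <- function(frac) {
    stats::uniroot(function(t) psc_kernel(t, rise_tau, decay_tau) - frac * s_pk,
                   lower = 0, upper = t_pk, tol = 1e-12)$root
  }
  crossing(0.9) - crossing(0.1)
}

#' Solve for the rise time constant giving a target 10-90% rise time
#'
#' @param rise_time_ms Target 10-90% rise time (ms).
#' @param decay_tau_ms Decay time constant (ms).
#' @return Rise time constant in ms.
#' @export
rise_tau_for_rise_time <- function(rise_time_ms, decay_tau_ms) {
  stats::uniroot(
    function(r) psc_rise_time(r, decay_tau_ms) - rise_time_ms,
    lower = decay_tau_ms * 1e-5, upper = decay_tau_ms * 0.999, tol = 1e-10
  )$root
}

#' Simulate an evoked postsynaptic current sweep
#'
#' Generates baseline + Gaussian noise, then from response onset (stimulus
#' onset + stimulus duration + latency) adds a difference-of-exponentials
#' kernel scaled so the signed noiseless peak equals `amplitude_pA`.
#'
#' @param params A [trace_sim_params()].
#' @return A [sweep_trace()] whose `truth` element carries the generating
#'   parameters.
#' @export
sim_evoked_trace <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"))
  onset <- params$stim_onset_ms + params$stim_duration_ms + params$latency_ms
  if (params$duration_ms - onset < 5 * params$decay_tau_ms) {
    stop("trace window must extend at least 5 decay constants past response onset")
  }
  dt <- 1000 / params$sampling_rate_hz
  time_ms <- seq(0, params$duration_ms, by = dt)
  s <- psc_kernel(time_ms - onset, params$rise_tau_ms, params$decay_tau_ms)
  t_pk <- psc_peak_time(params$rise_tau_ms, params$decay_tau_ms)
  s_pk <- psc_kernel(t_pk, params$rise_tau_ms, params$decay_tau_ms)
  current <- with_seed(params$seed, {
    params$baseline_pA + s * (params$amplitude_pA / s_pk) +
      stats::rnorm(length(time_ms), 0, params$noise_sd_pA)
  })
  sweep_trace(
    time_ms = time_ms, current_pA = current,
    stim_onset_ms = params$stim_onset_ms,
    stim_duration_ms = params$stim_duration_ms,
    holding_mV = params$holding_mV,
    baseline_window = c(0, params$stim_onset_ms),
    response_window = c(params$stim_onset_ms + params$stim_duration_ms,
                        params$duration_ms),
    truth = params
  )
}

#' Parameters for the synthetic GABA current-voltage series generator
#'
#' @param e_rev_true_mV True reversal potential (mV).
#' @param conductance_nS Slope conductance (nS); with voltages in mV the
#'   response amplitudes come out in pA.
#' @param holding_potentials_mV Holding potentials (mV); at least two
#'   distinct values.
#' @param noise_sd_pA SD of additive Gaussian amplitude noise (pA).
#' @param seed Integer seed.
#' @return An `iv_sim_params` list.
#' @export
iv_sim_params <- function(e_rev_true_mV = -25,
                          conductance_nS = 1,
                          holding_potentials_mV = seq(-70, 30, by = 20),
                          noise_sd_pA = 0,
                          seed = 1L) {
  assert_scalar_num(conductance_nS, "conductance_nS", 0, strict_lower = TRUE)
  if (length(unique(holding_potentials_mV)) < 2) {
    stop("at least two distinct holding potentials are required")
  }
  assert_scalar_num(noise_sd_pA, "noise_sd_pA", 0)
  structure(
    list(e_rev_true_mV = e_rev_true_mV, conductance_nS = conductance_nS,
         holding_potentials_mV = holding_potentials_mV,
         noise_sd_pA = noise_sd_pA, seed = as.integer(seed)),
    class = "iv_sim_params"
  )
}

#' Simulate a GABA current-voltage series
#'
#' Ohmic model: `amplitude = g * (V - E_rev) + noise`.
#'
#' @param params An [iv_sim_params()].
#' @return A data.frame with columns `holding_mV`, `amplitude_pA`, carrying
#'   the generating parameters as attribute `truth`.
#' @export
sim_iv_series <- function(params) {
  stopifnot(inherits(params, "iv_sim_params"))
  v <- params$holding_potentials_mV
  amp <- with_seed(params$seed, {
    params$conductance_nS * (v - params$e_rev_true_mV) +
      stats::rnorm(length(v), 0, params$noise_sd_pA)
  })
  out <- data.frame(holding_mV = v, amplitude_pA = amp)
  attr(out, "truth") <- params
  out
}

#' Parameters for the synthetic 3-D puncta field generator
#'
#' @param n_target Number of channel-A (e.g. gephyrin) puncta.
#' @param coloc_fraction_true Ground-truth fraction of A puncta with a
#'   channel-B (e.g. VGAT) partner, in `[0, 1]`.
#' @param coloc_offset_max_um Maximum A-B offset for constructed colocalized
#'   pairs (um).
#' @param min_noncoloc_distance_um Minimum distance from any non-colocalized
#'   A punctum to every B punctum (um); must exceed `coloc_offset_max_um`.
#' @param volume_um `(x, y, z)` extents of the imaging volume (um).
#' @param seed Integer seed.
#' @return A `puncta_sim_params` list.
#' @export
puncta_sim_params <- function(n_target = 500L,
                              coloc_fraction_true = 0.2,
                              coloc_offset_max_um = 0.5,
                              min_noncoloc_distance_um = 2,
                              volume_um = c(50, 50, 10),
                              seed = 1L) {
  n_target <- assert_count(n_target, "n_target")
  assert_scalar_num(coloc_fraction_true, "coloc_fraction_true", 0, 1)
  assert_scalar_num(coloc_offset_max_um, "coloc_offset_max_um", 0, strict_lower = TRUE)
  if (min_noncoloc_distance_um <= coloc_offset_max_um) {
    stop("min_noncoloc_distance_um must exceed coloc_offset_max_um")
  }
  if (length(volume_um) != 3 || any(volume_um <= 0)) {
    stop("volume_um must be three positive extents")
  }
  structure(
    list(n_target = n_target, coloc_fraction_true = coloc_fraction_true,
         coloc_offset_max_um = coloc_offset_max_um,
         min_noncoloc_distance_um = min_noncoloc_distance_um,
         volume_um = volume_um, seed = as.integer(seed)),
    class = "puncta_sim_params"
  )
}

#' Simulate paired 3-D synaptic puncta fields with constructed colocalization
#'
#' Exactly `round(n_target * coloc_fraction_true)` A puncta receive a B
#' partner within `coloc_offset_max_um`; every other A punctum is placed (by
#' rejection) at least `min_noncoloc_distance_um` from every B punctum, so a
#' search radius between the two bounds recovers the constructed fraction
#' exactly.
#'
#' @param params A [puncta_sim_params()].
#' @return A list with matrices `a` and `b` (columns x, y, z in um) and the
#'   ground-truth `n_colocalized`.
#' @export
sim_puncta_field <- function(params) {
  stopifnot(inherits(params, "puncta_sim_params"))
  with_seed(params$seed, {
    n_col <- round(params$n_target * params$coloc_fraction_true)
    vol <- params$volume_um
    runif_point <- function(n) {
      cbind(x = stats::runif(n, 0, vol[1]),
            y = stats::runif(n, 0, vol[2]),
            z = stats::runif(n, 0, vol[3]))
    }
    # colocalized A puncta, kept away from the boundary so partners fit inside
    pad <- params$coloc_offset_max_um
    a_col <- cbind(x = stats::runif(n_col, pad, vol[1] - pad),
                   y = stats::runif(n_col, pad, vol[2] - pad),
                   z = stats::runif(n_col, pad, vol[3] - pad))
    # partners: uniform direction, radius uniform in (0, offset_max]
    b <- if (n_col > 0) {
      dir <- matrix(stats::rnorm(3 * n_col), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      a_col + dir * stats::runif(n_col, 0, params$coloc_offset_max_um)
    } else {
      matrix(numeric(0), ncol = 3)
    }
    colnames(b) <- c("x", "y", "z")
    # non-colocalized A puncta: rejection-sample away from every B punctum
    n_non <- params$n_target - n_col
    a_non <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("x", "y", "z")))
    tries <- 0L
    while (nrow(a_non) < n_non) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("could not place non-colocalized puncta; volume too crowded")
      }
      cand <- runif_point(max(n_non - nrow(a_non), 1L) * 2L)
      keep <- if (nrow(b) == 0) rep(TRUE, nrow(cand)) else {
        apply(cand, 1, function(p) {
          min(sqrt(colSums((t(b) - p)^2))) >= params$min_noncoloc_distance_um
        })
      }
      a_non <- rbind(a_non, cand[keep, , drop = FALSE])
    }
    a_non <- a_non[seq_len(n_non), , drop = FALSE]
    list(a = rbind(a_col, a_non), b = b, n_colocalized = n_col,
         params = params)
  })
}

#' Simulate per-field proliferation count tables
#'
#' Field totals are Poisson around `mean_cells_per_field` (minimum 1);
#' marker-positive cells are binomial with the ground-truth index.
#'
#' @param true_index Ground-truth positive fraction in `[0, 1]`.
#' @param n_fields Number of counting fields.
#' @param mean_cells_per_field Expected total cells per field.
#' @param seed Integer seed.
#' @return A data.frame with columns `field`, `total`, `positive` and
#'   attribute `truth`.
#' @export
sim_count_fields <- function(true_index, n_fields, mean_cells_per_field,
                             seed = 1L) {
  assert_scalar_num(true_index, "true_index", 0, 1)
  n_fields <- assert_count(n_fields, "n_fields")
  assert_scalar_num(mean_cells_per_field, "mean_cells_per_field", 0,
                    strict_lower = TRUE)
  with_seed(seed, {
    total <- pmax(1L, stats::rpois(n_fields, mean_cells_per_field))
    positive <- stats::rbinom(n_fields, total, true_index)
    out <- data.frame(field = sprintf("F%03d", seq_len(n_fields)),
                      total = total, positive = positive)
    attr(out, "truth") <- list(true_index = true_index)
    out
  })
}
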