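#' Run the simulate -> score -> compare pipeline
#'
#' End-to-end orchestration over the package's own building blocks:
#' simulates a labelled single-cell TPM matrix, log-normalizes it, scores a
#' GABAergic signature per cell with bin-matched controls, pseudobulks the
#' scores per sample, and compares sample groups with the Wilcoxon rank-sum
#' test. All artefacts are CSV/JSON under `out_dir`, plus a run manifest
#' with seeds and md5 checksums so a rerun with the same config is
#' byte-identical and tampering is detectable.
#'
#' @param config Named list (or path to a YAML file holding one) with keys:
#'   \describe{
#'     \item{seed}{integer seed for every stochastic stage (default 0)}
#'     \item{simulate}{arguments forwarded to [expr_sim_config()] (optional)}
#'     \item{score}{list with `signature` (fixture name from
#'       [load_fixture_signatures()] or a gene vector), `n_bins`,
#'       `n_control` (optional)}
#'     \item{compare}{list with `group_by`, an annotation column name
#'       (default `"population"`)}
#'   }
#'   Unknown top-level keys are rejected.
#' @param out_dir Output directory.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  allowed <- c("seed", "simulate", "score", "compare")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- simulate ---------------------------------------------------------
  sim_args <- config$simulate %||% list()
  sig_spec <- config$score$signature %||% "synapse_total"
  signature <- if (is.character(sig_spec) && length(sig_spec) == 1 &&
                   sig_spec %in% names(load_fixture_signatures())) {
    load_fixture_signatures()[[sig_spec]]
  } else {
    gene_signature("custom", sig_spec)
  }
  if (is.null(sim_args$signature_genes)) {
    sim_args$signature_genes <- signature$genes
  }
  sim_args$seed <- sim_args$seed %||% seed
  sim <- sim_expression(do.call(expr_sim_config, sim_args))
  expr_dir <- file.path(out_dir, "expression")
  write_expression(sim, expr_dir)

  # -- score ------------------------------------------------------------
  e <- normalize_tpm(sim$tpm)
  n_bins <- config$score$n_bins %||% 25L
  n_control <- config$score$n_control %||% 100L
  score <- module_score(e, signature, n_bins = n_bins,
                        n_control = n_control, seed = seed)
  scores <- data.frame(cell_id = names(score), score = unname(score))
  scores_path <- file.path(out_dir, "scores.csv")
  utils::write.csv(merge(scores, sim$cells, by = "cell_id", sort = TRUE),
                   scores_path, row.names = FALSE)

  # -- compare ----------------------------------------------------------
  group_by <- config$compare$group_by %||% "population"
  if (!group_by %in% names(sim$cells)) {
    stop("compare$group_by column not found in cell annotations: ", group_by)
  }
  groups <- sim$cells[[group_by]][match(scores$cell_id, sim$cells$cell_id)]
  pb <- pseudobulk_means(score, sim$cells$sample)
  pb_path <- file.path(out_dir, "pseudobulk.csv")
  utils::write.csv(pb, pb_path, row.names = FALSE)
  lv <- unique(groups)
  comparisons <- list()
  if (length(lv) >= 2) {
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(p) {
      res <- wilcoxon_rank_sum(score[groups == p[1]], score[groups == p[2]])
      list(group_a = p[1], group_b = p[2], statistic = res$statistic,
           p_value = res$p.value, method = res$method)
    })
  }
  stats_path <- file.path(out_dir, "comparisons.json")
  jsonlite::write_json(comparisons, stats_path, auto_unbox = TRUE,
                       digits = NA)

  # -- manifest ---------------------------------------------------------
  outputs <- c(list.files(expr_dir, full.names = TRUE), scores_path,
               pb_path, stats_path)
  manifest <- list(
    tool = "gabaglioma",
    version = as.character(utils::packageVersion("gabaglioma")),
    seed = seed,
    config = config,
    signature = signature$name,
    n_cells = nrow(sim$cells),
    n_genes = nrow(sim$tpm),
    checksums = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Verify a pipeline run against its manifest
#'
#' Recomputes md5 checksums of the files recorded in `manifest.json` and
#' reports any mismatch or missing file.
#'
#' @param out_dir Directory holding a [run_pipeline()] result.
#' @return `TRUE` if all checksums match, otherwise an error listing the
#'   offending files.
#' @export
verify_manifest <- function(out_dir) {
  mpath <- file.path(out_dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest.json not found in ", out_dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- names(manifest$checksums)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("file(s) recorded in manifest are missing: ",
         paste(missing, collapse = ", "))
  }
  current <- tools::md5sum(files)
  bad <- files[current != unlist(manifest$checksums)]
  if (length(bad)) {
    stop("checksum mismatch (file modified since the run): ",
         paste(bad, collapse = ", "))
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
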