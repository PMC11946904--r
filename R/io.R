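#' Write an expression matrix to disk
#'
#' Sparse Matrix Market (`matrix.mtx` + `genes.tsv` + `cells.tsv`) or a
#' single dense TSV (genes in rows, first column `gene_id`). Cell
#' annotations and any simulation ground truth go to sidecar files.
#'
#' @param x Genes x cells matrix or a `glioma_sim` object.
#' @param dir Output directory (created if needed).
#' @param format `"mtx"` (sparse, default) or `"tsv"` (dense).
#' @param cells Optional cell-annotation data.frame (taken from the sim
#'   object when available); must have a `cell_id` column.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(x, dir, format = c("mtx", "tsv"), cells = NULL) {
  format <- match.arg(format)
  truth <- NULL
  if (inherits(x, "glioma_sim")) {
    if (is.null(cells)) cells <- x$cells
    truth <- x$truth
    x <- x$tpm
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (format == "mtx") {
    mtx <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), mtx)
    genes <- file.path(dir, "genes.tsv")
    utils::write.table(data.frame(gene_id = rownames(x)), genes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(mtx, genes)
  } else {
    dense <- file.path(dir, "matrix.tsv")
    utils::write.table(
      data.frame(gene_id = rownames(x), x, check.names = FALSE),
      dense, sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- dense
  }
  if (is.null(cells)) {
    cells <- data.frame(cell_id = colnames(x), stringsAsFactors = FALSE)
  }
  cpath <- file.path(dir, "cells.tsv")
  utils::write.table(cells, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, cpath)
  if (!is.null(truth)) {
    tpath <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(seed = truth$config$seed,
           signature_genes = truth$config$signature_genes,
           signature_effect = as.list(truth$config$signature_effect),
           dropout_rate = truth$config$dropout_rate),
      tpath, auto_unbox = TRUE, digits = NA, null = "null"
    )
    paths <- c(paths, tpath)
  }
  invisible(paths)
}

#' Read an expression matrix from disk
#'
#' Accepts a directory holding either sparse Matrix Market output
#' (`matrix.mtx` + `genes.tsv` [+ `cells.tsv`]) or a dense `matrix.tsv`,
#' i.e. the inverse of [write_expression()]. Gene and cell ids must be
#' unique and the sidecar dimensions must match the matrix.
#'
#' @param dir Directory containing the matrix files.
#' @return List with `tpm` (genes x cells matrix) and `cells`
#'   (annotation data.frame, `NULL` when no `cells.tsv` is present).
#' @export
read_expression <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  dense <- file.path(dir, "matrix.tsv")
  cpath <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cpath)) {
    utils::read.delim(cpath, stringsAsFactors = FALSE)
  } else NULL
  if (file.exists(mtx)) {
    gpath <- file.path(dir, "genes.tsv")
    if (!file.exists(gpath)) stop("matrix.mtx present but genes.tsv missing")
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.delim(gpath, stringsAsFactors = FALSE)$gene_id
    if (length(genes) != nrow(m)) {
      stop(sprintf("genes.tsv lists %d genes but the matrix has %d rows",
                   length(genes), nrow(m)))
    }
    if (is.null(cells)) stop("sparse format requires a cells.tsv sidecar")
    if (nrow(cells) != ncol(m)) {
      stop(sprintf("cells.tsv lists %d cells but the matrix has %d columns",
                   nrow(cells), ncol(m)))
    }
    dimnames(m) <- list(genes, cells$cell_id)
  } else if (file.exists(dense)) {
    df <- utils::read.delim(dense, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!nrow(df) || names(df)[1] != "gene_id") {
      stop("dense matrix.tsv must be non-empty with a gene_id first column")
    }
    genes <- df$gene_id
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
    if (!is.null(cells) && nrow(cells) != ncol(m)) {
      stop(sprintf("cells.tsv lists %d cells but the matrix has %d columns",
                   nrow(cells), ncol(m)))
    }
  } else {
    stop("no matrix.mtx or matrix.tsv found in ", dir)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids in matrix")
  if (any(m < 0)) stop("expression values must be non-negative")
  list(tpm = m, cells = cells)
}

#' Read a gene signature from a text or GMT file
#'
#' Plain-text files hold one gene per line (the file name, sans extension,
#' becomes the signature name). GMT lines are
#' `name<TAB>description<TAB>gene1<TAB>gene2...`; all signatures in the file
#' are returned.
#'
#' @param path File path, `.txt`/one-per-line or `.gmt`.
#' @return A [gene_signature()] (plain text) or list of them (GMT).
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    lapply(lines, function(l) {
      parts <- strsplit(l, "\t")[[1]]
      if (length(parts) < 3) stop("malformed GMT line: ", l)
      gene_signature(parts[1], parts[-(1:2)])
    })
  } else {
    genes <- readLines(path)
    genes <- trimws(genes[nzchar(trimws(genes))])
    gene_signature(sub("\\.[^.]+$", "", basename(path)), genes)
  }
}

#' Packaged GABAergic gene signatures
#'
#' The GABA_A receptor subunit and GABAergic synapse gene lists shipped with
#' the package: the six alpha-subunit genes (GABRA1-GABRA6), three beta
#' (GABRB1-GABRB3), three gamma (GABRG1-GABRG3), the 19-gene total GABA_A
#' receptor set, and the 24-gene total GABAergic synapse-related set (the
#' receptor set plus GPHN, ARHGEF9, NLGN2, SLC12A2 and SLC12A5).
#'
#' @return Named list of [gene_signature()] objects: `alpha`, `beta`,
#'   `gamma`, `receptor_total`, `synapse_total`.
#' @export
load_fixture_signatures <- function() {
  dir <- system.file("extdata", "signatures", package = "gabaglioma",
                     mustWork = TRUE)
  files <- c(alpha = "gaba_a_alpha.txt", beta = "gaba_a_beta.txt",
             gamma = "gaba_a_gamma.txt",
             receptor_total = "gaba_a_receptor_total.txt",
             synapse_total = "gabaergic_synapse_total.txt")
  lapply(files, function(f) read_signature(file.path(dir, f)))
}

#' Read a solution recipe from YAML
#'
#' @param path YAML file with fields `name`, `salts` (salt -> mM mapping)
#'   and optional `temperature_C`.
#' @return A [solution_recipe()].
#' @export
read_solution <- function(path) {
  if (!file.exists(path)) stop("solution file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$salts)) {
    stop("solution YAML must define `name` and `salts`")
  }
  solution_recipe(y$name, y$salts,
                  temperature_C = if (is.null(y$temperature_C)) 29
                                  else y$temperature_C)
}

#' Packaged solution recipes
#'
#' The recording ACSF (133.5 mM free chloride), the high-chloride CsCl
#' pipette solution (152 mM) and the low-chloride CsMeSO4 pipette solution.
#'
#' @return Named list of [solution_recipe()]s: `acsf`, `pipette_cscl`,
#'   `pipette_csme`.
#' @export
load_fixture_solutions <- function() {
  dir <- system.file("extdata", "solutions", package = "gabaglioma",
                     mustWork = TRUE)
  list(
    acsf = read_solution(file.path(dir, "acsf_recording.yaml")),
    pipette_cscl = read_solution(file.path(dir, "pipette_cscl.yaml")),
    pipette_csme = read_solution(file.path(dir, "pipette_csme.yaml"))
  )
}

#' Write / read a sweep trace as CSV plus JSON metadata
#'
#' The CSV holds `time_ms,current_pA` with a header; stimulus timing,
#' holding potential and analysis windows go to a JSON sidecar of the same
#' stem.
#'
#' @param trace A [sweep_trace()].
#' @param path CSV path (the sidecar replaces the extension with `.json`).
#' @return `write_trace`: invisibly, the two paths. `read_trace`: the
#'   reconstructed [sweep_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  utils::write.csv(
    data.frame(time_ms = trace$time_ms, current_pA = trace$current_pA),
    path, row.names = FALSE
  )
  meta_path <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(stim_onset_ms = trace$stim_onset_ms,
         stim_duration_ms = trace$stim_duration_ms,
         holding_mV = trace$holding_mV,
         baseline_window = trace$baseline_window,
         response_window = trace$response_window),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(path, meta_path))
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "current_pA") %in% names(df))) {
    stop("trace CSV needs columns time_ms and current_pA")
  }
  meta_path <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(meta_path)) stop("trace metadata sidecar not found: ",
                                    meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sweep_trace(
    time_ms = df$time_ms, current_pA = df$current_pA,
    stim_onset_ms = meta$stim_onset_ms,
    stim_duration_ms = meta$stim_duration_ms,
    holding_mV = if (is.null(meta$holding_mV)) NA_real_ else meta$holding_mV,
    baseline_window = meta$baseline_window,
    response_window = meta$response_window
  )
}

#' Read a current-voltage series from CSV
#'
#' @param path CSV with header columns `holding_mV,amplitude_pA`.
#' @return Data.frame suitable for [reversal_from_iv()].
#' @export
read_iv_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("holding_mV", "amplitude_pA") %in% names(df))) {
    stop("I-V CSV needs columns holding_mV and amplitude_pA")
  }
  df
}
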