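#' Expression study container
#'
#' A genes-by-samples matrix of (log2) intensities plus a class label per
#' sample. This is the substrate for differential-expression calling.
#'
#' @param mat Numeric matrix, genes in rows (rownames required), samples in
#'   columns (colnames required).
#' @param sample_classes Character vector, one class per column of `mat`
#'   (e.g. `"LaBC"`, `"normal"`). Recycled names are not allowed; length
#'   must equal `ncol(mat)`.
#' @param already_logged Logical; `TRUE` if `mat` is on the log2 scale.
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(mat, sample_classes, already_logged = TRUE) {
  if (!is.matrix(mat) || !is.numeric(mat))
    ts_stop("invalid_study", "`mat` must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    ts_stop("invalid_study", "`mat` must carry gene rownames and sample colnames")
  if (length(sample_classes) != ncol(mat))
    ts_stop("invalid_study", "one class label per sample column is required")
  structure(
    list(matrix = mat,
         sample_classes = setNames(as.character(sample_classes), colnames(mat)),
         already_logged = isTRUE(already_logged)),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study>", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples;", if (x$already_logged) "log2 scale" else "linear scale", "\n")
  print(table(x$sample_classes))
  invisible(x)
}

#' Simulate a subtype-vs-normal expression study
#'
#' Draws a log2-scale intensity matrix under a simple microarray null: each
#' gene receives a baseline mean from N(7, 1) once, and every sample value
#' is that mean plus N(0, `noise_sd`) noise. A set of `n_spiked` genes is
#' shifted by `spike_log2fc` (first half up, second half down) in every
#' tumour group, leaving the normal group at baseline. Ground truth is
#' recorded before noise is added.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   `study` (an [expression_study()]) and
#'   `truth` (list with `spiked_up`, `spiked_down` gene ids and
#'   `spike_log2fc`).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 100,
#'                                       n_spiked = 10))
#' dim(sim$study$matrix)
simulate_expression <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "expression"))

  groups <- cfg$group_sizes
  classes <- rep(names(groups), times = groups)
  n_samp <- length(classes)
  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  samples <- sprintf("S%03d", seq_len(n_samp))

  base_mean <- rnorm(cfg$n_genes, mean = 7, sd = 1)
  mat <- matrix(rnorm(cfg$n_genes * n_samp, sd = cfg$noise_sd),
                nrow = cfg$n_genes, dimnames = list(genes, samples))
  mat <- mat + base_mean

  spiked_up <- character(0)
  spiked_down <- character(0)
  if (cfg$n_spiked > 0L) {
    spiked <- sample(genes, cfg$n_spiked)
    half <- ceiling(cfg$n_spiked / 2)
    spiked_up <- sort(spiked[seq_len(half)])
    spiked_down <- sort(spiked[-seq_len(half)])
    tumour_cols <- classes != "normal"
    mat[spiked_up, tumour_cols] <- mat[spiked_up, tumour_cols] + cfg$spike_log2fc
    mat[spiked_down, tumour_cols] <- mat[spiked_down, tumour_cols] - cfg$spike_log2fc
  }

  list(
    study = expression_study(mat, classes, already_logged = TRUE),
    truth = list(spiked_up = spiked_up, spiked_down = spiked_down,
                 spike_log2fc = cfg$spike_log2fc)
  )
}

#' Simulate per-compound target-prediction tables
#'
#' Emulates the output of ligand-based target-prediction services: for each
#' compound, a table of candidate genes with a prediction probability and a
#' source tag (`swiss_like` carries only a probability; `super_like` also
#' carries a model accuracy).
#'
#' @param config A [sim_config()].
#' @param genes Character vector of gene symbols to draw targets from.
#' @param compound_ids Compound identifiers; defaults to
#'   `CMP001..CMP<n_compounds>`.
#' @param targets_per_compound Mean number of predicted rows per compound.
#' @return A data frame with columns `compound_id`, `gene`, `probability`,
#'   `source`, `model_accuracy` (NA for `swiss_like` rows).
#' @export
simulate_target_predictions <- function(config, genes,
                                        compound_ids = NULL,
                                        targets_per_compound = 12L) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "compounds", extra = 97L))
  if (is.null(compound_ids))
    compound_ids <- sprintf("CMP%03d", seq_len(cfg$n_compounds))
  rows <- lapply(compound_ids, function(id) {
    n <- max(1L, rbinom(1L, 2L * targets_per_compound, 0.5))
    data.frame(
      compound_id = id,
      gene = sample(genes, min(n, length(genes))),
      probability = round(runif(min(n, length(genes))), 3),
      source = sample(c("swiss_like", "super_like"),
                      min(n, length(genes)), replace = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$model_accuracy <- ifelse(out$source == "super_like",
                               round(runif(nrow(out), 0.7, 1.0), 3), NA_real_)
  out
}
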