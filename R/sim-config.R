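#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. One global `seed` fans
#' out to fixed per-generator child seeds, so adding or re-running one
#' generator never perturbs the streams of the others, and the same seed
#' reproduces every output bit for bit.
#'
#' The default expression design mirrors the GSE45827 breast-cancer
#' microarray study the pipeline emulates: 29 luminal-A (LaBC), 30
#' luminal-B (LbBC), 30 HER2-positive (Her2BC) and 41 triple-negative
#' (TNBC) tumour samples against 11 normal tissue samples.
#'
#' @param seed Integer seed controlling all generators.
#' @param n_genes Number of genes in the simulated expression matrix.
#' @param group_sizes Named integer vector of samples per class; must
#'   contain a `normal` entry.
#' @param n_spiked Number of genes shifted away from the null (half up,
#'   half down) in every tumour group.
#' @param spike_log2fc True shift of spiked genes, in log2 units.
#' @param noise_sd Per-gene residual standard deviation, log2 units.
#' @param n_compounds Size of the simulated compound library.
#' @param frac_es_positive Fraction of compounds built on electron-shuttle
#'   (ortho/para-dihydroxy aromatic) scaffolds.
#' @param ppi_nodes Number of genes in the simulated interaction network.
#' @param ppi_edge_prob Background edge probability of the random graph.
#' @param planted_clique_size Size of the fully connected, high-confidence
#'   clique planted in the network.
#' @param plate_noise_sd Absorbance noise (AU) added to plate wells.
#' @param cv_peak_current Amplitude of the oxidation peak in simulated
#'   voltammograms, in microamps.
#' @param cv_scan_limits Two-element numeric, the low and high scan
#'   voltages (V) of the cyclic-voltammetry window.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, n_spiked = 5)
#' cfg$group_sizes
sim_config <- function(seed = 1L,
                       n_genes = 20000L,
                       group_sizes = c(LaBC = 29L, LbBC = 30L, Her2BC = 30L,
                                       TNBC = 41L, normal = 11L),
                       n_spiked = 200L,
                       spike_log2fc = 2,
                       noise_sd = 0.3,
                       n_compounds = 40L,
                       frac_es_positive = 0.5,
                       ppi_nodes = 60L,
                       ppi_edge_prob = 0.04,
                       planted_clique_size = 6L,
                       plate_noise_sd = 0.01,
                       cv_peak_current = 50,
                       cv_scan_limits = c(-1.5, 1.5)) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    group_sizes = group_sizes,
    n_spiked = as.integer(n_spiked),
    spike_log2fc = spike_log2fc,
    noise_sd = noise_sd,
    n_compounds = as.integer(n_compounds),
    frac_es_positive = frac_es_positive,
    ppi_nodes = as.integer(ppi_nodes),
    ppi_edge_prob = ppi_edge_prob,
    planted_clique_size = as.integer(planted_clique_size),
    plate_noise_sd = plate_noise_sd,
    cv_peak_current = cv_peak_current,
    cv_scan_limits = as.numeric(cv_scan_limits)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$seed)) ts_stop("invalid_config", "`seed` must be an integer")
  if (cfg$n_genes < 1L) ts_stop("invalid_config", "`n_genes` must be >= 1")
  if (is.null(names(cfg$group_sizes)) || !"normal" %in% names(cfg$group_sizes))
    ts_stop("invalid_config", "`group_sizes` must be named and include 'normal'")
  if (any(cfg$group_sizes < 1))
    ts_stop("invalid_config", "all group sizes must be >= 1")
  if (cfg$n_spiked > cfg$n_genes)
    ts_stop("invalid_config", sprintf(
      "`n_spiked` (%d) cannot exceed `n_genes` (%d)", cfg$n_spiked, cfg$n_genes))
  for (p in c("frac_es_positive", "ppi_edge_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      ts_stop("invalid_config", sprintf("`%s` must lie in [0, 1]", p))
  }
  if (cfg$noise_sd < 0 || cfg$plate_noise_sd < 0)
    ts_stop("invalid_config", "noise standard deviations must be >= 0")
  if (length(cfg$cv_scan_limits) != 2L ||
      cfg$cv_scan_limits[1] >= cfg$cv_scan_limits[2])
    ts_stop("invalid_config", "`cv_scan_limits` must be c(low, high) with low < high")
  if (cfg$planted_clique_size > cfg$ppi_nodes)
    ts_stop("invalid_config", "`planted_clique_size` cannot exceed `ppi_nodes`")
  cfg
}

# Fixed per-generator offsets; `extra` distinguishes e.g. assay types.
child_seed <- function(cfg, stage, extra = 0L) {
  offsets <- c(expression = 101L, compounds = 211L, ppi = 307L,
               plate = 401L, mfc = 503L, cv = 601L, gene_sets = 701L)
  if (!stage %in% names(offsets))
    ts_stop("invalid_config", paste("unknown generator stage:", stage))
  (cfg$seed + offsets[[stage]] + as.integer(extra)) %% .Machine$integer.max
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("  expression:", x$n_genes, "genes;",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n")
  cat("  spikes:", x$n_spiked, "genes at +/-", x$spike_log2fc,
      "log2 units, noise sd", x$noise_sd, "\n")
  cat("  compounds:", x$n_compounds,
      sprintf("(%.0f%% electron-shuttle scaffolds)", 100 * x$frac_es_positive), "\n")
  cat("  network:", x$ppi_nodes, "nodes, edge prob", x$ppi_edge_prob,
      "planted clique", x$planted_clique_size, "\n")
  invisible(x)
}
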