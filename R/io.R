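# Readers and writers for the pipeline's plain-text interchange formats.
# All tables are plain CSV/TSV so that runs are reproducible and diffable.

#' Read / write a plate CSV
#'
#' Columns: `sample_id`, `role`, `concentration`, `replicate`,
#' `absorbance`; assay and wavelength travel in the file name or the
#' arguments.
#'
#' @param path File path.
#' @param assay,wavelength Plate metadata for the constructed object.
#' @return [read_plate_csv()]: an [absorbance_plate()].
#' @export
read_plate_csv <- function(path, assay, wavelength = NA_real_) {
  absorbance_plate(read.csv(path, stringsAsFactors = FALSE),
                   wavelength = wavelength, assay = assay)
}

#' @rdname read_plate_csv
#' @param plate An [absorbance_plate()].
#' @export
write_plate_csv <- function(plate, path) {
  write.csv(plate$wells, path, row.names = FALSE)
  invisible(path)
}

#' Read / write MFC voltage series
#'
#' Long CSV with columns `condition_id`, `time_s`, `voltage_V`; the circuit
#' metadata (resistance, anode area) is supplied per call.
#'
#' @param path File path.
#' @param external_resistance,anode_area Circuit metadata (ohm, m^2).
#' @return [read_mfc_csv()]: named list of [mfc_series()].
#' @export
read_mfc_csv <- function(path, external_resistance = 1000,
                         anode_area = 1.649e-4) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$condition_id)[unique(d$condition_id)], function(x) {
    mfc_series(x$condition_id[1],
               data.frame(time = x$time_s, voltage = x$voltage_V),
               external_resistance, anode_area)
  })
}

#' @rdname read_mfc_csv
#' @param series List of [mfc_series()].
#' @export
write_mfc_csv <- function(series, path) {
  d <- do.call(rbind, lapply(series, function(s) {
    data.frame(condition_id = s$condition_id, time_s = s$samples$time,
               voltage_V = s$samples$voltage)
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write voltammogram sweeps
#'
#' CSV with columns `cycle`, `direction`, `voltage_V`, `current_uA`.
#'
#' @param path File path.
#' @param scan_rate Scan rate metadata, mV/s.
#' @return [read_cv_csv()]: a [voltammogram()].
#' @export
read_cv_csv <- function(path, scan_rate = 10) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  cycles <- data.frame(cycle = d$cycle, direction = d$direction,
                       voltage = d$voltage_V, current = d$current_uA)
  voltammogram(cycles, v_low = min(cycles$voltage),
               v_high = max(cycles$voltage), scan_rate = scan_rate)
}

#' @rdname read_cv_csv
#' @param vgram A [voltammogram()].
#' @export
write_cv_csv <- function(vgram, path) {
  d <- data.frame(cycle = vgram$cycles$cycle,
                  direction = vgram$cycles$direction,
                  voltage_V = vgram$cycles$voltage,
                  current_uA = vgram$cycles$current)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a STRING-dialect edge list
#'
#' Tab-separated columns `protein1`, `protein2`, `combined_score`.
#'
#' @param path File path.
#' @return [read_edges_tsv()]: edge data frame.
#' @export
read_edges_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_edges_tsv
#' @param edges Edge data frame.
#' @export
write_edges_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an expression study
#'
#' The matrix travels as a TSV with gene ids in the first column; the class
#' labels as a two-column CSV `sample`, `class`.
#'
#' @param matrix_path,classes_path File paths.
#' @param already_logged Scale flag for the constructed study.
#' @return [read_expression_tsv()]: an [expression_study()].
#' @export
read_expression_tsv <- function(matrix_path, classes_path,
                                already_logged = TRUE) {
  m <- read.delim(matrix_path, row.names = 1, check.names = FALSE)
  cls <- read.csv(classes_path, stringsAsFactors = FALSE)
  classes <- setNames(cls$class, cls$sample)[colnames(m)]
  expression_study(as.matrix(m), classes, already_logged = already_logged)
}

#' @rdname read_expression_tsv
#' @param study An [expression_study()].
#' @export
write_expression_tsv <- function(study, matrix_path, classes_path) {
  m <- data.frame(gene = rownames(study$matrix), study$matrix,
                  check.names = FALSE)
  write.table(m, matrix_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(data.frame(sample = colnames(study$matrix),
                       class = unname(study$sample_classes)),
            classes_path, row.names = FALSE)
  invisible(matrix_path)
}

#' Bundled power-density reference table
#'
#' Mean and standard deviation of microbial-fuel-cell power densities
#' (mW/m^2 reporting scale) for four Oolong-tea extract preparations -
#' solvent extraction (OTL) and supercritical-fluid pre-extraction (OTS),
#' each with water (W) and ethanol (E) solvents - across a dosing schedule
#' of blanks, six concentrations and a dopamine standard, together with the
#' published blank-normalised amplification factors. Useful as a worked
#' example for [amplification()] and [es_presence()].
#'
#' @return Data frame `extract`, `condition_id`, `pd_mean`, `pd_sd`,
#'   `published_amplification`, `published_amplification_sd`.
#' @export
#' @examples
#' pd <- example_power_density()
#' otlw <- pd[pd$extract == "OTL-W", ]
#' amplification(otlw)$amplification
example_power_density <- function() {
  read.csv(system.file("extdata", "mfc_power_density.csv",
                       package = "teashuttle"),
           stringsAsFactors = FALSE)
}

#' Bundled per-subtype hub-gene lists
#'
#' The per-subtype hub genes (consensus of four centrality rankings on
#' compound-target x differential-expression overlap networks) reported in
#' a published Oolong-tea breast-cancer network-pharmacology analysis, per
#' regulation direction. Useful as a worked example for
#' [key_hub_intersection()].
#'
#' @return Named list (`up`, `down`) of named lists (subtype -> character
#'   vector of hub genes).
#' @export
#' @examples
#' hubs <- example_hub_lists()
#' key_hub_intersection(hubs$down)  # HSP90AB1, MAPK1
example_hub_lists <- function() {
  d <- read.csv(system.file("extdata", "hub_genes.csv",
                            package = "teashuttle"),
                stringsAsFactors = FALSE)
  lapply(split(d, d$direction), function(x) {
    lapply(split(x$gene, x$subtype), sort)
  })
}
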