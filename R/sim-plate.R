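#' Absorbance plate container
#'
#' A tidy table of plate-reader wells for one assay: each well has a sample
#' id, a role (`standard`, `sample`, `blank`, `control`), an optional known
#' concentration (mg/mL), a replicate index and an absorbance (AU).
#'
#' @param wells Data frame with columns `sample_id`, `role`,
#'   `concentration`, `replicate`, `absorbance`.
#' @param wavelength Detection wavelength in nm (metadata).
#' @param assay One of `"TPC"`, `"TFC"`, `"TCTC"`, `"DPPH"`, `"FRAP"`.
#' @return An object of class `absorbance_plate`.
#' @export
absorbance_plate <- function(wells, wavelength, assay) {
  need <- c("sample_id", "role", "concentration", "replicate", "absorbance")
  if (!all(need %in% names(wells)))
    ts_stop("invalid_plate", paste("wells must have columns:",
                                   paste(need, collapse = ", ")))
  bad <- !wells$role %in% c("standard", "sample", "blank", "control")
  if (any(bad))
    ts_stop("invalid_plate", "well roles must be standard/sample/blank/control")
  if (any(!is.finite(wells$absorbance)))
    ts_stop("invalid_plate", "absorbances must be finite")
  structure(list(wells = wells, wavelength = wavelength,
                 assay = match.arg(assay, c("TPC", "TFC", "TCTC", "DPPH", "FRAP"))),
            class = "absorbance_plate")
}

#' @export
print.absorbance_plate <- function(x, ...) {
  cat("<absorbance_plate>", x$assay, "at", x$wavelength, "nm;",
      nrow(x$wells), "wells\n")
  print(table(x$wells$role))
  invisible(x)
}

# Per-assay generator defaults: calibration line, detection wavelength and
# equivalent unit. Content-assay lines are the published calibration curves
# for gallic-acid, rutin and catechin standards; the FRAP Trolox line is a
# realistic invented one.
.assay_defaults <- list(
  TPC  = list(slope = 3.8354, intercept = -0.0132, wavelength = 600, unit = "GAE"),
  TFC  = list(slope = 4.9008, intercept =  0.0287, wavelength = 430, unit = "RE"),
  TCTC = list(slope = 7.7867, intercept = -0.0242, wavelength = 530, unit = "CE"),
  FRAP = list(slope = 2.2000, intercept =  0.0150, wavelength = 593, unit = "Trolox"),
  DPPH = list(slope = NA, intercept = NA, wavelength = 517, unit = NA)
)

# Two-fold serial dilutions from 1 mg/mL, matching the bench protocol's
# concentration ladders (6 levels for content assays, 8 for DPPH).
.dilution_ladder <- function(levels) 1 / 2^(seq_len(levels) - 1)

#' Simulate a plate read for one assay
#'
#' Content assays (`TPC`, `TFC`, `TCTC`, `FRAP`) produce a standard
#' dilution ladder following `A = slope * c + intercept + N(0,
#' plate_noise_sd)` in triplicate plus triplicate sample wells at a known
#' true concentration (and, for FRAP, matched per-sample blanks). The
#' `DPPH` assay produces control/blank wells and a sample dilution series
#' whose percent radical-scavenging activity is linear in concentration and
#' crosses 50% exactly at `true_ic50`.
#'
#' @param config A [sim_config()].
#' @param assay Assay name.
#' @param true_concentration True sample concentration (mg/mL) for content
#'   assays.
#' @param true_ic50 True half-maximal concentration (mg/mL) for DPPH.
#' @param rsa_slope Slope of %RSA per (mg/mL) for the DPPH response;
#'   the default keeps the whole ladder inside (0, 100)%.
#' @return A list with elements `plate` (an [absorbance_plate()]) and
#'   `truth` (generator parameters: calibration line or IC50, and the true
#'   sample concentration).
#' @export
#' @examples
#' sim <- simulate_plate(sim_config(seed = 1, plate_noise_sd = 0), "TPC")
#' fit_calibration(sim$plate)
simulate_plate <- function(config,
                           assay = c("TPC", "TFC", "TCTC", "DPPH", "FRAP"),
                           true_concentration = 0.2,
                           true_ic50 = 0.075,
                           rsa_slope = 50) {
  cfg <- validate_sim_config(config)
  assay <- match.arg(assay)
  defs <- .assay_defaults[[assay]]
  set.seed(child_seed(cfg, "plate", extra = match(assay, names(.assay_defaults))))
  noise <- function(n) rnorm(n, sd = cfg$plate_noise_sd)

  if (assay == "DPPH") {
    conc <- .dilution_ladder(8L)
    a_ctl <- 1.0
    a_blk <- 0.05
    rsa <- 50 + rsa_slope * (conc - true_ic50)
    if (any(rsa <= 0 | rsa >= 100))
      ts_stop("invalid_config",
              "DPPH generator: %RSA leaves (0, 100); lower `rsa_slope`")
    rows <- list()
    for (rep in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = "control", role = "control", concentration = NA_real_,
        replicate = rep, absorbance = a_ctl + noise(1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = "blank", role = "blank", concentration = NA_real_,
        replicate = rep, absorbance = a_blk + noise(1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = "extract", role = "sample", concentration = conc,
        replicate = rep,
        absorbance = a_blk + (1 - rsa / 100) * (a_ctl - a_blk) + noise(length(conc)))
    }
    wells <- do.call(rbind, rows)
    truth <- list(ic50 = true_ic50, rsa_slope = rsa_slope,
                  a_ctl = a_ctl, a_blk = a_blk)
  } else {
    conc <- .dilution_ladder(6L)
    rows <- list()
    for (rep in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("std%02d", seq_along(conc)), role = "standard",
        concentration = conc, replicate = rep,
        absorbance = defs$slope * conc + defs$intercept + noise(length(conc)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = "extract", role = "sample", concentration = NA_real_,
        replicate = rep,
        absorbance = defs$slope * true_concentration + defs$intercept + noise(1))
      if (assay == "FRAP")
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = "extract", role = "blank", concentration = NA_real_,
          replicate = rep, absorbance = defs$intercept + noise(1))
    }
    wells <- do.call(rbind, rows)
    truth <- list(slope = defs$slope, intercept = defs$intercept,
                  equivalent_unit = defs$unit,
                  true_concentration = true_concentration)
  }
  rownames(wells) <- NULL
  list(plate = absorbance_plate(wells, defs$wavelength, assay), truth = truth)
}
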