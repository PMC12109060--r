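#' Fit a linear calibration curve from plate standards
#'
#' Replicate absorbances of each standard concentration are averaged first,
#' then an ordinary-least-squares line `absorbance ~ concentration` is
#' fitted through the level means. This mirrors routine plate practice for
#' content assays calibrated against gallic acid, rutin, catechin or Trolox
#' standards.
#'
#' @param plate An [absorbance_plate()] containing `standard` wells.
#' @param equivalent_unit Unit label carried on the curve (`"GAE"`, `"RE"`,
#'   `"CE"`, `"Trolox"`); defaults to the plate assay's conventional unit.
#' @return An object of class `calibration_curve`: list with `slope` (AU
#'   per mg/mL), `intercept` (AU), `r_squared`, `equivalent_unit`,
#'   `n_levels`.
#' @export
#' @examples
#' sim <- simulate_plate(sim_config(seed = 1, plate_noise_sd = 0), "TPC")
#' fit_calibration(sim$plate)
fit_calibration <- function(plate, equivalent_unit = NULL) {
  stopifnot(inherits(plate, "absorbance_plate"))
  std <- plate$wells[plate$wells$role == "standard", ]
  if (nrow(std) == 0L || length(unique(std$concentration)) < 3L)
    ts_stop("insufficient_standards",
            "calibration needs >= 3 distinct standard concentrations")
  means <- tapply(std$absorbance, std$concentration, mean)
  conc <- as.numeric(names(means))
  if (var(conc) == 0)
    ts_stop("degenerate_design", "standard concentrations have zero variance")
  fit <- lm(abs_mean ~ conc, data = data.frame(conc = conc,
                                               abs_mean = as.numeric(means)))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((means - mean(means))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (is.null(equivalent_unit))
    equivalent_unit <- .assay_defaults[[plate$assay]]$unit
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 equivalent_unit = equivalent_unit,
                 n_levels = length(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A = %.4f c %+ .4f  (R^2 = %.4f, %s, %d levels)\n",
              x$slope, x$intercept, x$r_squared,
              if (is.na(x$equivalent_unit)) "?" else x$equivalent_unit,
              x$n_levels))
  invisible(x)
}

#' Convert absorbance to standard equivalents
#'
#' Inverts the calibration line, `c = (A - intercept) / slope`, and scales
#' by the dilution factor of the measured solution. With absorbance in AU
#' and the curve in AU per (mg/mL), the result is mg of standard
#' equivalents per mL; multiplied through the caller's dilution chain and
#' extract-mass convention it reads as mg equivalents per g extract.
#'
#' @param absorbance Absorbance value(s), AU.
#' @param curve A [fit_calibration()] result.
#' @param dilution_factor Fold dilution applied to the measured solution.
#' @return Numeric equivalents, same length as `absorbance`.
#' @export
to_equivalents <- function(absorbance, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0)
    ts_stop("degenerate_curve", "calibration slope is zero")
  (absorbance - curve$intercept) / curve$slope * dilution_factor
}

#' Percent radical-scavenging activity
#'
#' The DPPH assay statistic: `100 * ((A_ctl - A_blk) - (A_spl - A_blk)) /
#' (A_ctl - A_blk)`. A sample absorbing like the blank scavenged every
#' radical (100%); one absorbing like the control scavenged none (0%).
#' Adding a constant to all three absorbances leaves the value unchanged.
#'
#' @param a_ctl,a_blk,a_spl Control, blank and sample absorbances (AU);
#'   vectors are recycled by the usual rules.
#' @return %RSA value(s).
#' @export
#' @examples
#' rsa_percent(1.0, 0.1, 0.55)  # 50
rsa_percent <- function(a_ctl, a_blk, a_spl) {
  if (any(a_ctl == a_blk))
    ts_stop("undefined_control",
            "control and blank absorbances coincide; %RSA undefined")
  100 * ((a_ctl - a_blk) - (a_spl - a_blk)) / (a_ctl - a_blk)
}

#' Estimate IC50 from a %RSA dose series
#'
#' Fits `%RSA ~ concentration` by ordinary least squares over all supplied
#' points (concentrations on the raw scale) and solves for the 50% crossing
#' `IC50 = (50 - intercept) / slope`. The crossing is expected within the
#' observed concentration range extended by one two-fold dilution step on
#' either side; a crossing outside that range is returned with
#' `extrapolated = TRUE`.
#'
#' @param concentration Concentrations, mg/mL.
#' @param rsa Matching %RSA values.
#' @param dilution_step Dilution ratio between neighbouring ladder levels
#'   (2 for two-fold series); controls the allowed extrapolation margin.
#' @return List with `ic50` (mg/mL), `slope`, `intercept`, `extrapolated`
#'   and `degenerate` flags.
#' @export
#' @examples
#' estimate_ic50(c(0.05, 0.15), c(40, 80))$ic50  # 0.075
estimate_ic50 <- function(concentration, rsa, dilution_step = 2) {
  if (length(concentration) != length(rsa) || length(rsa) < 2L)
    ts_stop("insufficient_points", "need >= 2 (concentration, %RSA) points")
  if (all(rsa == 50)) {
    return(list(ic50 = min(concentration), slope = 0, intercept = 50,
                extrapolated = FALSE, degenerate = TRUE))
  }
  fit <- lm(rsa ~ concentration)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (is.na(slope) || slope <= 0)
    ts_stop("non_responsive_sample",
            "fitted %RSA does not increase with concentration")
  ic50 <- (50 - intercept) / slope
  lo <- min(concentration) / dilution_step
  hi <- max(concentration) * dilution_step
  list(ic50 = ic50, slope = slope, intercept = intercept,
       extrapolated = ic50 < lo || ic50 > hi, degenerate = FALSE)
}

#' DPPH plate summary: %RSA per concentration and IC50
#'
#' Averages control, blank and per-concentration sample wells, computes
#' [rsa_percent()] for each ladder level and estimates the IC50 by
#' [estimate_ic50()].
#'
#' @param plate A DPPH [absorbance_plate()].
#' @param ... Passed to [estimate_ic50()].
#' @return List with `points` (data frame `concentration`, `rsa_percent`)
#'   and the [estimate_ic50()] fields.
#' @export
dpph_summary <- function(plate, ...) {
  stopifnot(inherits(plate, "absorbance_plate"))
  w <- plate$wells
  a_ctl <- mean(w$absorbance[w$role == "control"])
  a_blk <- mean(w$absorbance[w$role == "blank"])
  spl <- w[w$role == "sample", ]
  a_spl <- tapply(spl$absorbance, spl$concentration, mean)
  conc <- as.numeric(names(a_spl))
  rsa <- rsa_percent(a_ctl, a_blk, as.numeric(a_spl))
  c(list(points = data.frame(concentration = conc, rsa_percent = rsa)),
    estimate_ic50(conc, rsa, ...))
}

#' Quantify a content-assay plate in standard equivalents
#'
#' Averages the replicate sample wells of each `sample_id` and converts the
#' mean absorbance via [to_equivalents()].
#'
#' @param plate An [absorbance_plate()].
#' @param curve A [fit_calibration()] result.
#' @param dilution_factor Fold dilution of the measured solutions.
#' @return Data frame `sample_id`, `absorbance`, `equivalents`.
#' @export
quantify_plate <- function(plate, curve, dilution_factor = 1) {
  stopifnot(inherits(plate, "absorbance_plate"))
  spl <- plate$wells[plate$wells$role == "sample", ]
  if (nrow(spl) == 0L) ts_stop("no_data", "plate has no sample wells")
  means <- tapply(spl$absorbance, spl$sample_id, mean)
  data.frame(sample_id = names(means),
             absorbance = as.numeric(means),
             equivalents = to_equivalents(as.numeric(means), curve,
                                          dilution_factor),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' FRAP equivalents with per-sample blank subtraction
#'
#' The ferric-reducing power protocol carries a blank for each sample; the
#' blank signal corresponds to the calibration intercept, so the
#' blank-corrected absorbance is converted through the slope alone:
#' `equivalents = (A_sample - A_blank) / slope * dilution_factor`. A sample
#' absorbing like its blank therefore reports zero reducing power.
#'
#' @param plate A FRAP [absorbance_plate()] with matched `sample`/`blank`
#'   wells sharing a `sample_id`.
#' @param curve A Trolox [fit_calibration()] result.
#' @param dilution_factor Fold dilution of the measured solutions.
#' @return Data frame `sample_id`, `corrected_absorbance`, `equivalents`
#'   (Trolox mg/g convention left to the caller's dilution chain).
#' @export
frap_equivalents <- function(plate, curve, dilution_factor = 1) {
  stopifnot(inherits(plate, "absorbance_plate"),
            inherits(curve, "calibration_curve"))
  if (curve$slope == 0)
    ts_stop("degenerate_curve", "calibration slope is zero")
  w <- plate$wells
  spl <- w[w$role == "sample", ]
  blk <- w[w$role == "blank", ]
  if (nrow(spl) == 0L) ts_stop("no_data", "plate has no sample wells")
  spl_mean <- tapply(spl$absorbance, spl$sample_id, mean)
  blk_mean <- if (nrow(blk)) tapply(blk$absorbance, blk$sample_id, mean) else NULL
  ids <- names(spl_mean)
  corr <- vapply(ids, function(id) {
    b <- if (!is.null(blk_mean) && id %in% names(blk_mean)) blk_mean[[id]]
         else if (!is.null(blk_mean)) mean(blk$absorbance) else 0
    spl_mean[[id]] - b
  }, numeric(1))
  data.frame(sample_id = ids,
             corrected_absorbance = unname(corr),
             equivalents = unname(corr) / curve$slope * dilution_factor,
             row.names = NULL, stringsAsFactors = FALSE)
}
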