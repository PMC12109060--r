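#' Microbial-fuel-cell voltage series container
#'
#' One condition's voltage time course together with the circuit metadata
#' needed to convert voltage to power density: the external resistance and
#' the anode working area.
#'
#' @param condition_id Condition label (e.g. `"blank1"`, `"250ppm"`,
#'   `"dopamine"`).
#' @param samples Data frame with strictly increasing `time` (s) and
#'   `voltage` (V).
#' @param external_resistance External load in ohm (default 1 kOhm).
#' @param anode_area Anode working area in m^2 (default 1.649 cm^2).
#' @return An object of class `mfc_series`.
#' @export
mfc_series <- function(condition_id, samples,
                       external_resistance = 1000,
                       anode_area = 1.649e-4) {
  if (!all(c("time", "voltage") %in% names(samples)))
    ts_stop("invalid_series", "`samples` needs columns time, voltage")
  if (is.unsorted(samples$time, strictly = TRUE))
    ts_stop("invalid_series", "times must be strictly increasing")
  if (external_resistance <= 0 || anode_area <= 0)
    ts_stop("invalid_series", "resistance and anode area must be positive")
  structure(list(condition_id = condition_id, samples = samples,
                 external_resistance = external_resistance,
                 anode_area = anode_area),
            class = "mfc_series")
}

# The default dosing schedule and true fold amplifications: the water
# solvent-extracted tea profile (blank before dosing, six concentrations,
# blank after, dopamine standard), with a blank power density of 9.882
# mW/m^2.
.default_mfc_conditions <- function() {
  data.frame(
    condition_id = c("blank1", "250ppm", "500ppm", "750ppm", "1000ppm",
                     "1500ppm", "2000ppm", "blank2", "dopamine"),
    amplification = c(1.00, 1.65, 1.92, 2.04, 2.16, 2.24, 2.47, 1.22, 3.39),
    stringsAsFactors = FALSE)
}

#' Simulate MFC voltage time courses per condition
#'
#' For each condition, the voltage rises to a plateau chosen so that the
#' plateau power density equals `blank_pd * amplification` for that
#' condition (power density = V^2 / (R * A)), plus Gaussian noise. The
#' true amplification factors are recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @param conditions Data frame with `condition_id` and true
#'   `amplification` (fold vs the first blank); defaults to the
#'   water-extract dosing schedule.
#' @param blank_pd Blank plateau power density in mW/m^2.
#' @param noise_sd Voltage noise standard deviation in V.
#' @param duration,dt Series length and sampling step in seconds.
#' @param external_resistance,anode_area Circuit metadata (ohm, m^2).
#' @return A list with `series` (list of [mfc_series()]) and `truth`
#'   (the `conditions` table plus `blank_pd`, and the plateau window).
#' @export
#' @examples
#' sim <- simulate_mfc_series(sim_config(seed = 1), noise_sd = 0)
#' power_density(sim$series[["2000ppm"]])
simulate_mfc_series <- function(config,
                                conditions = .default_mfc_conditions(),
                                blank_pd = 9.882,
                                noise_sd = 0.001,
                                duration = 3600, dt = 30,
                                external_resistance = 1000,
                                anode_area = 1.649e-4) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "mfc"))
  if (any(conditions$amplification <= 0))
    ts_stop("invalid_config", "true amplifications must be positive")
  times <- seq(0, duration, by = dt)
  plateau_window <- c(0.6 * duration, duration)
  series <- lapply(seq_len(nrow(conditions)), function(i) {
    pd_w <- blank_pd * conditions$amplification[i] / 1000  # W/m^2
    v_plateau <- sqrt(pd_w * external_resistance * anode_area)
    v <- v_plateau * (1 - exp(-times / (0.08 * duration))) +
      rnorm(length(times), sd = noise_sd)
    mfc_series(conditions$condition_id[i],
               data.frame(time = times, voltage = v),
               external_resistance, anode_area)
  })
  names(series) <- conditions$condition_id
  list(series = series,
       truth = list(conditions = conditions, blank_pd = blank_pd,
                    plateau_window = plateau_window))
}

#' Voltammogram container
#'
#' Cyclic-voltammetry sweep points: per cycle, a forward (increasing
#' voltage) and a reverse (decreasing voltage) sweep of current readings.
#'
#' @param cycles Data frame with columns `cycle` (integer), `direction`
#'   (`"forward"`/`"reverse"`), `voltage` (V) and `current` (uA).
#' @param v_low,v_high Scan window limits in volts.
#' @param scan_rate Scan rate in mV/s (metadata only).
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(cycles, v_low = -1.5, v_high = 1.5, scan_rate = 10) {
  need <- c("cycle", "direction", "voltage", "current")
  if (!all(need %in% names(cycles)))
    ts_stop("invalid_voltammogram",
            paste("cycles must have columns:", paste(need, collapse = ", ")))
  if (v_low >= v_high)
    ts_stop("invalid_voltammogram", "v_low must be below v_high")
  if (any(cycles$voltage < v_low - 1e-9 | cycles$voltage > v_high + 1e-9))
    ts_stop("invalid_voltammogram", "sweep voltages outside [v_low, v_high]")
  if (!all(cycles$direction %in% c("forward", "reverse")))
    ts_stop("invalid_voltammogram", "direction must be forward/reverse")
  structure(list(cycles = cycles, v_low = v_low, v_high = v_high,
                 scan_rate = scan_rate),
            class = "voltammogram")
}

#' Simulate a multi-cycle voltammogram
#'
#' Each cycle consists of a forward and a reverse sweep sampled on the same
#' fixed voltage grid. The forward (oxidation) current is a rectangular
#' capacitive offset plus a Gaussian oxidation peak; the reverse
#' (reduction) current mirrors it with a reduction peak, emulating a
#' reversible redox couple. All currents of cycle `k` are scaled by
#' `decay^(k-1)`, so per-cycle closed-loop areas decay geometrically -
#' exactly, when `noise_sd = 0`.
#'
#' @param config A [sim_config()].
#' @param n_cycles Number of cycles.
#' @param decay Per-cycle attenuation factor (1 = no attenuation).
#' @param capacitive_gap Rectangular forward-reverse current gap in uA.
#' @param peak_center,peak_sd Gaussian peak position (V) and width (V); the
#'   reduction peak sits `peak_sep` volts below the oxidation peak.
#' @param peak_sep Oxidation-reduction peak separation in V.
#' @param step Voltage grid step in V (default 10 mV).
#' @param noise_sd Current noise in uA.
#' @return A list with `vgram` (a [voltammogram()]) and `truth`
#'   (`first_cycle_area` in uA.V from the closed form, and `decay`).
#' @export
#' @examples
#' sim <- simulate_voltammogram(sim_config(seed = 1), n_cycles = 3,
#'                              decay = 0.9)
#' area_profile(sim$vgram)$attenuation_ratio
simulate_voltammogram <- function(config, n_cycles = 50L, decay = 1,
                                  capacitive_gap = 10,
                                  peak_center = 0.3, peak_sd = 0.15,
                                  peak_sep = 0.08, step = 0.01,
                                  noise_sd = 0) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "cv"))
  v_low <- cfg$cv_scan_limits[1]
  v_high <- cfg$cv_scan_limits[2]
  grid <- seq(v_low, v_high, by = step)
  amp_ox <- cfg$cv_peak_current
  amp_red <- 0.8 * cfg$cv_peak_current

  i_fwd_base <- capacitive_gap / 2 +
    amp_ox * exp(-(grid - peak_center)^2 / (2 * peak_sd^2))
  i_rev_base <- -capacitive_gap / 2 -
    amp_red * exp(-(grid - (peak_center - peak_sep))^2 / (2 * peak_sd^2))

  rows <- lapply(seq_len(n_cycles), function(k) {
    scale <- decay^(k - 1)
    rbind(
      data.frame(cycle = k, direction = "forward", voltage = grid,
                 current = scale * i_fwd_base + rnorm(length(grid), sd = noise_sd)),
      data.frame(cycle = k, direction = "reverse", voltage = rev(grid),
                 current = scale * rev(i_rev_base) +
                   rnorm(length(grid), sd = noise_sd)))
  })
  vg <- voltammogram(do.call(rbind, rows), v_low, v_high)

  # Closed-form area of cycle 1: rectangle plus two truncated Gaussians.
  gauss_int <- function(amp, mu) {
    amp * peak_sd * sqrt(2 * pi) *
      (pnorm(v_high, mu, peak_sd) - pnorm(v_low, mu, peak_sd))
  }
  area1 <- capacitive_gap * (v_high - v_low) +
    gauss_int(amp_ox, peak_center) + gauss_int(amp_red, peak_center - peak_sep)

  list(vgram = vg, truth = list(first_cycle_area = area1, decay = decay))
}
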