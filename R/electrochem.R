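#' Power density of an MFC voltage series
#'
#' Per sample, the cell current is `I = V / R_ext` and the areal power is
#' `P = V * I / A_anode`; the record reports the mean and standard
#' deviation of `P` over a plateau window. Values are labelled mW/m^2 by
#' default (the conventional reporting scale for bench-top two-chamber
#' cells).
#'
#' @param series An [mfc_series()].
#' @param window Two-element numeric time interval (s) over which to
#'   average; defaults to the final 40% of the series.
#' @param unit `"mW/m2"` (default) or `"W/m2"`.
#' @return Data frame with one row: `condition_id`, `pd_mean`, `pd_sd`,
#'   `n`, `unit`.
#' @export
#' @examples
#' s <- mfc_series("test", data.frame(time = 1:10, voltage = 0.05))
#' power_density(s, window = c(1, 10), unit = "W/m2")$pd_mean
power_density <- function(series, window = NULL, unit = c("mW/m2", "W/m2")) {
  stopifnot(inherits(series, "mfc_series"))
  unit <- match.arg(unit)
  tt <- series$samples$time
  if (is.null(window)) window <- c(tt[1] + 0.6 * (tt[length(tt)] - tt[1]),
                                   tt[length(tt)])
  keep <- tt >= window[1] & tt <= window[2]
  if (!any(keep))
    ts_stop("no_data", "plateau window contains no samples")
  v <- series$samples$voltage[keep]
  p <- v * (v / series$external_resistance) / series$anode_area  # W/m^2
  if (unit == "mW/m2") p <- 1000 * p
  data.frame(condition_id = series$condition_id,
             pd_mean = mean(p),
             pd_sd = if (length(p) > 1L) sd(p) else 0,
             n = length(p),
             unit = unit,
             stringsAsFactors = FALSE)
}

#' Blank-normalised power-density amplification
#'
#' Fold amplification of each condition relative to the pre-dosing blank:
#' `amplification = pd_mean(condition) / pd_mean(blank)`. The ratio's
#' standard deviation is propagated to first order,
#' `sqrt((s_a/b)^2 + (a s_b / b^2)^2)`. The anode area and resistance
#' cancel, so amplification is scale-invariant to the cell geometry.
#'
#' @param records Data frame of [power_density()] rows (or any table with
#'   `condition_id`, `pd_mean`, `pd_sd`).
#' @param blank_id Condition id of the reference blank.
#' @return `records` with `amplification` and `amplification_sd` appended.
#' @export
#' @examples
#' pd <- data.frame(condition_id = c("blank1", "2000ppm"),
#'                  pd_mean = c(9.882, 24.374), pd_sd = c(0.494, 4.113))
#' amplification(pd)$amplification  # 1.00, 2.47 (2 d.p.)
amplification <- function(records, blank_id = "blank1") {
  if (!all(c("condition_id", "pd_mean", "pd_sd") %in% names(records)))
    ts_stop("invalid_records",
            "records need condition_id, pd_mean, pd_sd columns")
  i <- match(blank_id, records$condition_id)
  if (is.na(i))
    ts_stop("missing_reference",
            sprintf("blank condition '%s' not found", blank_id))
  b <- records$pd_mean[i]
  sb <- records$pd_sd[i]
  if (!is.finite(b) || b <= 0)
    ts_stop("missing_reference", "blank power density must be positive")
  a <- records$pd_mean
  sa <- records$pd_sd
  records$amplification <- a / b
  records$amplification_sd <- sqrt((sa / b)^2 + (a * sb / b^2)^2)
  records
}

#' Electron-shuttle presence rule
#'
#' A condition whose power-density amplification strictly exceeds the
#' threshold (default 2.00-fold) is flagged as indicating electron
#' shuttles: compounds whose ortho/para-dihydroxy aromatics mediate
#' reversible electron transfer strongly enough to at least double the
#' cell's power output.
#'
#' @param amplification Numeric fold amplification(s).
#' @param threshold Fold threshold (strict `>`).
#' @return Logical vector.
#' @export
#' @examples
#' es_presence(c(2.47, 1.40, 2.00))  # TRUE FALSE FALSE
es_presence <- function(amplification, threshold = 2.00) {
  amplification > threshold
}

# Interpolate one sweep direction of one cycle onto a uniform voltage grid.
.sweep_on_grid <- function(cyc, direction, grid) {
  sw <- cyc[cyc$direction == direction, ]
  sw <- sw[order(sw$voltage), ]
  sw <- sw[!duplicated(sw$voltage), ]
  approx(sw$voltage, sw$current, xout = grid, rule = 1)$y
}

#' Closed-loop area of one voltammetric cycle
#'
#' The oxidation (forward) and reduction (reverse) sweeps are interpolated
#' onto a common uniform voltage grid and the enclosed area is the
#' trapezoidal integral of `i_forward - i_reverse` from the low to the high
#' scan voltage. Sample ordering within a sweep is immaterial: sweeps are
#' sorted by voltage internally.
#'
#' @param vgram A [voltammogram()].
#' @param cycle Cycle index.
#' @param grid_step Interpolation grid step in volts (default 10 mV).
#' @param ih_direction Which sweep carries the oxidation current `i_h`
#'   (convention flag; default `"forward"`).
#' @return Closed-loop area in uA.V.
#' @export
cv_loop_area <- function(vgram, cycle = 1L, grid_step = 0.01,
                         ih_direction = c("forward", "reverse")) {
  stopifnot(inherits(vgram, "voltammogram"))
  ih_direction <- match.arg(ih_direction)
  il_direction <- setdiff(c("forward", "reverse"), ih_direction)
  cyc <- vgram$cycles[vgram$cycles$cycle == cycle, ]
  if (nrow(cyc) == 0L)
    ts_stop("malformed_cycle", sprintf("cycle %s not present", cycle))
  if (!all(c("forward", "reverse") %in% cyc$direction))
    ts_stop("malformed_cycle",
            sprintf("cycle %s lacks one sweep direction", cycle))
  rng_h <- range(cyc$voltage[cyc$direction == ih_direction])
  rng_l <- range(cyc$voltage[cyc$direction == il_direction])
  lo <- max(rng_h[1], rng_l[1])
  hi <- min(rng_h[2], rng_l[2])
  if (lo >= hi)
    ts_stop("no_overlap", "sweep voltage ranges do not overlap")
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  ih <- .sweep_on_grid(cyc, ih_direction, grid)
  il <- .sweep_on_grid(cyc, il_direction, grid)
  pracma::trapz(grid, ih - il)
}

#' Per-cycle area profile and attenuation of a voltammogram
#'
#' Computes the closed-loop area of every cycle, the attenuation ratio
#' `area(last) / area(first)`, and the stabilisation cycle: the first cycle
#' after which every successive relative area change is at most
#' `tolerance` (2% by default). Repeated identical cycles stabilise at
#' cycle 1; a profile that never settles reports `NA`.
#'
#' @param vgram A [voltammogram()].
#' @param tolerance Maximum relative change between successive cycles for
#'   the profile to count as stabilised.
#' @param ... Passed to [cv_loop_area()].
#' @return List of class `cv_area_profile`: `areas` (uA.V, one per cycle),
#'   `stabilization_cycle`, `attenuation_ratio`.
#' @export
area_profile <- function(vgram, tolerance = 0.02, ...) {
  stopifnot(inherits(vgram, "voltammogram"))
  cycles <- sort(unique(vgram$cycles$cycle))
  if (length(cycles) < 2L)
    ts_stop("insufficient_cycles", "area profile needs >= 2 cycles")
  areas <- vapply(cycles, function(k) cv_loop_area(vgram, k, ...), numeric(1))
  rel <- abs(diff(areas)) / abs(areas[-length(areas)])
  ok <- rev(cumprod(rev(rel <= tolerance))) == 1  # all subsequent changes small
  stab <- if (any(ok)) cycles[which(ok)[1]] else NA_integer_
  structure(list(areas = setNames(areas, cycles),
                 stabilization_cycle = stab,
                 attenuation_ratio = areas[length(areas)] / areas[1]),
            class = "cv_area_profile")
}

#' @export
print.cv_area_profile <- function(x, ...) {
  cat("<cv_area_profile>", length(x$areas), "cycles; attenuation",
      sprintf("%.3f;", x$attenuation_ratio), "stabilised at cycle",
      x$stabilization_cycle, "\n")
  invisible(x)
}
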