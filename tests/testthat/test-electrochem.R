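test_that("power density follows P = V^2 / (R * A)", {
  s <- mfc_series("flat", data.frame(time = 0:9, voltage = 0.05),
                  external_resistance = 1000, anode_area = 1.649e-4)
  pd <- power_density(s, window = c(0, 9), unit = "W/m2")
  expect_equal(pd$pd_mean, 0.05 * (0.05 / 1000) / 1.649e-4, tolerance = 1e-12)
  expect_equal(pd$pd_sd, 0)

  zero <- mfc_series("z", data.frame(time = 0:9, voltage = 0))
  expect_equal(power_density(zero, c(0, 9))$pd_mean, 0)

  dbl <- mfc_series("d", data.frame(time = 0:9, voltage = 0.10),
                    external_resistance = 1000, anode_area = 1.649e-4)
  expect_equal(power_density(dbl, c(0, 9), "W/m2")$pd_mean,
               4 * pd$pd_mean, tolerance = 1e-12)
  expect_error(power_density(s, window = c(100, 200)), class = "no_data")
})

test_that("amplification normalises by the first blank and propagates SD", {
  rec <- data.frame(condition_id = c("blank1", "c1"),
                    pd_mean = c(10, 25), pd_sd = c(1, 2))
  out <- amplification(rec)
  expect_equal(out$amplification, c(1, 2.5))
  expect_equal(out$amplification_sd[2],
               sqrt((2 / 10)^2 + (25 * 1 / 100)^2), tolerance = 1e-12)
  expect_error(amplification(rec, blank_id = "nope"),
               class = "missing_reference")
})

test_that("amplification is invariant to the anode area", {
  mk <- function(area) {
    lapply(c(blank1 = 0.03, dose = 0.05), function(v)
      mfc_series("x", data.frame(time = 0:9, voltage = v), anode_area = area))
  }
  amp_of <- function(area) {
    s <- mk(area)
    pd <- rbind(power_density(s[[1]], c(0, 9)), power_density(s[[2]], c(0, 9)))
    pd$condition_id <- c("blank1", "dose")
    amplification(pd)$amplification[2]
  }
  expect_equal(amp_of(1e-4), amp_of(5e-4), tolerance = 1e-12)
})

test_that("the electron-shuttle rule is a strict 2.00-fold threshold", {
  expect_identical(es_presence(c(2.47, 1.40, 2.00, 2.0001)),
                   c(TRUE, FALSE, FALSE, TRUE))
})

test_that("closed-loop area of a constant gap is the exact rectangle", {
  grid <- seq(-1.5, 1.5, by = 0.01)
  cyc <- rbind(
    data.frame(cycle = 1, direction = "forward", voltage = grid, current = 1),
    data.frame(cycle = 1, direction = "reverse", voltage = rev(grid),
               current = -1))
  vg <- voltammogram(cyc)
  expect_equal(cv_loop_area(vg, 1), 2 * 3, tolerance = 1e-9)

  flat <- cyc
  flat$current <- 0.7
  expect_equal(cv_loop_area(voltammogram(flat), 1), 0, tolerance = 1e-12)
})

test_that("loop area is invariant to sweep sample ordering", {
  sim <- simulate_voltammogram(sim_config(seed = 8), n_cycles = 1)
  a1 <- cv_loop_area(sim$vgram, 1)
  shuffled <- sim$vgram
  set.seed(1)
  shuffled$cycles <- shuffled$cycles[sample(nrow(shuffled$cycles)), ]
  expect_equal(cv_loop_area(shuffled, 1), a1, tolerance = 1e-12)
})

test_that("trapezoidal loop area matches a fine-grid quadrature reference", {
  cfg <- sim_config(seed = 8, cv_peak_current = 40)
  sim <- simulate_voltammogram(cfg, n_cycles = 1, capacitive_gap = 12,
                               peak_center = 0.3, peak_sd = 0.15,
                               peak_sep = 0.08)
  f_fwd <- function(v) 6 + 40 * exp(-(v - 0.3)^2 / (2 * 0.15^2))
  f_rev <- function(v) -6 - 32 * exp(-(v - 0.22)^2 / (2 * 0.15^2))
  ref <- quadrature_oracle(f_fwd, f_rev, -1.5, 1.5, n = 2e5)
  expect_lt(abs(cv_loop_area(sim$vgram, 1) / ref - 1), 0.001)
})

test_that("malformed cycles are rejected", {
  grid <- seq(-1, 1, by = 0.1)
  one_dir <- data.frame(cycle = 1, direction = "forward", voltage = grid,
                        current = 1)
  vg <- voltammogram(one_dir, v_low = -1, v_high = 1)
  expect_error(cv_loop_area(vg, 1), class = "malformed_cycle")
  expect_error(cv_loop_area(vg, 2), class = "malformed_cycle")
})

test_that("area profile finds the stabilisation cycle by construction", {
  grid <- seq(-1, 1, by = 0.05)
  mk_cycle <- function(k, gap) rbind(
    data.frame(cycle = k, direction = "forward", voltage = grid,
               current = gap / 2),
    data.frame(cycle = k, direction = "reverse", voltage = rev(grid),
               current = -gap / 2))
  # decays for 3 cycles then constant from cycle 4
  gaps <- c(8, 6, 4.5, 4, 4, 4)
  vg <- voltammogram(do.call(rbind, Map(mk_cycle, seq_along(gaps), gaps)),
                     v_low = -1, v_high = 1)
  prof <- area_profile(vg)
  expect_equal(unname(prof$stabilization_cycle), 4)
  expect_equal(unname(prof$attenuation_ratio), 4 / 8, tolerance = 1e-12)

  never <- simulate_voltammogram(sim_config(seed = 2), n_cycles = 4,
                                 decay = 0.8)
  expect_true(is.na(area_profile(never$vgram)$stabilization_cycle))
})

test_that("MFC and CV tables round-trip through their CSV formats", {
  cfg <- sim_config(seed = 5)
  mfc <- simulate_mfc_series(cfg, conditions = data.frame(
    condition_id = c("blank1", "dose"), amplification = c(1, 2)))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_mfc_csv(mfc$series, p1)
  back <- read_mfc_csv(p1)
  expect_equal(names(back), c("blank1", "dose"))
  expect_equal(back$dose$samples$voltage, mfc$series$dose$samples$voltage,
               tolerance = 1e-12)

  cv <- simulate_voltammogram(cfg, n_cycles = 2)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cv_csv(cv$vgram, p2)
  back2 <- read_cv_csv(p2)
  expect_equal(cv_loop_area(back2, 2), cv_loop_area(cv$vgram, 2),
               tolerance = 1e-12)
})
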