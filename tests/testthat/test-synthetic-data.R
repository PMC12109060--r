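test_that("every generator is bit-for-bit reproducible under one seed", {
  cfg <- sim_config(seed = 11, n_genes = 80, n_spiked = 8,
                    group_sizes = c(TNBC = 6, normal = 5),
                    n_compounds = 10, ppi_nodes = 20)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_compound_library(cfg), simulate_compound_library(cfg))
  expect_identical(simulate_ppi(cfg), simulate_ppi(cfg))
  expect_identical(simulate_plate(cfg, "TFC"), simulate_plate(cfg, "TFC"))
  expect_identical(simulate_mfc_series(cfg), simulate_mfc_series(cfg))
  expect_identical(simulate_voltammogram(cfg, n_cycles = 2),
                   simulate_voltammogram(cfg, n_cycles = 2))
})

test_that("generators draw from independent child streams", {
  cfg <- sim_config(seed = 11, n_genes = 40, n_spiked = 4,
                    group_sizes = c(TNBC = 4, normal = 4), n_compounds = 8)
  e1 <- simulate_expression(cfg)
  invisible(simulate_compound_library(cfg))  # consuming another stream
  expect_identical(e1, simulate_expression(cfg))
})

test_that("spiked genes shift by the configured effect within analytic error", {
  cfg <- sim_config(seed = 7, n_genes = 400, n_spiked = 40, spike_log2fc = 2,
                    noise_sd = 0.3, group_sizes = c(TNBC = 30, normal = 11))
  sim <- simulate_expression(cfg)
  cls <- sim$study$sample_classes
  se <- cfg$noise_sd * sqrt(1 / 30 + 1 / 11)
  for (ids in list(sim$truth$spiked_up, sim$truth$spiked_down)) {
    d <- rowMeans(sim$study$matrix[ids, cls == "TNBC", drop = FALSE]) -
      rowMeans(sim$study$matrix[ids, cls == "normal", drop = FALSE])
    sgn <- if (identical(ids, sim$truth$spiked_up)) 1 else -1
    expect_true(all(abs(d - sgn * 2) < 3 * se))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_spiked = 50, n_genes = 10), class = "invalid_config")
  expect_error(sim_config(frac_es_positive = 1.2), class = "invalid_config")
  expect_error(sim_config(cv_scan_limits = c(1, -1)), class = "invalid_config")
  expect_error(sim_config(group_sizes = c(TNBC = 5)), class = "invalid_config")
})

test_that("compound ground-truth labels are consistent with the emitted SMILES", {
  for (frac in c(0, 0.5, 1)) {
    lib <- simulate_compound_library(
      sim_config(seed = 3, n_compounds = 16, frac_es_positive = frac))
    expect_equal(mean(lib$truth$es_positive), frac)
    cls <- es_classify(lib$compounds$smiles)
    expect_identical(cls$es_positive, lib$truth$es_positive)
  }
})

test_that("planted clique edges are present and above the confidence cutoff", {
  cfg <- sim_config(seed = 9, ppi_nodes = 25, planted_clique_size = 5,
                    ppi_edge_prob = 0.05)
  sim <- simulate_ppi(cfg)
  members <- sim$truth$clique_members
  pairs <- t(combn(members, 2))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(sim$edges$protein1, sim$edges$protein2)
  want <- key(pairs[, 1], pairs[, 2])
  expect_true(all(want %in% have))
  clq <- have %in% want
  expect_true(all(sim$edges$combined_score[clq] >= 700))
  expect_true(all(sim$edges$combined_score >= 0 &
                    sim$edges$combined_score <= 1000))
})

test_that("noise-free plates invert exactly and noisy slopes recover on average", {
  cfg0 <- sim_config(seed = 1, plate_noise_sd = 0)
  pl <- simulate_plate(cfg0, "TCTC")
  curve <- fit_calibration(pl$plate)
  expect_equal(curve$slope, pl$truth$slope, tolerance = 1e-12)
  expect_equal(curve$intercept, pl$truth$intercept, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)

  dp <- dpph_summary(simulate_plate(cfg0, "DPPH", true_ic50 = 0.075)$plate)
  expect_equal(dp$ic50, 0.075, tolerance = 1e-12)

  slopes <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = s, plate_noise_sd = 0.01)
    fit_calibration(simulate_plate(cfg, "TPC")$plate)$slope
  }, numeric(1))
  expect_true(all(abs(slopes / 3.8354 - 1) < 0.05))
})

test_that("MFC plateaus reproduce the configured amplification", {
  cfg <- sim_config(seed = 2)
  conds <- data.frame(condition_id = c("blank1", "dose"),
                      amplification = c(1, 2))
  sim <- simulate_mfc_series(cfg, conditions = conds, noise_sd = 0)
  pd <- amplification(do.call(rbind, lapply(sim$series, power_density,
                                            window = c(3000, 3600))))
  expect_equal(pd$amplification[pd$condition_id == "dose"], 2, tolerance = 1e-4)

  noisy <- simulate_mfc_series(cfg, conditions = conds, noise_sd = 0.002)
  pdn <- amplification(do.call(rbind, lapply(noisy$series, power_density,
                                             window = c(3000, 3600))))
  a <- pdn[pdn$condition_id == "dose", ]
  expect_lt(abs(a$amplification - 2), 3 * a$amplification_sd + 0.05)
})

test_that("voltammogram cycles decay geometrically and match the closed form", {
  cfg <- sim_config(seed = 4)
  sim <- simulate_voltammogram(cfg, n_cycles = 5, decay = 0.9)
  prof <- area_profile(sim$vgram)
  expect_equal(unname(prof$attenuation_ratio), 0.9^4, tolerance = 1e-9)
  expect_equal(unname(prof$areas[1]), sim$truth$first_cycle_area,
               tolerance = 1e-3)
  same <- simulate_voltammogram(cfg, n_cycles = 4, decay = 1)
  prof1 <- area_profile(same$vgram)
  expect_equal(unname(prof1$stabilization_cycle), 1)
  expect_equal(unname(prof1$attenuation_ratio), 1, tolerance = 1e-12)
})
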