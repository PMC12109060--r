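small_study <- function(seed = 1, n_genes = 60, n1 = 6, n2 = 5,
                        n_spiked = 0, lfc = 2, sd = 0.3) {
  simulate_expression(sim_config(seed = seed, n_genes = n_genes,
                                 n_spiked = n_spiked, spike_log2fc = lfc,
                                 noise_sd = sd,
                                 group_sizes = c(TNBC = n1, normal = n2)))
}

test_that("normalisation log-transforms linear data and equalises quantiles", {
  sim <- small_study()
  expect_identical(normalize_expression(sim$study)$matrix, sim$study$matrix)

  linear <- expression_study(2^sim$study$matrix, sim$study$sample_classes,
                             already_logged = FALSE)
  norm <- normalize_expression(linear)
  expect_true(max(norm$matrix) < 50)

  qn <- normalize_expression(sim$study, quantile = TRUE)
  sorted <- apply(qn$matrix, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("with zero prior df the moderated t equals the pooled t-test", {
  sim <- small_study(seed = 2, n_genes = 25)
  recs <- moderated_t(sim$study, "TNBC", prior_df = 0)
  cls <- sim$study$sample_classes
  ref <- pooled_t_oracle(sim$study$matrix[, cls == "TNBC"],
                         sim$study$matrix[, cls == "normal"])
  expect_equal(recs$t_stat, unname(ref$t), tolerance = 1e-10)
  expect_equal(recs$p_value, unname(ref$p), tolerance = 1e-10)
  expect_equal(recs$adj_p, bh_oracle(unname(ref$p)), tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up procedure by hand", {
  # four genes engineered to give a known p-vector shape
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))  # documented worked example
  set.seed(3)
  p2 <- runif(40)
  expect_equal(p.adjust(p2, "BH"), bh_oracle(p2), tolerance = 1e-14)
})

test_that("a gene with identical group means gets t = 0 and p = 1", {
  sim <- small_study(seed = 4, n_genes = 20)
  m <- sim$study$matrix
  cls <- sim$study$sample_classes
  m[1, ] <- 7                                   # constant gene
  m[2, cls == "TNBC"] <- m[2, cls == "TNBC"] -
    mean(m[2, cls == "TNBC"]) + mean(m[2, cls == "normal"])
  study <- expression_study(m, cls)
  recs <- moderated_t(study, "TNBC")
  expect_equal(recs$t_stat[1:2], c(0, 0), tolerance = 1e-10)
  expect_equal(recs$p_value[1:2], c(1, 1), tolerance = 1e-10)
})

test_that("moderated statistics track limma on a common dataset", {
  skip_if_not_installed("limma")
  sim <- small_study(seed = 5, n_genes = 300, n_spiked = 30)
  cls <- sim$study$sample_classes
  design <- cbind(1, cls == "TNBC")
  fit <- limma::eBayes(limma::lmFit(sim$study$matrix, design))
  recs <- moderated_t(sim$study, "TNBC")
  expect_equal(recs$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(cor(recs$t_stat, fit$t[, 2]), 0.999)
  expect_gt(cor(-log10(recs$p_value), -log10(fit$p.value[, 2])), 0.999)
})

test_that("swapping class labels negates every log fold change", {
  sim <- small_study(seed = 6, n_genes = 40, n_spiked = 6)
  fwd <- moderated_t(sim$study, "TNBC", reference = "normal")
  rev <- moderated_t(sim$study, "normal", reference = "TNBC")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
})

test_that("DEG calls apply strict thresholds on both criteria", {
  recs <- data.frame(gene = c("a", "b", "c", "d"),
                     log2fc = c(2, 2, 0.1, -2),
                     signed_fc = c(4, 4, 1.07, -4),
                     t_stat = 0, p_value = 0,
                     adj_p = c(0.05, 0.01, 0.01, 0.01))
  out <- call_degs(recs)
  expect_identical(out$call, c("ns", "up", "ns", "down"))
  border <- data.frame(gene = "e", log2fc = log2(1.5), signed_fc = 1.5,
                       t_stat = 0, p_value = 0, adj_p = 0.001)
  expect_identical(call_degs(border)$call, "ns")  # fc strictly > 1.5
})

test_that("spiked genes are recovered in direction and magnitude", {
  sim <- small_study(seed = 7, n_genes = 500, n1 = 30, n2 = 11,
                     n_spiked = 50, lfc = 2, sd = 0.3)
  recs <- call_degs(moderated_t(sim$study, "TNBC"))
  up_ok <- mean(recs$call[match(sim$truth$spiked_up, recs$gene)] == "up")
  dn_ok <- mean(recs$call[match(sim$truth$spiked_down, recs$gene)] == "down")
  expect_gte(up_ok, 0.95)
  expect_gte(dn_ok, 0.95)
  est <- recs$log2fc[match(sim$truth$spiked_up, recs$gene)]
  expect_lt(abs(median(est) - 2), 0.1)
})

test_that("duplicate probes collapse to the smallest raw p per gene", {
  recs <- data.frame(gene = c("g1", "g1", "g2"),
                     log2fc = c(1, 2, 0), signed_fc = c(2, 4, 1),
                     t_stat = 0, p_value = c(0.5, 0.01, 0.2),
                     adj_p = c(0.5, 0.02, 0.2))
  out <- collapse_probes(recs)
  expect_equal(nrow(out), 2)
  expect_equal(out$p_value[out$gene == "g1"], 0.01)
})

test_that("target qualification applies the per-source probability rules", {
  preds <- data.frame(
    compound_id = "c1",
    gene = c("A", "B", "C", "D", "E"),
    probability = c(0.10, 0.09, 0.60, 0.60, 0.95),
    source = c("swiss_like", "swiss_like", "super_like", "super_like",
               "super_like"),
    model_accuracy = c(NA, NA, 0.90, 0.89, NA))
  q <- qualify_targets(preds)
  expect_identical(q$pooled, c("A", "C"))  # boundary keeps, low acc drops

  set.seed(8)
  tbl <- simulate_target_predictions(sim_config(seed = 8, n_compounds = 6),
                                     genes = sprintf("G%02d", 1:30))
  q2 <- qualify_targets(tbl)
  keep <- (tbl$source == "swiss_like" & tbl$probability >= 0.10) |
    (tbl$source == "super_like" & tbl$probability >= 0.60 &
       tbl$model_accuracy >= 0.90)
  expect_identical(q2$pooled, sort(unique(tbl$gene[keep])))
})

test_that("DEG/target overlap is a plain sorted intersection", {
  recs <- data.frame(gene = c("A", "B", "C", "D"),
                     log2fc = c(2, 2, -2, 2), signed_fc = c(4, 4, -4, 4),
                     t_stat = 0, p_value = 0, adj_p = 0.01,
                     call = c("up", "up", "down", "up"))
  expect_identical(overlap_targets(recs, c("B", "C", "Z"), "up"), "B")
  expect_identical(overlap_targets(recs, c("B", "C", "Z"), "down"), "C")
  expect_identical(overlap_targets(recs, "Q", "up"), character(0))
  expect_identical(overlap_targets(recs, c("D", "A", "B", "C"), "up"),
                   c("A", "B", "D"))
})

test_that("null data keeps the positive rate at the nominal level", {
  rates <- vapply(1:20, function(s) {
    sim <- small_study(seed = s, n_genes = 400, n1 = 10, n2 = 8, n_spiked = 0)
    recs <- moderated_t(sim$study, "TNBC")
    mean(recs$adj_p < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (20 * 400))
  expect_lte(mean(rates), 0.05 + 3 * se)
})

test_that("expression studies round-trip through TSV/CSV files", {
  sim <- small_study(seed = 9, n_genes = 15)
  mp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_expression_tsv(sim$study, mp, cp)
  back <- read_expression_tsv(mp, cp)
  expect_equal(back$matrix, sim$study$matrix, tolerance = 1e-6)
  expect_identical(unname(back$sample_classes),
                   unname(sim$study$sample_classes))
})
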