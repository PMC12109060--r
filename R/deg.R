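#' Normalise an expression study
#'
#' Applies a log2 transform when the values look linear-scale (maximum
#' above `log_threshold`, unless `already_logged` says otherwise) and,
#' optionally, quantile normalisation across samples so every column shares
#' the same empirical distribution.
#'
#' @param study An [expression_study()].
#' @param quantile Apply quantile normalisation across samples.
#' @param log_threshold Heuristic: matrices whose maximum exceeds this are
#'   treated as linear scale and log2-transformed (after a +1 offset
#'   guarding zeros).
#' @return A normalised [expression_study()] with `already_logged = TRUE`.
#' @export
normalize_expression <- function(study, quantile = FALSE, log_threshold = 50) {
  stopifnot(inherits(study, "expression_study"))
  mat <- study$matrix
  if (!study$already_logged || max(mat, na.rm = TRUE) > log_threshold)
    mat <- log2(pmax(mat, 0) + 1)
  if (quantile) {
    ranks <- apply(mat, 2, rank, ties.method = "first")
    means <- rowMeans(apply(mat, 2, sort))
    mat <- apply(ranks, 2, function(r) means[r])
    dimnames(mat) <- dimnames(study$matrix)
  }
  expression_study(mat, study$sample_classes, already_logged = TRUE)
}

# Newton solve of trigamma(y) = x, vectorised; used to fit the prior
# degrees of freedom of the variance distribution by matching log-variance
# moments across genes.
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Method-of-moments fit of the scaled-F model s^2 ~ s0^2 * F(df, d0) on the
# log scale: Var[log s^2] = trigamma(df/2) + trigamma(d0/2) and
# E[log s^2] = log s0^2 + digamma(df/2) - log(df/2) - digamma(d0/2) +
# log(d0/2).
.fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  e <- log(s2[ok])
  evar <- var(e)
  excess <- evar - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-8) {
    d0 <- Inf
    s0_2 <- exp(mean(e) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(excess)
    s0_2 <- exp(mean(e) - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated two-group t-tests per gene
#'
#' For one tumour subtype against the reference class: per gene, the effect
#' is the mean log2 difference; the pooled within-group variance is shrunk
#' towards a prior variance `s0^2` with prior degrees of freedom `d0`, both
#' fitted across genes by matching the moments of the log variances under a
#' scaled-F model. The moderated statistic
#' `t = log2fc / (s_tilde * sqrt(1/n1 + 1/n2))` with
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` is referred to a t
#' distribution on `d + d0` degrees of freedom, and p-values are
#' Benjamini-Hochberg adjusted across all genes of the contrast. With
#' `prior_df = 0` the statistic reduces exactly to the ordinary pooled
#' two-sample t-test.
#'
#' The signed linear fold change reported alongside follows the microarray
#' convention `signed_fc = 2^log2fc` for positive effects and
#' `-2^(-log2fc)` for negative ones.
#'
#' @param study An [expression_study()] (log2 scale).
#' @param subtype Class label of the tumour group.
#' @param reference Class label of the reference group (default
#'   `"normal"`).
#' @param prior_df `NULL` to estimate the prior degrees of freedom from the
#'   data (default); a number to fix them (0 = unmoderated pooled t).
#' @return Data frame with `gene`, `log2fc`, `signed_fc`, `t_stat`,
#'   `p_value`, `adj_p`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 50,
#'   n_spiked = 4, group_sizes = c(TNBC = 10, normal = 8)))
#' head(moderated_t(sim$study, "TNBC"))
moderated_t <- function(study, subtype, reference = "normal",
                        prior_df = NULL) {
  stopifnot(inherits(study, "expression_study"))
  cls <- study$sample_classes
  g1 <- which(cls == subtype)
  g2 <- which(cls == reference)
  if (length(g1) < 2L || length(g2) < 2L)
    ts_stop("insufficient_replicates",
            sprintf("classes '%s' and '%s' each need >= 2 samples",
                    subtype, reference))
  x1 <- study$matrix[, g1, drop = FALSE]
  x2 <- study$matrix[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  lfc <- m1 - m2

  if (is.null(prior_df)) {
    prior <- .fit_variance_prior(s2, df)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_2 = 0)
  } else {
    prior <- list(d0 = prior_df, s0_2 = mean(s2[s2 > 0]))
  }
  d0 <- prior$d0
  s_tilde2 <- if (is.infinite(d0)) rep(prior$s0_2, length(s2)) else
    (d0 * prior$s0_2 + df * s2) / (d0 + df)
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se == 0, ifelse(lfc == 0, 0, sign(lfc) * Inf), lfc / se)
  df_total <- if (is.infinite(d0)) Inf else df + d0
  p <- 2 * pt(-abs(tt), df = df_total)

  data.frame(
    gene = rownames(study$matrix),
    log2fc = lfc,
    signed_fc = ifelse(lfc >= 0, 2^lfc, -2^(-lfc)),
    t_stat = tt,
    p_value = p,
    adj_p = p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Applies the published thresholds: a gene is `up` when its adjusted
#' p-value is below `alpha` and its signed linear fold change exceeds `fc`,
#' `down` when the adjusted p-value is below `alpha` and the signed fold
#' change is below `-fc`, and `ns` otherwise. All inequalities are strict.
#' With `fc_scale = "log2"` the threshold is applied to `log2fc` instead,
#' since the fold-change convention of array pipelines is ambiguous.
#'
#' @param records Output of [moderated_t()].
#' @param alpha Adjusted-p cutoff (strict `<`).
#' @param fc Fold-change magnitude cutoff (strict).
#' @param fc_scale `"linear"` (signed fold change) or `"log2"`.
#' @return `records` with a `call` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_degs <- function(records, alpha = 0.05, fc = 1.5,
                      fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  eff <- if (fc_scale == "linear") records$signed_fc else records$log2fc
  records$call <- ifelse(records$adj_p < alpha & eff > fc, "up",
                  ifelse(records$adj_p < alpha & eff < -fc, "down", "ns"))
  records
}

#' Collapse multi-probe genes to one record
#'
#' Arrays measure many genes with several probes; before overlapping gene
#' sets, duplicate gene symbols are collapsed by keeping the record with
#' the smallest raw p-value per gene.
#'
#' @param records Output of [moderated_t()] (optionally after
#'   [call_degs()]).
#' @return Deduplicated records.
#' @export
collapse_probes <- function(records) {
  ord <- order(records$gene, records$p_value)
  records <- records[ord, ]
  records[!duplicated(records$gene), , drop = FALSE]
}

#' Qualify predicted compound targets
#'
#' Applies the target-prediction probability rules: ligand-similarity
#' (`swiss_like`) rows are kept at probability >= `swiss_min` (non-strict)
#' and `super_like` rows at probability >= `super_min` together with a
#' model accuracy >= `accuracy_min`.
#'
#' @param predictions Data frame with `compound_id`, `gene`, `probability`,
#'   `source` and (for `super_like` rows) `model_accuracy`.
#' @param swiss_min,super_min,accuracy_min Thresholds.
#' @return List with `per_compound` (named list of sorted gene vectors) and
#'   `pooled` (sorted union across compounds).
#' @export
qualify_targets <- function(predictions, swiss_min = 0.10, super_min = 0.60,
                            accuracy_min = 0.90) {
  need <- c("compound_id", "gene", "probability", "source")
  if (!all(need %in% names(predictions)))
    ts_stop("invalid_predictions",
            paste("predictions need columns:", paste(need, collapse = ", ")))
  keep <- (predictions$source == "swiss_like" &
             predictions$probability >= swiss_min) |
          (predictions$source == "super_like" &
             predictions$probability >= super_min &
             !is.na(predictions$model_accuracy) &
             predictions$model_accuracy >= accuracy_min)
  kept <- predictions[keep, , drop = FALSE]
  per <- lapply(split(kept$gene, kept$compound_id), function(g) sort(unique(g)))
  list(per_compound = per, pooled = sort(unique(kept$gene)))
}

#' Overlap DEG calls with qualified target genes
#'
#' The intersection of the genes called in one direction for one subtype
#' with the pooled qualified target genes of the compound library - the
#' subtype's compound-targetable deregulated gene set.
#'
#' @param records [call_degs()] output (probe-collapsed).
#' @param target_genes Character vector of qualified target genes.
#' @param direction `"up"` or `"down"`.
#' @return Sorted character vector of overlapping genes.
#' @export
overlap_targets <- function(records, target_genes,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!"call" %in% names(records))
    ts_stop("invalid_records", "run call_degs() before overlapping")
  sort(intersect(records$gene[records$call == direction],
                 unique(target_genes)))
}
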