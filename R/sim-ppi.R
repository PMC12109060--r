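#' Simulate a STRING-dialect interaction edge list
#'
#' Draws an Erdos-Renyi background graph on `ppi_nodes` genes with edge
#' probability `ppi_edge_prob` and background confidence scores uniform on
#' 150-1000, then plants one fully connected clique of
#' `planted_clique_size` members whose edges all score above the 70%
#' confidence cutoff (850-1000). Clique membership is recorded as ground
#' truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `edges` (data frame `protein1`, `protein2`,
#'   `combined_score` on the 0-1000 STRING scale) and `truth` (list with
#'   `clique_members`).
#' @export
#' @examples
#' sim <- simulate_ppi(sim_config(seed = 1, ppi_nodes = 20,
#'                                planted_clique_size = 5))
#' head(sim$edges)
simulate_ppi <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "ppi"))

  nodes <- sprintf("G%04d", seq_len(cfg$ppi_nodes))
  clique <- sort(sample(nodes, cfg$planted_clique_size))

  pairs <- if (cfg$ppi_nodes >= 2L) t(combn(nodes, 2L)) else
    matrix(character(0), ncol = 2L)
  in_clique <- pairs[, 1] %in% clique & pairs[, 2] %in% clique

  keep_bg <- runif(nrow(pairs)) < cfg$ppi_edge_prob & !in_clique
  keep <- keep_bg | in_clique
  edges <- data.frame(protein1 = pairs[keep, 1],
                      protein2 = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  score <- numeric(nrow(edges))
  clq <- edges$protein1 %in% clique & edges$protein2 %in% clique
  score[clq] <- round(runif(sum(clq), 850, 1000))
  score[!clq] <- round(runif(sum(!clq), 150, 1000))
  edges$combined_score <- as.integer(score)

  list(edges = edges, truth = list(clique_members = clique))
}

#' Simulate a GO-style annotation database
#'
#' Builds a gene-set collection over a given gene universe: random terms of
#' varying size across the three GO domains, plus (optionally) one term per
#' domain concentrated on a designated gene set so that enrichment is
#' recoverable by construction.
#'
#' @param config A [sim_config()].
#' @param genes Character vector, the annotation universe.
#' @param n_terms Number of random terms to draw.
#' @param enriched_genes Optional character vector; when supplied, three
#'   additional terms (`SIM:ENRICH_BP/CC/MF`) consist mostly of these genes.
#' @return A `gene_set_db` (see [gene_set_db()]).
#' @export
simulate_gene_sets <- function(config, genes, n_terms = 50L,
                               enriched_genes = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(child_seed(cfg, "gene_sets"))
  cats <- c("BP", "CC", "MF")
  sets <- lapply(seq_len(n_terms), function(i) {
    size <- sample(5:min(40L, max(5L, length(genes) %/% 2L)), 1L)
    sort(sample(genes, size))
  })
  names(sets) <- sprintf("SIM:%04d", seq_len(n_terms))
  category <- setNames(sample(cats, n_terms, replace = TRUE), names(sets))
  if (!is.null(enriched_genes)) {
    enriched_genes <- intersect(enriched_genes, genes)
    for (cat in cats) {
      id <- paste0("SIM:ENRICH_", cat)
      pad <- sample(setdiff(genes, enriched_genes),
                    max(1L, length(enriched_genes) %/% 4L))
      sets[[id]] <- sort(unique(c(enriched_genes, pad)))
      category[id] <- cat
    }
  }
  gene_set_db(sets, category = category, universe = genes)
}
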