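#' Gene-set database container
#'
#' A named list of gene sets (GO terms), each with a category among the
#' three GO domains, plus the annotation universe against which
#' over-representation is assessed.
#'
#' @param sets Named list of character vectors (term id -> genes).
#' @param category Named character vector of `"BP"`, `"CC"`, `"MF"` (or
#'   `NA`) per term; defaults to all `NA`.
#' @param universe Character vector of background genes; defaults to the
#'   union of all sets.
#' @param description Optional named character vector of term names.
#' @return An object of class `gene_set_db`.
#' @export
gene_set_db <- function(sets, category = NULL, universe = NULL,
                        description = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    ts_stop("invalid_db", "gene sets must be named by term id")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  if (!length(universe)) ts_stop("invalid_db", "annotation universe is empty")
  sets <- lapply(sets, function(g) sort(unique(intersect(g, universe))))
  if (is.null(category))
    category <- setNames(rep(NA_character_, length(sets)), names(sets))
  bad <- !is.na(category) & !category %in% c("BP", "CC", "MF")
  if (any(bad))
    ts_stop("invalid_db", "categories must be BP, CC or MF")
  structure(list(sets = sets, category = category,
                 universe = sort(unique(universe)),
                 description = description),
            class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat("<gene_set_db>", length(x$sets), "terms over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Read a GMT annotation file
#'
#' Tab-separated lines of `term_id`, `description`, then member genes. A
#' description equal to `BP`, `CC` or `MF` (or ending in `|BP` etc.) is
#' taken as the GO category.
#'
#' @param path GMT file path.
#' @param universe Optional background gene vector; defaults to all genes
#'   seen in the file.
#' @return A [gene_set_db()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3L
  if (any(short))
    ts_stop("parse_error",
            sprintf("GMT line(s) with fewer than 3 fields: %s",
                    paste(head(which(short), 5L), collapse = ", ")))
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  cat_raw <- sub("^.*\\|", "", desc)
  category <- setNames(ifelse(cat_raw %in% c("BP", "CC", "MF"),
                              cat_raw, NA_character_), ids)
  gene_set_db(sets, category = category, universe = universe,
              description = setNames(desc, ids))
}

#' Write a gene-set database to GMT
#'
#' @param db A [gene_set_db()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  lines <- vapply(names(db$sets), function(id) {
    desc <- if (!is.null(db$description) && id %in% names(db$description))
      db$description[[id]] else if (!is.na(db$category[[id]]))
        db$category[[id]] else "NA"
    paste(c(id, desc, db$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For every term sharing at least one gene with the query, the upper-tail
#' hypergeometric probability of observing at least the seen overlap:
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)` for a universe of `N` genes,
#' `K` of them in the term and a query of `n` genes. Fold enrichment is
#' `(k / n) / (K / N)`. The optional EASE variant discounts one overlapping
#' gene in the tail computation (`P(X >= k - 1)` evaluated at `k - 1`),
#' giving the more conservative score some annotation servers report.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of genes.
#' @param db A [gene_set_db()].
#' @param ease Use the EASE-style discounted overlap.
#' @return Data frame of class rows: `term_id`, `category`, `n_query`,
#'   `n_term`, `n_overlap`, `fold_enrichment`, `p_value`, `neg_log10_p`,
#'   sorted by p-value.
#' @export
#' @examples
#' db <- gene_set_db(list(T1 = letters[1:5]), universe = letters[1:20])
#' enrich(letters[c(1:3, 6, 7)], db)  # p = 1126/15504, FE = 2.4
enrich <- function(query, db, ease = FALSE) {
  stopifnot(inherits(db, "gene_set_db"))
  query <- unique(query)
  outside <- setdiff(query, db$universe)
  if (length(outside))
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)))
  query <- intersect(query, db$universe)
  N <- length(db$universe)
  n <- length(query)
  rows <- lapply(names(db$sets), function(id) {
    term <- db$sets[[id]]
    k <- length(intersect(query, term))
    if (k < 1L) return(NULL)
    K <- length(term)
    k_eff <- if (ease) max(k - 1L, 0L) else k
    p <- phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id,
               category = db$category[[id]],
               n_query = n, n_term = K, n_overlap = k,
               fold_enrichment = (k / n) / (K / N),
               p_value = p,
               neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), category = character(0),
                      n_query = integer(0), n_term = integer(0),
                      n_overlap = integer(0), fold_enrichment = numeric(0),
                      p_value = numeric(0), neg_log10_p = numeric(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Filter and rank enrichment rows
#'
#' Keeps terms with `p < alpha` (strict), sorts by descending
#' `-log10(p)` with term id as tie-break and truncates to the top `top`
#' rows - the plot-ready table of the strongest annotations.
#'
#' @param rows [enrich()] output.
#' @param alpha Significance cutoff (strict `<`).
#' @param top Maximum number of rows returned.
#' @return Filtered, ranked rows.
#' @export
rank_terms <- function(rows, alpha = 0.05, top = 20L) {
  keep <- rows[rows$p_value < alpha, , drop = FALSE]
  keep <- keep[order(-keep$neg_log10_p, keep$term_id), , drop = FALSE]
  out <- head(keep, top)
  rownames(out) <- NULL
  out
}
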