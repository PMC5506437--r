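#' Hypergeometric over-representation of gene sets
#'
#' One-sided enrichment of a selected gene list against each gene set,
#' relative to a gene universe. For a universe of size N, a set with K
#' universe members, and n selected universe genes of which k fall in the
#' set: the expected overlap is `n * K / N`, the ratio of enrichment is
#' `k / expected`, and the p-value is the hypergeometric upper tail
#' `P(X >= k)` ([stats::phyper()] at `k - 1` with `lower.tail = FALSE`).
#' Q-values are Benjamini-Hochberg across the sets tested; results are
#' sorted by p. Selected genes outside the universe are dropped with a
#' warning; duplicate genes are removed before counting; sets with no
#' universe member are skipped with a warning.
#'
#' @param selected_genes Character vector of selected genes.
#' @param gene_sets Named list of gene sets, or a path to a GMT file.
#' @param universe Character vector: the gene universe (non-empty).
#' @return A tibble of class `enrich_result`: `set_name`, `set_size`
#'   (within the universe), `genes_in_overlap`, `expected`,
#'   `ratio_of_enrichment`, `p`, `q`.
#' @export
hypergeom_enrich <- function(selected_genes, gene_sets, universe) {
  if (length(universe) == 0) abort("universe is empty")
  if (is.character(gene_sets) && length(gene_sets) == 1 &&
      file.exists(gene_sets))
    gene_sets <- read_gmt(gene_sets)
  universe <- unique(universe)
  selected_genes <- unique(selected_genes)
  outside <- setdiff(selected_genes, universe)
  if (length(outside)) {
    warn(sprintf("%d selected gene(s) outside the universe dropped",
                 length(outside)))
    selected_genes <- intersect(selected_genes, universe)
  }
  N <- length(universe)
  n <- length(selected_genes)

  rows <- imap(gene_sets, function(set, nm) {
    set <- unique(intersect(set, universe))
    K <- length(set)
    if (K == 0) {
      warn(sprintf("gene set '%s' has no universe members; skipped", nm))
      return(NULL)
    }
    k <- length(intersect(selected_genes, set))
    expected <- n * K / N
    tibble(set_name = nm, set_size = K, genes_in_overlap = as.integer(k),
           expected = expected,
           ratio_of_enrichment = if (expected > 0) k / expected else NA_real_,
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- bind_rows(keep(rows, Negate(is.null)))
  if (nrow(out) == 0) return(out)
  out$q <- bh_fdr(out$p)
  out <- arrange(out, .data$p, .data$set_name)
  structure(out, class = c("enrich_result", class(out)))
}

#' Enrichment against user-supplied pathway lists
#'
#' Identical machinery to [hypergeom_enrich()] applied to custom named gene
#' lists (e.g. curated aging pathways such as insulin-signaling, mTOR, or
#' an aging-gene catalogue) supplied directly or as a GMT file.
#'
#' @inheritParams hypergeom_enrich
#' @param pathways Named list of gene vectors or a GMT path.
#' @return See [hypergeom_enrich()].
#' @export
enrich_custom_pathways <- function(selected_genes, pathways, universe) {
  hypergeom_enrich(selected_genes, pathways, universe)
}
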