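#' Read and write gene sets in GMT format
#'
#' GMT is the tab-delimited gene-set format: one set per line, fields are
#' set name, description, then member genes. Reading is delegated to
#' [fgsea::gmtPathways()]; an empty file yields an empty named list.
#'
#' @param path File path.
#' @param sets Named list of character vectors (gene sets).
#' @param descriptions Optional character vector of set descriptions
#'   (recycled; defaults to `"na"`).
#' @return `read_gmt()`: a named list of character vectors. `write_gmt()`:
#'   `path`, invisibly.
#' @name gmt
NULL

#' @rdname gmt
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0) return(setNames(list(), character()))
  fgsea::gmtPathways(path)
}

#' @rdname gmt
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (length(sets) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  desc <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-set fixture with one planted enriched set
#'
#' Creates `n_sets` gene sets over `universe`: the first ("planted") set is
#' seeded with block genes (80% of `set_size`, capped at the number of block
#' genes available) topped up with random genes, and the remaining sets are
#' uniform random draws from the universe. Used to exercise enrichment code
#' with a known positive.
#'
#' @param block_genes Genes of the coexpressed block to plant.
#' @param n_sets Number of sets (0 gives an empty GMT).
#' @param set_size Genes per set; must not exceed the universe size.
#' @param universe Gene universe (must contain `block_genes`).
#' @param seed Integer seed.
#' @param file Optional path; if given, the sets are also written as GMT.
#' @return A named list of gene sets (the planted set is
#'   `"planted_block_set"`), invisibly if `file` is given.
#' @export
make_geneset_fixture <- function(block_genes, n_sets, set_size, universe,
                                 seed = 1L, file = NULL) {
  if (set_size > length(universe)) abort("set_size exceeds universe size")
  if (!all(block_genes %in% universe)) abort("universe must contain block_genes")
  set.seed(seed)
  sets <- list()
  if (n_sets >= 1) {
    n_block <- min(length(block_genes), ceiling(0.8 * set_size))
    planted <- c(sample(block_genes, n_block),
                 sample(setdiff(universe, block_genes), set_size - n_block))
    sets[["planted_block_set"]] <- planted
    for (i in seq_len(n_sets - 1)) {
      sets[[sprintf("random_set_%02d", i)]] <- sample(universe, set_size)
    }
  }
  if (!is.null(file)) {
    write_gmt(sets, file)
    return(invisible(sets))
  }
  sets
}
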