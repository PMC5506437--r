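#' Read and write cohort and expression tables
#'
#' Fixed TSV dialects used throughout the package. Cohort tables are plain
#' TSV with one header row. Cq matrices are TSV with participants as rows
#' and miRNAs as columns; undetected entries are written as `"ND"` and
#' not-assayed entries as empty cells, and read back to the in-memory
#' encoding (`Inf` = undetected, `NA` = not assayed). mRNA matrices use the
#' same layout with no special codes.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return The input (writers, invisibly) or a tibble (readers).
#' @name gripmir-io
NULL

#' @rdname gripmir-io
#' @export
write_cohort <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname gripmir-io
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname gripmir-io
#' @export
write_cq_matrix <- function(x, path) {
  out <- x
  for (j in setdiff(names(out), "participant_id")) {
    v <- out[[j]]
    s <- ifelse(is.na(v), "", ifelse(is.infinite(v), "ND", format(v, digits = 10)))
    out[[j]] <- s
  }
  readr::write_tsv(out, path)
  invisible(x)
}

#' @rdname gripmir-io
#' @export
read_cq_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  for (j in setdiff(names(raw), "participant_id")) {
    v <- raw[[j]]
    num <- suppressWarnings(as.numeric(v))
    num[v == "ND"] <- CQ_UNDETECTED
    num[v == ""] <- NA_real_
    raw[[j]] <- num
  }
  raw
}

#' @rdname gripmir-io
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname gripmir-io
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a miRNA-target prediction table
#'
#' Two-column TSV (`mirna`, `gene`). Rows with missing or extra fields are
#' dropped with a message reporting how many were skipped.
#'
#' @param path File path.
#' @return A tibble with columns `mirna` and `gene`.
#' @export
read_predictions <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(raw)[1:2] <- c("mirna", "gene")
  bad <- !complete.cases(raw) | raw$mirna == "" | raw$gene == ""
  if (any(bad)) message(sum(bad), " malformed prediction rows skipped")
  raw[!bad, ]
}
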