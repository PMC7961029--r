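#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, character(1), 1))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write expression tables as TSV
#'
#' Expression tables are genes-in-rows TSVs whose first column is `gene` and
#' remaining columns are samples.
#'
#' @param path File path.
#' @return `read_expr_tsv()` returns the expression tibble;
#'   `write_expr_tsv()` returns `path` invisibly.
#' @export
read_expr_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene = readr::col_character(),
                                          .default = readr::col_double()))
}

#' @rdname read_expr_tsv
#' @param tbl Expression tibble to write.
#' @export
write_expr_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}
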