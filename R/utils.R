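# Internal helpers shared across modules.

# Expression tables are tibbles whose first column is `gene` and whose
# remaining columns are samples. These two helpers move between that
# representation and a plain numeric matrix with gene rownames.
expr_to_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "gene")
  if (anyDuplicated(tbl$gene) > 0) {
    stop("duplicate gene ids in expression table", call. = FALSE)
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$gene
  storage.mode(m) <- "double"
  m
}

matrix_to_expr <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

check_meta_alignment <- function(expr_samples, meta) {
  stopifnot(is.data.frame(meta), "sample" %in% names(meta))
  missing <- setdiff(expr_samples, meta$sample)
  if (length(missing) > 0) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample) > 0) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  invisible(TRUE)
}

# Stable per-stage sub-seed derived from the master seed; keeps every stage's
# randomness reproducible without sharing one global stream.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
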