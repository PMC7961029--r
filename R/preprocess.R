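#' Counts per million
#'
#' Library-size normalization: each sample's counts are scaled to sum to one
#' million, so values are comparable across sequencing depths.
#'
#' @param counts Expression tibble (`gene` column + one column per sample) of
#'   nonnegative counts.
#' @return Tibble of the same shape with CPM values; every sample column sums
#'   to 1e6.
#' @export
cpm <- function(counts) {
  m <- expr_to_matrix(counts)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  matrix_to_expr(sweep(m, 2, 1e6 / tot, `*`))
}

#' Expression filter: minimum CPM in at least one region
#'
#' A gene is retained if, in at least one brain region, it reaches
#' `min_cpm` in at least `ceiling(min_sample_frac * n_region)` of that
#' region's samples. This keeps genes that are expressed in any single
#' region even if silent elsewhere.
#'
#' @param cpm_tbl CPM tibble from [cpm()].
#' @param meta Sample metadata with `sample` and `region` columns.
#' @param min_cpm Minimum CPM counted as "expressed" (default 1).
#' @param min_sample_frac Minimum fraction of a region's samples that must be
#'   expressed (default 0.5, "at least half", rounded up).
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_expressed <- function(cpm_tbl, meta, min_cpm = 1,
                             min_sample_frac = 0.5) {
  stopifnot(min_sample_frac > 0, min_sample_frac <= 1)
  m <- expr_to_matrix(cpm_tbl)
  check_meta_alignment(colnames(m), meta)
  meta <- meta[match(colnames(m), meta$sample), ]
  keep <- rep(FALSE, nrow(m))
  for (r in unique(meta$region)) {
    cols <- meta$region == r
    if (!any(cols)) stop("region with zero samples: ", r, call. = FALSE)
    need <- ceiling(min_sample_frac * sum(cols))
    keep <- keep |
      rowSums(m[, cols, drop = FALSE] >= min_cpm) >= need
  }
  rownames(m)[keep]
}

#' Coefficient-of-variation filter
#'
#' Computes each gene's coefficient of variation `CV_j = sd_j / mean_j` over
#' all samples and retains genes with `CV_j < T` where
#' `T = mean(CV) + cv_sd_multiplier * sd(CV)`. Genes with zero mean are
#' excluded before CV computation and reported in the `excluded_zero_mean`
#' attribute. When `sd(CV) = 0` (all CVs identical, including the
#' single-gene case) every gene is retained: the filter targets outliers and
#' a degenerate spread has none.
#'
#' The cutoff is estimated once, on the gene set the filter is given; to
#' re-apply the filter to a subset without re-estimating (the filter is then
#' exactly idempotent), pass the first pass's cutoff as `threshold`.
#'
#' @param expr_tbl Expression tibble over all subjects and regions.
#' @param cv_sd_multiplier Number of CV standard deviations above the mean CV
#'   that defines the cutoff `T` (default 3).
#' @param threshold Optional fixed cutoff `T`; when supplied the
#'   mean/sd estimation step is skipped.
#' @return Character vector of retained gene ids with attributes `threshold`
#'   (the cutoff `T`), `cv` (named CV vector) and `excluded_zero_mean`.
#' @export
filter_cv <- function(expr_tbl, cv_sd_multiplier = 3, threshold = NULL) {
  m <- expr_to_matrix(expr_tbl)
  if (ncol(m) < 2) stop("need >= 2 samples for CV", call. = FALSE)
  mu <- rowMeans(m)
  zero <- mu == 0
  m2 <- m[!zero, , drop = FALSE]
  cv <- apply(m2, 1, stats::sd) / rowMeans(m2)
  if (is.null(threshold)) {
    s <- if (length(cv) > 1) stats::sd(cv) else 0
    threshold <- if (s == 0) Inf else mean(cv) + cv_sd_multiplier * s
  }
  structure(names(cv)[cv < threshold],
            threshold = threshold,
            cv = cv,
            excluded_zero_mean = rownames(m)[zero])
}

#' Between-region consensus correlation
#'
#' For every subject sampled in both regions, computes the Pearson
#' correlation across genes between the subject's two samples, after
#' centering each gene on its mean over all samples (raw expression profiles
#' correlate near 1 through shared gene baselines; centering isolates the
#' subject-specific deviations that distinguish regions). The consensus is
#' summarized by the median (and mean) over subjects.
#'
#' @param expr_tbl Expression tibble (typically log2 CPM).
#' @param meta Sample metadata (`sample`, `subject`, `region`).
#' @param region_a,region_b The two region labels to compare.
#' @param center_genes Center each gene across all samples first (default
#'   TRUE).
#' @return One-row tibble: `region_a`, `region_b`, `n_subjects`, `r_median`,
#'   `r_mean`; the per-subject correlations are in attribute `per_subject`.
#' @export
consensus_correlation <- function(expr_tbl, meta, region_a, region_b,
                                  center_genes = TRUE) {
  m <- expr_to_matrix(expr_tbl)
  check_meta_alignment(colnames(m), meta)
  meta <- meta[match(colnames(m), meta$sample), ]
  if (center_genes) m <- m - rowMeans(m)
  in_a <- meta$subject[meta$region == region_a]
  in_b <- meta$subject[meta$region == region_b]
  shared <- intersect(in_a, in_b)
  if (length(shared) < 2) {
    stop("fewer than 2 subjects sampled in both regions", call. = FALSE)
  }
  rs <- purrr::map_dbl(shared, function(s) {
    a <- m[, meta$sample[meta$subject == s & meta$region == region_a][1]]
    b <- m[, meta$sample[meta$subject == s & meta$region == region_b][1]]
    stats::cor(a, b)
  })
  out <- tibble::tibble(
    region_a = region_a, region_b = region_b,
    n_subjects = length(shared),
    r_median = stats::median(rs), r_mean = mean(rs)
  )
  attr(out, "per_subject") <- tibble::tibble(subject = shared, r = rs)
  out
}

#' Merge regions into one pseudo-region by per-subject averaging
#'
#' Replaces each subject's samples in the listed regions with a single
#' pseudo-sample holding the arithmetic mean expression per gene (used to
#' collapse highly correlated cortical regions into one analysis region).
#' Subjects with samples in only some of the listed regions contribute the
#' mean over the regions they have; subjects absent from all listed regions
#' are excluded from the merged block with a warning.
#'
#' @param expr_tbl Expression tibble.
#' @param meta Sample metadata.
#' @param regions_to_merge Character vector of region labels to collapse.
#' @param new_label Label of the merged pseudo-region.
#' @return List with the updated `expr` and `meta` tibbles: merged
#'   pseudo-samples (named `<subject>_<new_label>`) replace the original
#'   samples of the merged regions; other regions pass through unchanged.
#' @export
merge_regions <- function(expr_tbl, meta, regions_to_merge,
                          new_label = "merged") {
  m <- expr_to_matrix(expr_tbl)
  check_meta_alignment(colnames(m), meta)
  meta <- meta[match(colnames(m), meta$sample), ]
  in_merge <- meta$region %in% regions_to_merge
  subjects <- unique(meta$subject)
  absent <- setdiff(subjects, meta$subject[in_merge])
  if (length(absent) > 0) {
    warning("subject(s) absent from all merged regions: ",
            paste(absent, collapse = ", "))
  }
  merged_subjects <- intersect(subjects, meta$subject[in_merge])
  merged <- vapply(merged_subjects, function(s) {
    cols <- meta$sample[in_merge & meta$subject == s]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  colnames(merged) <- paste(merged_subjects, new_label, sep = "_")

  keep_meta <- meta[!in_merge, ]
  add_meta <- meta[in_merge, ] |>
    dplyr::distinct(.data$subject, .keep_all = TRUE) |>
    dplyr::mutate(region = new_label,
                  sample = paste(.data$subject, new_label, sep = "_"))
  new_meta <- dplyr::bind_rows(add_meta, keep_meta) |>
    dplyr::arrange(.data$subject, .data$region)
  new_m <- cbind(merged, m[, !in_merge, drop = FALSE])
  new_m <- new_m[, new_meta$sample, drop = FALSE]
  list(expr = matrix_to_expr(new_m), meta = new_meta)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance and `df = n1 + n2 - 2`, computed directly
#' from group means, standard deviations and sizes — the form used for
#' cohort demographic tables, where only summaries may be available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return One-row tibble: `t`, `df`, `p` (two-sided).
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohort demographic table
#'
#' Per-covariate group means, standard deviations and sizes for the two
#' diagnosis groups, with a pooled-variance two-sample t-test
#' (`df = n1 + n2 - 2`) of the case-versus-comparison difference.
#'
#' @param meta Sample or subject metadata with a `diagnosis` column
#'   (`case` / `comparison`); one row per subject is used (deduplicated on
#'   `subject` when present).
#' @param covariates Numeric covariate columns to summarize.
#' @return Tibble: `covariate`, `mean_case`, `sd_case`, `n_case`,
#'   `mean_comparison`, `sd_comparison`, `n_comparison`, `df`, `t`, `p`.
#' @export
cohort_table <- function(meta, covariates = c("age", "ph", "pmi", "rin")) {
  if ("subject" %in% names(meta)) {
    meta <- dplyr::distinct(meta, .data$subject, .keep_all = TRUE)
  }
  groups <- split(meta, meta$diagnosis == "case")
  if (length(groups) < 2 || any(vapply(groups, nrow, 1L) < 2)) {
    stop("need two diagnosis groups with n >= 2 each", call. = FALSE)
  }
  cases <- meta[meta$diagnosis == "case", ]
  comps <- meta[meta$diagnosis != "case", ]
  purrr::map_dfr(covariates, function(cv) {
    x <- cases[[cv]]; y <- comps[[cv]]
    tt <- pooled_t(mean(x), stats::sd(x), length(x),
                   mean(y), stats::sd(y), length(y))
    tibble::tibble(
      covariate = cv,
      mean_case = mean(x), sd_case = stats::sd(x), n_case = length(x),
      mean_comparison = mean(y), sd_comparison = stats::sd(y),
      n_comparison = length(y),
      df = tt$df, t = tt$t, p = tt$p
    )
  })
}
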