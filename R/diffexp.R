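#' Log-transform counts to log2(CPM + prior)
#'
#' @param counts Count tibble (`gene` + samples).
#' @param prior Positive pseudo-count added before the log (default 1, so
#'   zero CPM maps to 0).
#' @return Expression tibble of log2(CPM + prior) values.
#' @export
normalize_log <- function(counts, prior = 1) {
  if (prior <= 0) stop("prior must be > 0", call. = FALSE)
  m <- expr_to_matrix(cpm(counts))
  matrix_to_expr(log2(m + prior))
}

#' Differential-expression model specification
#'
#' @param fixed Covariates always in the model; `diagnosis` is mandatory and
#'   `region` is dropped automatically for single-region fits.
#' @param candidates Covariates admitted only if they pass the selection rule
#'   in [select_model()].
#' @param n_pcs Number of leading expression principal components used by
#'   the selection rule.
#' @param p_cut Selection p-value threshold: a candidate is retained if it
#'   associates with any of the top `n_pcs` PCs at p < `p_cut`.
#' @return List of class `de_model_spec`.
#' @export
de_model_spec <- function(fixed = c("diagnosis", "region", "sex", "ph"),
                          candidates = c("age", "pmi", "rin"),
                          n_pcs = 5, p_cut = 0.01) {
  if (!"diagnosis" %in% fixed) stop("diagnosis must be a fixed covariate",
                                    call. = FALSE)
  structure(list(fixed = fixed, candidates = candidates,
                 n_pcs = n_pcs, p_cut = p_cut),
            class = "de_model_spec")
}

#' Screen candidate covariates against expression principal components
#'
#' Keeps every fixed covariate and promotes a candidate covariate into the
#' model when it is linearly associated (p < `p_cut`) with at least one of
#' the top `n_pcs` principal components of the expression matrix — i.e. when
#' it demonstrably drives expression variation. Errors when the resulting
#' design is near-collinear, naming the offending covariate pair.
#'
#' @param expr_tbl Expression tibble (log scale).
#' @param meta Sample metadata holding all covariates.
#' @param spec A [de_model_spec()].
#' @return The spec with selected candidates appended to `fixed` and an
#'   empty candidate list; selection p-values in attribute `selection`.
#' @export
select_model <- function(expr_tbl, meta, spec = de_model_spec()) {
  stopifnot(inherits(spec, "de_model_spec"))
  if (length(spec$candidates) == 0) return(spec)
  m <- expr_to_matrix(expr_tbl)
  check_meta_alignment(colnames(m), meta)
  meta <- meta[match(colnames(m), meta$sample), ]
  missing <- setdiff(spec$candidates, names(meta))
  if (length(missing) > 0) {
    stop("candidate covariates absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_pcs <- min(spec$n_pcs, ncol(m) - 1)
  pcs <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                              drop = FALSE]
  sel <- purrr::map_dfr(spec$candidates, function(cv) {
    v <- covariate_vector(meta, cv)
    p_min <- min(vapply(seq_len(n_pcs), function(j) {
      summary(stats::lm(pcs[, j] ~ v))$coefficients[2, 4]
    }, numeric(1)))
    tibble::tibble(candidate = cv, p_min = p_min,
                   retained = p_min < spec$p_cut)
  })
  keep <- sel$candidate[sel$retained]
  out <- de_model_spec(fixed = c(spec$fixed, keep), candidates = character(0),
                       n_pcs = spec$n_pcs, p_cut = spec$p_cut)
  check_collinearity(meta, out$fixed)
  attr(out, "selection") <- sel
  out
}

covariate_vector <- function(meta, cv) {
  v <- meta[[cv]]
  if (is.character(v) || is.factor(v)) as.numeric(factor(v)) else as.numeric(v)
}

check_collinearity <- function(meta, covs, tol = 0.999) {
  covs <- intersect(covs, names(meta))
  num <- vapply(covs, function(cv) covariate_vector(meta, cv),
                numeric(nrow(meta)))
  num <- num[, apply(num, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(num) < 2) return(invisible(TRUE))
  cc <- stats::cor(num)
  cc[upper.tri(cc, diag = TRUE)] <- 0
  bad <- which(abs(cc) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("collinear covariates: ",
         paste(colnames(num)[bad[1, 2]], rownames(num)[bad[1, 1]],
               sep = " ~ "), call. = FALSE)
  }
  invisible(TRUE)
}

# Vectorized per-gene ordinary least squares: one QR decomposition of the
# shared design, betas/SEs/t/p for the diagnosis coefficient for every gene.
ols_diagnosis <- function(m, design, dx_col) {
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) stop("rank-deficient design", call. = FALSE)
  df <- nrow(design) - ncol(design)
  if (df < 1) stop("more model parameters than samples", call. = FALSE)
  coefs <- qr.coef(qr_x, t(m))
  resid <- t(m) - design %*% coefs
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[dx_col, dx_col])
  beta <- coefs[dx_col, ]
  tstat <- beta / se
  tibble::tibble(
    gene = rownames(m),
    log2fc = unname(beta), se = unname(se),
    p = unname(2 * stats::pt(-abs(tstat), df))
  )
}

build_design <- function(meta, covs) {
  meta$diagnosis <- factor(meta$diagnosis, levels = c("comparison", "case"))
  covs <- setdiff(covs, "diagnosis")
  rhs <- paste(c("diagnosis", covs), collapse = " + ")
  design <- stats::model.matrix(stats::as.formula(paste("~", rhs)),
                                data = meta)
  list(design = design, dx_col = which(colnames(design) == "diagnosiscase"))
}

finalize_de <- function(res, scope, alpha) {
  res$q <- bh_fdr(res$p)
  res$direction <- dplyr::case_when(
    res$q < alpha & res$log2fc > 0 ~ "up",
    res$q < alpha & res$log2fc < 0 ~ "down",
    TRUE ~ "ns"
  )
  dplyr::bind_cols(tibble::tibble(scope = scope), res) |>
    dplyr::relocate("gene")
}

#' Global differential expression across all regions
#'
#' Per-gene ordinary least squares of log2 expression on diagnosis plus
#' region and the model's covariates (default sex and pH). The diagnosis
#' coefficient is the log2 fold change, case minus comparison, so positive
#' values are upregulated in cases. Two-sided t-test p-values; BH q-values
#' over all fitted genes.
#'
#' @param expr_tbl Expression tibble (log2 scale; see [normalize_log()]).
#' @param meta Sample metadata.
#' @param spec A [de_model_spec()]; candidates still present are screened
#'   with [select_model()] first.
#' @param alpha FDR threshold used only to label `direction`.
#' @return Tibble: `gene`, `scope` ("global"), `log2fc`, `se`, `p`, `q`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
fit_global <- function(expr_tbl, meta, spec = de_model_spec(),
                       alpha = 0.05) {
  if (length(spec$candidates) > 0) spec <- select_model(expr_tbl, meta, spec)
  m <- expr_to_matrix(expr_tbl)
  check_meta_alignment(colnames(m), meta)
  meta <- meta[match(colnames(m), meta$sample), ]
  covs <- spec$fixed
  if (length(unique(meta$region)) < 2) covs <- setdiff(covs, "region")
  d <- build_design(meta, covs)
  finalize_de(ols_diagnosis(m, d$design, d$dx_col), "global", alpha)
}

#' Per-region differential expression
#'
#' Fits the global model without the region term separately inside each
#' region; BH correction is applied within region.
#'
#' @inheritParams fit_global
#' @return Tibble as in [fit_global()] with `scope` set to the region label,
#'   one block per region.
#' @export
fit_regional <- function(expr_tbl, meta, spec = de_model_spec(),
                         alpha = 0.05) {
  if (length(spec$candidates) > 0) spec <- select_model(expr_tbl, meta, spec)
  m <- expr_to_matrix(expr_tbl)
  check_meta_alignment(colnames(m), meta)
  meta <- meta[match(colnames(m), meta$sample), ]
  covs <- setdiff(spec$fixed, "region")
  purrr::map_dfr(unique(meta$region), function(r) {
    sub <- meta$region == r
    d <- build_design(meta[sub, ], covs)
    if (nrow(d$design) <= ncol(d$design)) {
      stop("region ", r, " has fewer samples than model parameters",
           call. = FALSE)
    }
    finalize_de(ols_diagnosis(m[, sub, drop = FALSE], d$design, d$dx_col),
                r, alpha)
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone q-values in `[p, 1]`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Volcano classification and DEG-set overlaps
#'
#' Classifies every (gene, scope) result as `up`/`down`/`ns` at the given
#' FDR, annotates whether the effect exceeds the fold-change guide line
#' (default |log2FC| > 0.26, a ~20% expression change), and counts all
#' pairwise and higher-order intersections of the significant gene sets
#' across scopes.
#'
#' @param results DE results tibble (possibly several scopes bound together,
#'   e.g. global + regional).
#' @param alpha FDR significance threshold.
#' @param fc_line Fold-change guide line (annotation only; it does not gate
#'   significance).
#' @return List with `classes` (tibble `gene`, `scope`, `class`,
#'   `beyond_fc_line`) and `overlaps` (tibble `scopes`, `n_scopes`, `n`,
#'   intersection counts of significant gene-id sets for every combination
#'   of 2+ scopes).
#' @export
classify_and_overlap <- function(results, alpha = 0.05, fc_line = 0.26) {
  stopifnot(alpha > 0, alpha < 1)
  classes <- results |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$q < alpha & .data$log2fc > 0 ~ "up",
        .data$q < alpha & .data$log2fc < 0 ~ "down",
        TRUE ~ "ns"
      ),
      beyond_fc_line = abs(.data$log2fc) > fc_line
    ) |>
    dplyr::select("gene", "scope", "class", "beyond_fc_line")
  sig_sets <- classes |>
    dplyr::filter(.data$class != "ns") |>
    dplyr::group_by(.data$scope) |>
    dplyr::summarise(genes = list(.data$gene), .groups = "drop")
  overlaps <- overlap_counts(stats::setNames(sig_sets$genes, sig_sets$scope))
  list(classes = classes, overlaps = overlaps)
}

overlap_counts <- function(sets) {
  scopes <- names(sets)
  if (length(scopes) < 2) {
    return(tibble::tibble(scopes = character(), n_scopes = integer(),
                          n = integer()))
  }
  combos <- unlist(lapply(2:length(scopes), function(k) {
    utils::combn(scopes, k, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map_dfr(combos, function(cs) {
    tibble::tibble(
      scopes = paste(cs, collapse = "&"),
      n_scopes = length(cs),
      n = length(Reduce(intersect, sets[cs]))
    )
  })
}
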