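#' Fisher-exact gene-set enrichment
#'
#' Tests each gene set for over-representation of the DEG list against a
#' background universe using the one-sided Fisher exact test (upper
#' hypergeometric tail). Sets are intersected with the background before
#' testing; sets overlapping the DEG list in fewer than `min_overlap` genes
#' are skipped (reported in attribute `skipped`). BH q-values are computed
#' over the tested sets.
#'
#' @param deg Character vector of differentially expressed gene ids (must be
#'   a subset of `background`).
#' @param background Character vector: the tested gene universe.
#' @param sets Named list of gene sets (e.g. from [read_gmt()] or
#'   [simulate_gene_sets()]).
#' @param min_overlap Minimum DEG overlap for a set to be tested (default 3).
#' @return Tibble: `set`, `k` (DEG in set), `K` (set size in background),
#'   `n` (DEG count), `N` (background size), `odds_ratio`, `p`, `q`, and a
#'   list-column `genes` with the overlapping DEG ids.
#' @export
fisher_enrichment <- function(deg, background, sets, min_overlap = 3) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  background <- unique(background)
  deg <- unique(deg)
  if (!all(deg %in% background)) {
    stop("deg must be a subset of background", call. = FALSE)
  }
  N <- length(background)
  n <- length(deg)
  rows <- purrr::imap_dfr(sets, function(members, name) {
    members <- intersect(members, background)
    K <- length(members)
    hits <- intersect(members, deg)
    k <- length(hits)
    tibble::tibble(set = name, k = k, K = K, n = n, N = N,
                   genes = list(hits))
  })
  skipped <- rows$set[rows$k < min_overlap]
  out <- rows[rows$k >= min_overlap, , drop = FALSE]
  if (nrow(out) > 0) {
    out$odds_ratio <- with(out, (k * (N - n - K + k)) /
                                pmax((K - k) * (n - k), 0.5))
    # P(X >= k) for X ~ Hypergeom(N, K, n); one-sided enrichment
    out$p <- with(out, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
    out$q <- bh_fdr(out$p)
    out <- dplyr::arrange(out, .data$p) |>
      dplyr::relocate("genes", .after = "q")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Tabulate DEG direction within enriched sets
#'
#' Counts how many of each set's overlapping DEGs are up- versus
#' downregulated and derives the downregulated fraction, the quantity used
#' by the directionality statistics.
#'
#' @param results Enrichment tibble from [fisher_enrichment()] (needs the
#'   `genes` list-column).
#' @param deg_table DE results tibble with `gene` and `direction` columns
#'   (every overlap gene must appear; `direction` in `up`/`down`).
#' @return `results` with `n_up`, `n_down`, `frac_down` columns appended.
#' @export
tabulate_direction <- function(results, deg_table) {
  dir_map <- stats::setNames(deg_table$direction, deg_table$gene)
  counts <- purrr::map(results$genes, function(g) {
    missing <- setdiff(g, names(dir_map))
    if (length(missing) > 0) {
      stop("overlap gene(s) missing from deg_table: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    d <- dir_map[g]
    c(up = sum(d == "up"), down = sum(d == "down"))
  })
  results$n_up <- vapply(counts, `[[`, numeric(1), "up")
  results$n_down <- vapply(counts, `[[`, numeric(1), "down")
  tot <- results$n_up + results$n_down
  results$frac_down <- ifelse(tot > 0, results$n_down / tot, NA_real_)
  results
}

#' Directionality statistics over clustered gene sets
#'
#' Given each enriched set's downregulated DEG fraction and a cluster label,
#' computes (i) a pooled two-sample t-test of the focal cluster's fractions
#' against all remaining sets (`df = n1 + n2 - 2`), (ii) a one-way ANOVA of
#' fractions across clusters, and (iii) per-cluster one-sample t-tests of
#' the fractions against 0.5 (no direction bias), two-sided, Bonferroni
#' corrected by the number of tested clusters. A cluster with a positive t
#' is biased toward downregulation.
#'
#' @param frac_down Numeric vector of per-set downregulated fractions.
#' @param cluster_labels Cluster label per set.
#' @param focal_cluster Cluster compared against the rest (default the first
#'   label in sorted order).
#' @return List with one-row tibbles `focal_vs_rest` (`mean_focal`,
#'   `mean_rest`, `t`, `df`, `p`) and `anova` (`F`, `df1`, `df2`, `p`), and
#'   tibble `per_cluster` (`cluster`, `n`, `mean_frac_down`, `t`, `df`, `p`,
#'   `p_bonferroni`). Singleton clusters are excluded from the per-cluster
#'   tests with a warning.
#' @export
directionality_tests <- function(frac_down, cluster_labels,
                                 focal_cluster = NULL) {
  stopifnot(length(frac_down) == length(cluster_labels))
  keep <- !is.na(frac_down)
  frac_down <- frac_down[keep]
  cluster_labels <- as.character(cluster_labels)[keep]
  if (is.null(focal_cluster)) focal_cluster <- sort(unique(cluster_labels))[1]
  focal <- frac_down[cluster_labels == focal_cluster]
  rest <- frac_down[cluster_labels != focal_cluster]
  if (length(focal) < 2 || length(rest) < 2) {
    stop("need >= 2 sets in the focal cluster and in the rest", call. = FALSE)
  }
  tt <- pooled_t(mean(focal), stats::sd(focal), length(focal),
                 mean(rest), stats::sd(rest), length(rest))
  focal_vs_rest <- tibble::tibble(
    focal_cluster = focal_cluster,
    mean_focal = mean(focal), mean_rest = mean(rest),
    t = tt$t, df = tt$df, p = tt$p
  )

  fit <- stats::aov(frac_down ~ factor(cluster_labels))
  an <- summary(fit)[[1]]
  f_stat <- an$`F value`[1]
  p_f <- an$`Pr(>F)`[1]
  if (isTRUE(all.equal(stats::var(frac_down), 0))) {  # constant fractions
    f_stat <- 0
    p_f <- 1
  }
  anova_tbl <- tibble::tibble(
    F = f_stat, df1 = an$Df[1], df2 = an$Df[2], p = p_f
  )

  sizes <- table(cluster_labels)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    warning("cluster(s) with a single set excluded from per-cluster tests: ",
            paste(singletons, collapse = ", "))
  }
  tested <- setdiff(names(sizes), singletons)
  per_cluster <- purrr::map_dfr(tested, function(cl) {
    x <- frac_down[cluster_labels == cl]
    se <- stats::sd(x) / sqrt(length(x))
    if (se == 0) {                # constant fractions: define the statistic
      t_stat <- if (mean(x) == 0.5) 0 else sign(mean(x) - 0.5) * Inf
      p_val <- if (mean(x) == 0.5) 1 else 0
    } else {
      t_stat <- (mean(x) - 0.5) / se
      p_val <- 2 * stats::pt(-abs(t_stat), length(x) - 1)
    }
    tibble::tibble(cluster = cl, n = length(x), mean_frac_down = mean(x),
                   t = t_stat, df = length(x) - 1, p = p_val,
                   p_bonferroni = pmin(p_val * length(tested), 1))
  })
  list(focal_vs_rest = focal_vs_rest, anova = anova_tbl,
       per_cluster = per_cluster)
}
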