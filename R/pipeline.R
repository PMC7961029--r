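#' Configure an end-to-end pipeline run
#'
#' Collects per-stage parameters and either a simulation block (a
#' [study_config()]) or paths to user-supplied inputs; exactly one of the
#' two must be given.
#'
#' @param simulate A [study_config()] describing the synthetic study, or
#'   NULL when `inputs` is given.
#' @param inputs Named list of file paths (`counts`, `meta` TSVs; optional
#'   `gmt`, `reference`, `partner`), or NULL when simulating.
#' @param qc List: `min_cpm`, `min_sample_frac`, `cv_sd_multiplier`,
#'   `merge_threshold` (consensus correlation at or above which the cortical
#'   pair is merged), `merge_label`.
#' @param de List: `alpha`, `fc_line`.
#' @param genesets List passed to [simulate_gene_sets()] when simulating:
#'   `n_sets`, `set_size_range`, `n_planted`, `down_bias`.
#' @param enrich List: `min_overlap`.
#' @param network List: `k`, `strong_threshold`.
#' @param deconv List: `n_markers`, plus `shifts`/`jitter_sd`/`noise_sd` for
#'   the simulated mixtures.
#' @param concord List: `fdr`, `overlap_frac`, `sign_agreement`, `n_report`.
#' @param seed Master integer seed; every stage derives a stable sub-seed
#'   from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = study_config(),
                            inputs = NULL,
                            qc = list(),
                            de = list(),
                            genesets = list(),
                            enrich = list(),
                            network = list(),
                            deconv = list(),
                            concord = list(),
                            seed = 1L) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` or `inputs` must be given", call. = FALSE)
  }
  defaults <- list(
    qc = list(min_cpm = 1, min_sample_frac = 0.5, cv_sd_multiplier = 3,
              merge_threshold = 0.5, merge_label = "OFC"),
    de = list(alpha = 0.05, fc_line = 0.26),
    genesets = list(n_sets = 50, set_size_range = c(10, 40), n_planted = 5,
                    down_bias = 0.8),
    enrich = list(min_overlap = 3),
    network = list(k = 4, strong_threshold = 0.5),
    deconv = list(n_markers = 15, noise_sd = 1, jitter_sd = 0.05),
    concord = list(fdr = 0.2, overlap_frac = 0.6, sign_agreement = 0.9,
                   n_report = 150)
  )
  merge_block <- function(name, given) {
    utils::modifyList(defaults[[name]], given)
  }
  structure(list(
    simulate = simulate, inputs = inputs,
    qc = merge_block("qc", qc), de = merge_block("de", de),
    genesets = merge_block("genesets", genesets),
    enrich = merge_block("enrich", enrich),
    network = merge_block("network", network),
    deconv = merge_block("deconv", deconv),
    concord = merge_block("concord", concord),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full case-control pipeline
#'
#' Executes the stages in order — simulate/load, expression QC and region
#' merging, global and regional differential expression, Fisher gene-set
#' enrichment with co-occurrence clustering and directionality statistics,
#' cell-type fraction deconvolution, and cross-study concordance — and
#' assembles a machine-readable report. Identical config and seed give an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every intermediate table is
#'   written as TSV and the report as `report.json`.
#' @return List with `report` (nested list of stage summaries) and `tables`
#'   (the intermediate tibbles), invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  tables <- list()
  report <- list(seed = seed)

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(seed, "simulate")
    sim_cfg <- do.call(study_config, sim_cfg[setdiff(names(sim_cfg), NULL)])
    study <- simulate_study(sim_cfg)
    counts <- study$counts; meta <- study$meta; truth <- study$truth
  } else {
    counts <- read_expr_tsv(config$inputs$counts)
    meta <- readr::read_tsv(config$inputs$meta, show_col_types = FALSE)
    truth <- NULL
  }
  report$input <- list(n_genes = nrow(counts), n_samples = ncol(counts) - 1)

  ## ---- qc ----
  qc <- config$qc
  cpm_tbl <- cpm(counts)
  keep_expr <- filter_expressed(cpm_tbl, meta, qc$min_cpm,
                                qc$min_sample_frac)
  cpm_kept <- cpm_tbl[cpm_tbl$gene %in% keep_expr, ]
  keep_cv <- filter_cv(cpm_kept, qc$cv_sd_multiplier)
  counts_qc <- counts[counts$gene %in% keep_cv, ]
  logexpr <- normalize_log(counts_qc)

  regions <- unique(meta$region)
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  cons <- purrr::map_dfr(pairs, function(pr) {
    consensus_correlation(logexpr, meta, pr[1], pr[2])
  })
  report$qc <- list(
    genes_in = nrow(counts),
    genes_after_cpm_filter = length(keep_expr),
    genes_after_cv_filter = length(keep_cv),
    cv_threshold = attr(keep_cv, "threshold"),
    consensus_correlations = as.data.frame(cons)
  )

  sim_block <- config$simulate
  cortical <- if (!is.null(sim_block)) sim_block$cortical_regions
              else intersect(c("BA11", "BA47"), regions)
  merged_label <- NULL
  if (length(cortical) == 2) {
    cc <- cons[(cons$region_a %in% cortical) & (cons$region_b %in% cortical), ]
    if (nrow(cc) == 1 && cc$r_median >= qc$merge_threshold) {
      mg <- merge_regions(logexpr, meta, cortical, qc$merge_label)
      logexpr <- mg$expr; meta_de <- mg$meta
      merged_label <- qc$merge_label
    } else meta_de <- meta
  } else meta_de <- meta
  report$qc$merged_cortical <- !is.null(merged_label)
  cohort <- cohort_table(meta)
  report$cohort <- as.data.frame(cohort)
  tables$log_expression <- logexpr
  tables$meta_analysis <- meta_de
  tables$cohort <- cohort

  ## ---- differential expression ----
  de_par <- config$de
  spec <- de_model_spec()
  spec <- select_model(logexpr, meta_de, spec)
  global <- fit_global(logexpr, meta_de, spec, de_par$alpha)
  regional <- fit_regional(logexpr, meta_de, spec, de_par$alpha)
  all_de <- dplyr::bind_rows(global, regional)
  cls <- classify_and_overlap(all_de, de_par$alpha, de_par$fc_line)
  deg_counts <- all_de |>
    dplyr::group_by(.data$scope) |>
    dplyr::summarise(
      n_deg = sum(.data$direction != "ns"),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"), .groups = "drop")
  report$diffexp <- list(
    model_covariates = spec$fixed,
    deg_counts = as.data.frame(deg_counts),
    overlaps = as.data.frame(cls$overlaps)
  )
  tables$de_global <- global
  tables$de_regional <- regional

  ## ---- enrichment + network ----
  background <- global$gene
  deg_global <- global$gene[global$direction != "ns"]
  en_par <- config$enrich
  if (!is.null(sim_block)) {
    gs <- simulate_gene_sets(
      background, n_sets = config$genesets$n_sets,
      set_size_range = config$genesets$set_size_range,
      n_planted = config$genesets$n_planted, truth = truth,
      down_bias = config$genesets$down_bias,
      seed = derive_seed(seed, "genesets"))
    sets <- gs$sets
    truth$enriched_sets <- gs$planted
  } else if (!is.null(config$inputs$gmt)) {
    sets <- read_gmt(config$inputs$gmt)
  } else sets <- NULL

  if (!is.null(sets) && length(deg_global) >= en_par$min_overlap) {
    enr <- fisher_enrichment(deg_global, background, sets,
                             en_par$min_overlap)
    enr <- tabulate_direction(enr, global)
    sig_sets <- if (nrow(enr) > 0) enr$set[enr$q < de_par$alpha]
                else character(0)
    report$enrichment <- list(
      n_tested = nrow(enr),
      n_significant = length(sig_sets),
      significant_sets = sig_sets
    )
    tables$enrichment <- enr
    net_par <- config$network
    if (length(sig_sets) >= max(4, net_par$k)) {
      J <- set_cooccurrence(sets[sig_sets], restrict_to = background)
      clusters <- cluster_sets(J, k = min(net_par$k, nrow(J)))
      edges <- network_edges(J, net_par$strong_threshold)
      enr_sig <- enr[match(clusters$set, enr$set), ]
      dir_stats <- tryCatch(
        directionality_tests(enr_sig$frac_down, clusters$cluster),
        error = function(e) NULL)
      report$network <- list(
        n_clusters = length(unique(clusters$cluster)),
        n_edges = nrow(edges),
        n_strong_edges = sum(edges$strong),
        directionality = if (!is.null(dir_stats)) list(
          focal_vs_rest = as.data.frame(dir_stats$focal_vs_rest),
          anova = as.data.frame(dir_stats$anova),
          per_cluster = as.data.frame(dir_stats$per_cluster)
        )
      )
      tables$clusters <- clusters
      tables$edges <- edges
    }
  }

  ## ---- deconvolution ----
  dc <- config$deconv
  if (!is.null(sim_block)) {
    ref <- simulate_reference(seed = derive_seed(seed, "reference"))
    fr <- simulate_fractions(meta, jitter_sd = dc$jitter_sd,
                             seed = derive_seed(seed, "fractions"))
    truth$true_fractions <- fr$subject_fractions
    sig0 <- build_signature(ref$reference, dc$n_markers)
    bulk <- simulate_mixtures(ref$reference, fr$sample_fractions,
                              noise_sd = dc$noise_sd,
                              seed = derive_seed(seed, "mixtures"))
    fracs <- estimate_fractions(bulk, sig0, meta)
    subj_fracs <- global_average(fracs, meta)
    cmp <- compare_fractions(subj_fracs, meta)
    report$deconvolution <- list(
      cell_types = sort(unique(fracs$cell_type)),
      comparison = as.data.frame(cmp)
    )
    tables$fractions <- fracs
    tables$fraction_comparison <- cmp
  } else if (!is.null(config$inputs$reference)) {
    ref_tbl <- read_expr_tsv(config$inputs$reference)
    sig0 <- build_signature(ref_tbl, dc$n_markers)
    bulk <- cpm(counts_qc)
    fracs <- estimate_fractions(bulk, sig0, meta)
    subj_fracs <- global_average(fracs, meta)
    cmp <- compare_fractions(subj_fracs, meta)
    report$deconvolution <- list(comparison = as.data.frame(cmp))
    tables$fractions <- fracs
    tables$fraction_comparison <- cmp
  }

  ## ---- concordance ----
  cn <- config$concord
  internal <- NULL
  striatal <- intersect(c("NAcc", "caudate"), unique(regional$scope))
  if (length(striatal) > 0) {
    internal <- regional[regional$scope == striatal[1], ]
  } else internal <- global
  partner <- NULL
  if (!is.null(sim_block)) {
    partner <- simulate_partner_study(
      truth, universe = background,
      overlap_frac = cn$overlap_frac, sign_agreement = cn$sign_agreement,
      n_report = min(cn$n_report, length(background)),
      seed = derive_seed(seed, "partner"))
    truth$partner_shared <- attr(partner, "shared_genes")
  } else if (!is.null(config$inputs$partner)) {
    partner <- readr::read_tsv(config$inputs$partner, show_col_types = FALSE)
  }
  if (!is.null(partner)) {
    conc <- concordance(internal, partner, fdr = cn$fdr)
    report$concordance <- list(
      scope = internal$scope[1],
      n_matched = conc$correlation$n_matched,
      r = conc$correlation$r,
      p_r = conc$correlation$p_r,
      lambda = conc$bum$lambda, a = conc$bum$a,
      pihat = conc$bum$pihat,
      signal_fraction = conc$bum$signal_fraction,
      tau = conc$tau,
      n_below_tau = conc$congruence$n_below_tau,
      n_congruent = conc$congruence$n_congruent
    )
    tables$partner <- partner
    tables$matched <- conc$matched
  }

  out <- list(report = report, tables = tables, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      tbl <- tables[[nm]]
      tbl <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(tbl, file.path(outdir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(out)
}
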