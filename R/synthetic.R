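#' Configure a synthetic case-control brain RNA-seq study
#'
#' Builds the configuration object consumed by [simulate_study()]. Defaults
#' emulate a post-mortem design of 7 cases and 8 unaffected comparison
#' subjects, each sampled in two cortical regions (BA11, BA47) and two
#' striatal regions (caudate, NAcc), with planted differential expression
#' concentrated in the striatum and a strong shared signal between the two
#' cortical regions.
#'
#' @param n_cases,n_controls Number of case and comparison subjects.
#' @param regions Character vector of region labels; every subject
#'   contributes one sample per region.
#' @param cortical_regions Subset of `regions` sharing a subject-level latent
#'   signal (they are biological near-replicates of one another).
#' @param n_genes Number of genes in the simulated universe.
#' @param n_de_global Number of genes with a diagnosis effect in every region.
#' @param n_de_regional Named integer vector, region -> number of genes with
#'   a diagnosis effect only in that region.
#' @param de_log2fc Absolute planted effect size, log2 units; signs are
#'   assigned at random per gene.
#' @param cortical_corr Target between-cortical-region consensus correlation
#'   in `[0, 1)` (per-subject, gene-centered Pearson; see
#'   [consensus_correlation()]).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param lib_size_range Range of per-sample library sizes (total counts).
#' @param covariate_effect_sizes Named vector of per-gene coefficient
#'   standard deviations (log2 units per standardized covariate unit) for
#'   covariates injected into expression; names among `sex`, `ph`, `age`,
#'   `pmi`, `rin`.
#' @param biological_sd Per-sample residual biological standard deviation on
#'   the log2 scale.
#' @param seed Integer seed; identical configurations give bitwise-identical
#'   output.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_cases = 7,
                         n_controls = 8,
                         regions = c("BA11", "BA47", "caudate", "NAcc"),
                         cortical_regions = c("BA11", "BA47"),
                         n_genes = 2000,
                         n_de_global = 100,
                         n_de_regional = c(caudate = 20, NAcc = 50),
                         de_log2fc = 1,
                         cortical_corr = 0.71,
                         dispersion = 0.1,
                         lib_size_range = c(1e6, 2e6),
                         covariate_effect_sizes = c(sex = 0.2, ph = 0.3),
                         biological_sd = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls,
    regions = regions, cortical_regions = cortical_regions,
    n_genes = n_genes, n_de_global = n_de_global,
    n_de_regional = n_de_regional, de_log2fc = de_log2fc,
    cortical_corr = cortical_corr, dispersion = dispersion,
    lib_size_range = lib_size_range,
    covariate_effect_sizes = covariate_effect_sizes,
    biological_sd = biological_sd, seed = as.integer(seed)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  counts <- c(cfg$n_cases, cfg$n_controls, cfg$n_genes, cfg$n_de_global,
              cfg$n_de_regional)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (cfg$n_de_global > cfg$n_genes) {
    stop("n_de_global exceeds n_genes", call. = FALSE)
  }
  if (cfg$n_de_global + sum(cfg$n_de_regional) > cfg$n_genes) {
    stop("planted DE genes exceed the gene universe", call. = FALSE)
  }
  if (cfg$cortical_corr < 0 || cfg$cortical_corr >= 1) {
    stop("cortical_corr must be in [0, 1)", call. = FALSE)
  }
  if (cfg$dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (!all(names(cfg$n_de_regional) %in% cfg$regions)) {
    stop("n_de_regional names must be regions", call. = FALSE)
  }
  if (!all(cfg$cortical_regions %in% cfg$regions)) {
    stop("cortical_regions must be a subset of regions", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a complete multi-region case-control RNA-seq study
#'
#' Draws negative-binomial counts for every gene and sample under a
#' log-normal baseline model, with planted diagnosis effects (global and
#' region-specific), gene-level covariate effects for sex and tissue pH, and
#' a shared subject-level latent signal between the cortical regions sized so
#' that the gene-centered between-region correlation of log2 CPM lands near
#' `cortical_corr` after negative-binomial measurement noise is accounted
#' for.
#'
#' @param config A [study_config()] object.
#'
#' @return A list with components:
#' \describe{
#'   \item{counts}{tibble, `gene` column plus one integer column per sample.}
#'   \item{meta}{tibble of sample metadata: `sample`, `subject`, `region`,
#'     `diagnosis` (`case`/`comparison`), `sex`, `age`, `pmi`, `ph`, `rin`.}
#'   \item{truth}{list with `de_genes` (tibble `scope`, `gene`, `log2fc`)
#'     recording every planted effect.}
#' }
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  subjects <- c(sprintf("case_%02d", seq_len(cfg$n_cases)),
                sprintf("ctrl_%02d", seq_len(cfg$n_controls)))
  diagnosis <- rep(c("case", "comparison"), c(cfg$n_cases, cfg$n_controls))

  subj <- tibble::tibble(
    subject = subjects,
    diagnosis = diagnosis,
    # sexes balanced within group, as in a matched design
    sex = unlist(lapply(c(cfg$n_cases, cfg$n_controls), function(n) {
      rep_len(c("M", "F"), n)
    })),
    age = pmin(pmax(stats::rnorm(length(subjects), 47.5, 14), 20), 70),
    pmi = pmax(stats::rnorm(length(subjects), 16.5, 6.5), 2),
    ph = stats::rnorm(length(subjects), 6.65, 0.15),
    rin = pmin(pmax(stats::rnorm(length(subjects), 7.7, 0.55), 5), 10)
  )

  meta <- tidyr::crossing(subj, region = cfg$regions) |>
    dplyr::mutate(sample = paste(.data$subject, .data$region, sep = "_")) |>
    dplyr::select("sample", "subject", "region", "diagnosis", "sex",
                  "age", "pmi", "ph", "rin") |>
    dplyr::arrange(.data$subject, .data$region)

  n_s <- nrow(meta)

  # planted effects: global genes first, then disjoint per-region genes
  pool <- sample(genes)
  de_global <- utils::head(pool, cfg$n_de_global)
  pool <- setdiff(pool, de_global)
  de_regional <- list()
  for (r in names(cfg$n_de_regional)) {
    take <- utils::head(pool, cfg$n_de_regional[[r]])
    de_regional[[r]] <- take
    pool <- setdiff(pool, take)
  }
  sign_of <- function(k) sample(c(-1, 1), k, replace = TRUE)
  truth_de <- dplyr::bind_rows(
    tibble::tibble(scope = "global", gene = de_global,
                   log2fc = cfg$de_log2fc * sign_of(length(de_global))),
    purrr::imap_dfr(de_regional, function(g, r) {
      tibble::tibble(scope = r, gene = g,
                     log2fc = cfg$de_log2fc * sign_of(length(g)))
    })
  )

  base <- stats::rnorm(cfg$n_genes, 3, 2)           # log2 relative abundance
  log2x <- matrix(base, cfg$n_genes, n_s)
  rownames(log2x) <- genes
  colnames(log2x) <- meta$sample

  # gene-level covariate effects on standardized covariates
  for (cv in names(cfg$covariate_effect_sizes)) {
    v <- if (cv == "sex") as.numeric(meta$sex == "M") else meta[[cv]]
    v <- as.numeric(scale(v))
    if (any(!is.finite(v))) v[] <- 0
    beta <- stats::rnorm(cfg$n_genes, 0, cfg$covariate_effect_sizes[[cv]])
    log2x <- log2x + outer(beta, v)
  }

  # diagnosis effects
  is_case <- meta$diagnosis == "case"
  for (i in seq_len(nrow(truth_de))) {
    g <- truth_de$gene[i]
    cols <- if (truth_de$scope[i] == "global") is_case
            else is_case & meta$region == truth_de$scope[i]
    log2x[g, cols] <- log2x[g, cols] + truth_de$log2fc[i]
  }

  # shared cortical latent signal, scaled to hit the target gene-centered
  # correlation of log2 CPM after NB measurement noise dilutes it
  sigma_r <- cfg$biological_sd
  w <- 2^base
  cpm_exp <- 1e6 * w / sum(w)
  mu_exp <- mean(cfg$lib_size_range) * w / sum(w)
  shrink <- (cpm_exp / (cpm_exp + 1))^2
  m_g <- shrink * (1 / log(2))^2 * (cfg$dispersion + 1 / pmax(mu_exp, 0.5))
  m_hat <- mean(m_g[cpm_exp >= 1])
  rho <- cfg$cortical_corr
  sigma_sh <- if (rho > 0) sqrt(rho / (1 - rho) * (sigma_r^2 + m_hat)) else 0

  if (sigma_sh > 0 && length(cfg$cortical_regions) >= 2) {
    for (s in subjects) {
      u <- stats::rnorm(cfg$n_genes, 0, sigma_sh)
      cols <- meta$subject == s & meta$region %in% cfg$cortical_regions
      log2x[, cols] <- log2x[, cols] + u
    }
  }

  # residual biological noise, all samples
  log2x <- log2x + matrix(stats::rnorm(cfg$n_genes * n_s, 0, sigma_r),
                          cfg$n_genes, n_s)

  lib <- stats::runif(n_s, cfg$lib_size_range[1], cfg$lib_size_range[2])
  wmat <- 2^log2x
  mu <- sweep(wmat, 2, lib / colSums(wmat), `*`)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
    cfg$n_genes, n_s, dimnames = dimnames(mu)
  )

  list(
    counts = matrix_to_expr(counts),
    meta = meta,
    truth = list(de_genes = truth_de,
                 enriched_sets = character(0),
                 true_fractions = NULL,
                 partner_shared = character(0))
  )
}

#' Simulate gene-set collections with planted enrichment
#'
#' Generates `n_sets` gene sets over a gene universe; the first `n_planted`
#' sets are composed preferentially of planted differentially expressed
#' genes, with a configurable bias toward the downregulated ones, so that
#' downstream Fisher enrichment and directionality statistics have known
#' positives.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of sets to emit.
#' @param set_size_range Length-2 integer range of set sizes (inclusive).
#' @param n_planted Number of enriched (DE-loaded) sets.
#' @param truth Ground-truth list from [simulate_study()] (required when
#'   `n_planted > 0`).
#' @param scope Truth scope whose DE genes seed the planted sets.
#' @param de_member_frac Fraction of each planted set drawn from DE genes.
#' @param down_bias Probability that a DE member is drawn from the
#'   downregulated pool (1 forces all DE members downregulated).
#' @param seed Integer seed.
#'
#' @return A list with `sets` (named list of character vectors, GMT-ready)
#'   and `planted` (names of the enriched sets).
#' @export
simulate_gene_sets <- function(universe, n_sets = 50,
                               set_size_range = c(10, 40),
                               n_planted = 5, truth = NULL,
                               scope = "global",
                               de_member_frac = 0.8, down_bias = 0.75,
                               seed = 1L) {
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  if (max(set_size_range) > length(universe)) {
    stop("set sizes exceed universe size", call. = FALSE)
  }
  if (n_planted > 0 && is.null(truth)) {
    stop("truth required to plant enriched sets", call. = FALSE)
  }
  withr::with_seed(seed, {
    de <- if (!is.null(truth)) {
      dplyr::filter(truth$de_genes, .data$scope == !!scope,
                    .data$gene %in% universe)
    } else tibble::tibble(gene = character(), log2fc = numeric())
    down_pool <- de$gene[de$log2fc < 0]
    up_pool <- de$gene[de$log2fc > 0]
    filler_pool <- setdiff(universe, de$gene)

    sets <- vector("list", n_sets)
    names(sets) <- sprintf("set_%03d", seq_len(n_sets))
    for (i in seq_len(n_sets)) {
      size <- if (set_size_range[1] == set_size_range[2]) set_size_range[1]
              else sample(seq(set_size_range[1], set_size_range[2]), 1)
      if (i <= n_planted) {
        n_de <- min(round(de_member_frac * size), length(down_pool) + length(up_pool))
        take_down <- sum(stats::runif(n_de) < down_bias)
        take_down <- min(take_down, length(down_pool))
        take_up <- min(n_de - take_down, length(up_pool))
        members <- c(sample(down_pool, take_down),
                     sample(up_pool, take_up))
        members <- c(members,
                     sample(filler_pool, size - length(members)))
      } else {
        members <- sample(filler_pool, min(size, length(filler_pool)))
      }
      sets[[i]] <- unique(members)
    }
    list(sets = sets, planted = names(sets)[seq_len(n_planted)])
  })
}

#' Simulate bulk expression as a convolution of cell-type signatures
#'
#' Bulk expression of gene g in sample s is
#' `sum_k fractions[s, k] * signature[g, k]` plus Gaussian noise truncated at
#' zero, the linear mixing model that signature-based deconvolution inverts.
#'
#' @param signature Tibble, `gene` column plus one column of linear-scale
#'   mean expression per cell type.
#' @param fractions Tibble, `sample` column plus one fraction column per cell
#'   type; rows must be nonnegative and sum to 1.
#' @param noise_sd Standard deviation of additive Gaussian noise (truncated
#'   at 0); 0 for noiseless mixtures.
#' @param seed Integer seed.
#'
#' @return Expression tibble (`gene` + samples).
#' @export
simulate_mixtures <- function(signature, fractions, noise_sd = 0, seed = 1L) {
  S <- expr_to_matrix(signature)
  stopifnot("sample" %in% names(fractions))
  f_types <- setdiff(names(fractions), "sample")
  if (!setequal(f_types, colnames(S))) {
    stop("fraction cell types do not match signature columns", call. = FALSE)
  }
  f <- as.matrix(fractions[, colnames(S), drop = FALSE])
  if (any(f < 0)) stop("negative fractions", call. = FALSE)
  if (any(abs(rowSums(f) - 1) > 1e-9)) {
    stop("fraction rows must sum to 1", call. = FALSE)
  }
  bulk <- S %*% t(f)
  colnames(bulk) <- fractions$sample
  if (noise_sd > 0) {
    bulk <- withr::with_seed(seed, {
      pmax(bulk + matrix(stats::rnorm(length(bulk), 0, noise_sd),
                         nrow(bulk), ncol(bulk)), 0)
    })
  }
  matrix_to_expr(bulk)
}

#' Simulate a cell-type reference expression table with planted markers
#'
#' Each cell type receives a dedicated block of marker genes whose mean
#' expression is `marker_fc`-fold above all other types; the remaining genes
#' share a common log-normal profile.
#'
#' @param cell_types Character vector of cell-type labels.
#' @param n_genes Total genes in the reference.
#' @param n_markers Planted markers per cell type.
#' @param marker_fc Fold elevation of a marker in its own type.
#' @param seed Integer seed.
#'
#' @return List with `reference` (tibble `gene` + cell-type columns,
#'   linear-scale means) and `markers` (named list of planted marker ids).
#' @export
simulate_reference <- function(cell_types = c(
                                 "astrocyte", "ependymal",
                                 "excitatory_neuron", "immune",
                                 "interneuron", "oligodendrocyte",
                                 "medium_spiny_neuron", "vascular"),
                               n_genes = 400, n_markers = 15,
                               marker_fc = 8, seed = 1L) {
  k <- length(cell_types)
  if (n_markers * k > n_genes) stop("too many markers for n_genes", call. = FALSE)
  withr::with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    base <- 2^stats::rnorm(n_genes, 4, 1)
    ref <- matrix(rep(base, k), n_genes, k,
                  dimnames = list(genes, cell_types))
    # mild type-specific jitter so types are not exactly collinear
    ref <- ref * 2^matrix(stats::rnorm(n_genes * k, 0, 0.25), n_genes, k)
    markers <- list()
    idx <- 1
    for (ct in cell_types) {
      rows <- seq(idx, idx + n_markers - 1)
      ref[rows, ct] <- ref[rows, ct] * marker_fc
      markers[[ct]] <- genes[rows]
      idx <- idx + n_markers
    }
    list(reference = matrix_to_expr(ref), markers = markers)
  })
}

#' Simulate a partner study's differentially-expressed-gene table
#'
#' Emulates an external study that reports only genes passing an uncorrected
#' p < 0.01 cutoff: a configurable fraction of the reported genes are true DE
#' genes of the current study (with sign agreement probability per gene), the
#' remainder are unrelated genes with null effects.
#'
#' @param truth Ground-truth list from [simulate_study()].
#' @param universe Gene universe to report from.
#' @param scope Truth scope supplying the shared DE genes.
#' @param overlap_frac Fraction of reported genes that are true DE genes.
#' @param sign_agreement Probability a shared gene's log2FC sign matches the
#'   planted sign.
#' @param n_report Number of genes reported.
#' @param seed Integer seed.
#'
#' @return Tibble `gene`, `log2fc`, `p` (all p < 0.01), with the shared true
#'   DE gene ids in attribute `shared_genes`.
#' @export
simulate_partner_study <- function(truth, universe, scope = "global",
                                   overlap_frac = 0.5, sign_agreement = 0.9,
                                   n_report = 200, seed = 1L) {
  if (n_report > length(universe)) {
    stop("n_report exceeds gene universe size", call. = FALSE)
  }
  stopifnot(overlap_frac >= 0, overlap_frac <= 1,
            sign_agreement >= 0, sign_agreement <= 1)
  withr::with_seed(seed, {
    de <- dplyr::filter(truth$de_genes, .data$scope == !!scope,
                        .data$gene %in% universe)
    n_shared <- min(round(overlap_frac * n_report), nrow(de))
    shared <- if (n_shared > 0) dplyr::slice_sample(de, n = n_shared)
              else de[0, ]
    others <- sample(setdiff(universe, truth$de_genes$gene),
                     n_report - nrow(shared))
    flip <- ifelse(stats::runif(nrow(shared)) < sign_agreement, 1, -1)
    tab <- dplyr::bind_rows(
      tibble::tibble(
        gene = shared$gene,
        log2fc = flip * sign(shared$log2fc) *
          abs(stats::rnorm(nrow(shared), abs(shared$log2fc), 0.3))
      ),
      tibble::tibble(gene = others,
                     log2fc = stats::rnorm(length(others), 0, 0.5))
    )
    tab$p <- stats::runif(nrow(tab), 1e-6, 0.0099999)
    tab <- dplyr::slice_sample(tab, n = nrow(tab))  # shuffle row order
    attr(tab, "shared_genes") <- shared$gene
    tab
  })
}
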