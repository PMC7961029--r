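# Shared fixtures, built in code. Expensive simulated studies are cached in
# this environment so several test files can reuse them.
.fixtures <- new.env(parent = emptyenv())

expr_tbl <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  neurobulk:::matrix_to_expr(m)
}

tiny_meta <- function(samples, region = "A", subject = samples,
                      diagnosis = "case") {
  tibble::tibble(sample = samples, subject = subject,
                 region = rep_len(region, length(samples)),
                 diagnosis = rep_len(diagnosis, length(samples)))
}

# default-sized study (7 vs 8 subjects, 4 regions, 2000 genes), shared
default_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study(study_config(seed = 101L))
  }
  .fixtures$study
}

default_logexpr <- function() {
  if (is.null(.fixtures$logexpr)) {
    .fixtures$logexpr <- normalize_log(default_study()$counts)
  }
  .fixtures$logexpr
}

default_global_de <- function() {
  if (is.null(.fixtures$global_de)) {
    st <- default_study()
    mg <- merge_regions(default_logexpr(), st$meta, c("BA11", "BA47"), "OFC")
    .fixtures$global_de <- fit_global(
      mg$expr, mg$meta, de_model_spec(candidates = character(0)))
  }
  .fixtures$global_de
}

# a small study for fast repeated simulations
small_config <- function(seed, n_genes = 300, n_de_global = 30,
                         n_de_regional = c(caudate = 0, NAcc = 0), ...) {
  study_config(n_genes = n_genes, n_de_global = n_de_global,
               n_de_regional = n_de_regional, seed = seed, ...)
}

# merge the cortical pair (the pipeline's own first analysis step, which
# folds the shared cortical latent into per-sample noise) then fit globally
fit_merged_global <- function(st) {
  lx <- normalize_log(st$counts)
  mg <- merge_regions(lx, st$meta, c("BA11", "BA47"), "OFC")
  fit_global(mg$expr, mg$meta, de_model_spec(candidates = character(0)))
}

# independent brute-force hypergeometric upper-tail oracle
hyper_tail <- function(k, K, n, N) {
  ks <- seq(k, min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
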