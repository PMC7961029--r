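frac_row <- function(types, values) {
  dplyr::bind_cols(tibble::tibble(sample = "s1"),
                   tibble::as_tibble(as.list(stats::setNames(values, types))))
}

test_that("build_signature selects planted markers", {
  ref <- simulate_reference(n_genes = 200, n_markers = 10, seed = 13L)
  sig <- build_signature(ref$reference, n_markers = 10)
  markers <- attr(sig, "markers")
  for (ct in names(ref$markers)) {
    expect_setequal(markers[[ct]], ref$markers[[ct]])
  }
  # diagonal reference -> each type keeps its unique gene
  d <- expr_tbl(diag(c(5, 7, 9)))
  names(d)[-1] <- c("t1", "t2", "t3")
  suppressWarnings(sd2 <- build_signature(d, n_markers = 1))
  expect_setequal(attr(sd2, "markers")$t1, "g01")
  # identical cell types: no positive-ratio markers, warning path
  same <- expr_tbl(cbind(a = c(3, 4), b = c(3, 4)))
  expect_error(suppressWarnings(build_signature(same, n_markers = 1)),
               "no marker genes")
})

test_that("fractions are recovered exactly on noiseless mixtures", {
  ref <- simulate_reference(n_genes = 240, n_markers = 12, seed = 19L)
  types <- setdiff(names(ref$reference), "gene")
  sig <- build_signature(ref$reference, 12)
  meta1 <- tibble::tibble(sample = "s1", region = "unrestricted")

  one <- rep(0, length(types)); one[3] <- 1
  bulk1 <- simulate_mixtures(ref$reference, frac_row(types, one), 0)
  est1 <- estimate_fractions(bulk1, sig, meta1)
  expect_equal(est1$fraction[est1$cell_type == types[3]], 1, tolerance = 1e-6)

  half <- rep(0, length(types)); half[c(1, 4)] <- 0.5
  bulk2 <- simulate_mixtures(ref$reference, frac_row(types, half), 0)
  est2 <- estimate_fractions(bulk2, sig, meta1)
  expect_equal(est2$fraction[est2$cell_type %in% types[c(1, 4)]],
               c(0.5, 0.5), tolerance = 1e-6)

  # random compositions, still exact with a full-rank signature
  withr::with_seed(43, {
    for (i in 1:5) {
      f <- rgamma(length(types), 2); f <- f / sum(f)
      bulk <- simulate_mixtures(ref$reference, frac_row(types, f), 0)
      est <- estimate_fractions(bulk, sig, meta1)
      expect_equal(est$fraction[match(types, est$cell_type)], f,
                   tolerance = 1e-6)
    }
  })
})

test_that("noisy mixtures are recovered with small mean error", {
  ref <- simulate_reference(n_genes = 400, n_markers = 15, seed = 23L)
  types <- setdiff(names(ref$reference), "gene")
  sig <- build_signature(ref$reference, 15)
  withr::with_seed(47, {
    f <- t(vapply(1:30, function(i) {
      x <- rgamma(length(types), 4); x / sum(x)
    }, numeric(length(types))))
    colnames(f) <- types
    fr <- dplyr::bind_cols(tibble::tibble(sample = sprintf("m%02d", 1:30)),
                           tibble::as_tibble(f))
  })
  noise <- 0.05 * mean(neurobulk:::expr_to_matrix(ref$reference))
  bulk <- simulate_mixtures(ref$reference, fr, noise_sd = noise, seed = 53L)
  meta <- tibble::tibble(sample = fr$sample, region = "unrestricted")
  est <- estimate_fractions(bulk, sig, meta)
  wide <- tidyr::pivot_wider(est, id_cols = "sample",
                             names_from = "cell_type",
                             values_from = "fraction")
  err <- abs(as.matrix(wide[match(fr$sample, wide$sample), types]) -
               as.matrix(fr[, types]))
  expect_lt(mean(err), 0.05)
})

test_that("estimates are invariant to bulk scaling and respect panels", {
  ref <- simulate_reference(n_genes = 240, n_markers = 12, seed = 29L)
  types <- setdiff(names(ref$reference), "gene")
  sig <- build_signature(ref$reference, 12)
  withr::with_seed(59, {
    f <- rgamma(length(types), 3); f <- f / sum(f)
  })
  bulk <- simulate_mixtures(ref$reference, frac_row(types, f), 0)
  meta1 <- tibble::tibble(sample = "s1", region = "unrestricted")
  scaled <- bulk; scaled[[2]] <- scaled[[2]] * 37.5
  a <- estimate_fractions(bulk, sig, meta1)
  b <- estimate_fractions(scaled, sig, meta1)
  expect_equal(a$fraction, b$fraction, tolerance = 1e-9)

  # region panels: no MSN in cortex, no excitatory neurons in striatum
  meta_c <- tibble::tibble(sample = "s1", region = "BA11")
  meta_s <- tibble::tibble(sample = "s1", region = "caudate")
  est_c <- estimate_fractions(bulk, sig, meta_c)
  est_s <- estimate_fractions(bulk, sig, meta_s)
  expect_false("medium_spiny_neuron" %in% est_c$cell_type)
  expect_false("excitatory_neuron" %in% est_s$cell_type)
  expect_equal(sum(est_c$fraction), 1, tolerance = 1e-9)
  expect_error(estimate_fractions(
    expr_tbl(matrix(0, 240, 1, dimnames = list(ref$reference$gene, "z"))),
    sig, tibble::tibble(sample = "z", region = "BA11")), "all-zero")
})

test_that("global averaging follows region availability", {
  fr <- tibble::tibble(
    sample = c("u1_OFC", "u1_caudate", "u1_NAcc", "u1_OFC"),
    region = c("OFC", "caudate", "NAcc", "OFC"),
    cell_type = c("astrocyte", "astrocyte", "astrocyte",
                  "excitatory_neuron"),
    fraction = c(0.2, 0.3, 0.4, 0.15))
  meta <- tibble::tibble(sample = unique(fr$sample),
                         subject = "u1")
  out <- global_average(fr, meta)
  expect_equal(out$fraction[out$cell_type == "astrocyte"], 0.3)
  expect_equal(out$fraction[out$cell_type == "excitatory_neuron"], 0.15)
})

test_that("fraction comparison equals a pooled t-test without covariates", {
  withr::with_seed(61, {
    fr <- tibble::tibble(
      subject = sprintf("u%02d", 1:16),
      cell_type = "astrocyte",
      fraction = c(rnorm(8, 0.3, 0.03), rnorm(8, 0.25, 0.03)))
    meta <- tibble::tibble(subject = fr$subject,
                           diagnosis = rep(c("case", "comparison"), each = 8))
    out <- compare_fractions(fr, meta, covariates = character(0))
    ref <- t.test(fraction ~ I(diagnosis == "case"), data = fr |>
                    dplyr::left_join(meta, by = "subject"),
                  var.equal = TRUE)
    expect_equal(out$p, ref$p.value, tolerance = 1e-12)
    expect_equal(out$estimate, mean(fr$fraction[1:8]) -
                   mean(fr$fraction[9:16]), tolerance = 1e-12)
  })
})

test_that("a planted fraction shift is detected with good power", {
  ref <- simulate_reference(n_genes = 400, n_markers = 15, seed = 67L)
  hits <- vapply(1:50, function(s) {
    meta <- tibble::tibble(
      sample = sprintf("u%02d_X", 1:15),
      subject = sprintf("u%02d", 1:15),
      region = "unrestricted",
      diagnosis = rep(c("case", "comparison"), c(7, 8)))
    fr <- simulate_fractions(meta, base_alpha = 8,
                             shifts = c(astrocyte = 0.1),
                             jitter_sd = 0.02, seed = 100L + s)
    sig <- build_signature(ref$reference, 15)
    bulk <- simulate_mixtures(ref$reference, fr$sample_fractions,
                              noise_sd = 1, seed = 200L + s)
    est <- estimate_fractions(bulk, sig, meta)
    subj <- global_average(est, meta)
    cmp <- compare_fractions(subj, meta, covariates = character(0))
    cmp$p[cmp$cell_type == "astrocyte"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("null fraction comparisons give uniform p-values", {
  withr::with_seed(71, {
    ps <- vapply(1:200, function(i) {
      fr <- tibble::tibble(subject = sprintf("u%02d", 1:16),
                           cell_type = "astrocyte",
                           fraction = rnorm(16, 0.3, 0.05))
      meta <- tibble::tibble(subject = fr$subject,
                             diagnosis = rep(c("case", "comparison"),
                                             each = 8))
      compare_fractions(fr, meta, covariates = character(0))$p
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  })
})

test_that("constant fractions are reported as untestable", {
  fr <- tibble::tibble(subject = sprintf("u%02d", 1:6),
                       cell_type = "ependymal", fraction = 0.1)
  meta <- tibble::tibble(subject = fr$subject,
                         diagnosis = rep(c("case", "comparison"), each = 3))
  out <- compare_fractions(fr, meta, covariates = character(0))
  expect_true(is.na(out$p))
})
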