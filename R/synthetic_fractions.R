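#' Simulate subject cell-type fractions with a diagnosis shift
#'
#' Draws each subject's global cell-type composition from a Dirichlet
#' distribution and applies additive shifts to selected types in case
#' subjects (renormalizing afterwards), emulating disease-associated
#' composition changes. Per-sample fractions restrict the subject's
#' composition to the region's allowed panel (cortical samples carry no
#' medium spiny neurons, striatal samples no excitatory neurons) with a
#' small region-level jitter.
#'
#' @param meta Sample metadata from [simulate_study()].
#' @param cell_types Cell-type labels (default the 8 broad brain types of
#'   [simulate_reference()]).
#' @param base_alpha Dirichlet concentration per type (recycled).
#' @param shifts Named vector of additive fraction shifts applied to case
#'   subjects (e.g. `c(medium_spiny_neuron = -0.06)`).
#' @param jitter_sd Per-sample lognormal jitter of the subject composition.
#' @param region_classes,panel_exclusions Region panel restrictions, as in
#'   [estimate_fractions()].
#' @param seed Integer seed.
#' @return List with `sample_fractions` (tibble `sample` + cell-type
#'   columns, rows summing to 1 with excluded types at 0) and
#'   `subject_fractions` (the ground-truth tibble `subject` + cell-type
#'   columns, pre-restriction).
#' @export
simulate_fractions <- function(meta,
                               cell_types = c(
                                 "astrocyte", "ependymal",
                                 "excitatory_neuron", "immune",
                                 "interneuron", "oligodendrocyte",
                                 "medium_spiny_neuron", "vascular"),
                               base_alpha = 30,
                               shifts = c(medium_spiny_neuron = -0.04,
                                          astrocyte = 0.04,
                                          vascular = 0.035),
                               jitter_sd = 0.05,
                               region_classes = default_region_classes(),
                               panel_exclusions = default_panel_exclusions(),
                               seed = 1L) {
  stopifnot(all(names(shifts) %in% cell_types))
  withr::with_seed(seed, {
    subj <- dplyr::distinct(meta, .data$subject, .data$diagnosis)
    k <- length(cell_types)
    alpha <- rep_len(base_alpha, k)
    g <- matrix(stats::rgamma(nrow(subj) * k, shape = alpha, rate = 1),
                nrow(subj), k, byrow = TRUE)
    f <- g / rowSums(g)
    colnames(f) <- cell_types
    is_case <- subj$diagnosis == "case"
    for (ct in names(shifts)) {
      f[is_case, ct] <- pmax(f[is_case, ct] + shifts[[ct]], 0)
    }
    f <- f / rowSums(f)
    subject_fractions <- dplyr::bind_cols(
      tibble::tibble(subject = subj$subject),
      tibble::as_tibble(f)
    )

    sample_fractions <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
      fs <- f[match(meta$subject[i], subj$subject), ]
      cls <- region_classes[meta$region[i]]
      if (!is.na(cls)) fs[panel_exclusions[[cls]]] <- 0
      fs <- fs * exp(stats::rnorm(k, 0, jitter_sd))
      fs[f[match(meta$subject[i], subj$subject), ] == 0] <- 0
      fs <- fs / sum(fs)
      dplyr::bind_cols(tibble::tibble(sample = meta$sample[i]),
                       tibble::as_tibble(as.list(fs)))
    })
    list(sample_fractions = sample_fractions,
         subject_fractions = subject_fractions)
  })
}
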