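#' Build a marker-gene signature matrix from a cell-type reference
#'
#' For each cell type, ranks genes by the ratio of that type's mean
#' expression to the maximum mean over all other types and keeps the top
#' `n_markers` genes with ratio > 1 (i.e. genes genuinely enriched in the
#' type). The signature is the reference restricted to the union of selected
#' markers, on the linear scale required by the additive mixing model.
#'
#' @param reference Tibble, `gene` column plus one column of linear-scale
#'   mean expression per cell type (>= 2 types).
#' @param n_markers Markers requested per cell type; if fewer genes have
#'   ratio > 1 the available ones are used with a warning.
#' @return Signature tibble (`gene` + cell-type columns) with the selected
#'   markers per type in attribute `markers`.
#' @export
build_signature <- function(reference, n_markers = 20) {
  ref <- expr_to_matrix(reference)
  if (ncol(ref) < 2) stop("need >= 2 cell types", call. = FALSE)
  if (any(ref < 0)) stop("reference must be nonnegative", call. = FALSE)
  markers <- list()
  for (ct in colnames(ref)) {
    others <- ref[, setdiff(colnames(ref), ct), drop = FALSE]
    max_other <- apply(others, 1, max)
    ratio <- ref[, ct] / pmax(max_other, .Machine$double.eps)
    ratio[ref[, ct] == 0] <- 0
    eligible <- names(ratio)[ratio > 1]
    if (length(eligible) < n_markers) {
      warning("cell type ", ct, ": only ", length(eligible),
              " marker(s) with positive enrichment ratio")
    }
    take <- utils::head(eligible[order(ratio[eligible], decreasing = TRUE)],
                        n_markers)
    markers[[ct]] <- take
  }
  sel <- unique(unlist(markers))
  if (length(sel) == 0) {
    stop("no marker genes could be selected for any cell type",
         call. = FALSE)
  }
  out <- matrix_to_expr(ref[sel, , drop = FALSE])
  attr(out, "markers") <- markers
  out
}

#' Region classes and panel exclusions for brain deconvolution
#'
#' Cortical tissue contains no medium spiny neurons and striatal tissue no
#' excitatory (cortical projection) neurons, so each region is solved over a
#' reduced cell-type panel. These defaults match an orbitofrontal +
#' striatal sampling design.
#' @keywords internal
default_region_classes <- function() {
  c(BA11 = "cortical", BA47 = "cortical", OFC = "cortical",
    caudate = "striatal", NAcc = "striatal")
}

default_panel_exclusions <- function() {
  list(cortical = "medium_spiny_neuron", striatal = "excitatory_neuron")
}

#' Estimate cell-type fractions by nonnegative least squares
#'
#' Solves `bulk ≈ signature %*% f` per sample over the marker genes with
#' `f >= 0`, then renormalizes `f` to sum to 1. Each sample is solved over
#' the cell-type panel allowed for its region class: cortical samples
#' exclude medium spiny neurons, striatal samples exclude excitatory
#' neurons (configurable).
#'
#' @param bulk Bulk expression tibble (`gene` + samples), linear scale.
#' @param signature Signature tibble from [build_signature()].
#' @param meta Sample metadata with `sample` and `region` (and optionally
#'   `subject`) columns.
#' @param region_classes Named vector mapping region label -> class; regions
#'   not listed use the full panel.
#' @param panel_exclusions Named list mapping class -> cell types excluded
#'   from that class's panel.
#' @return Long tibble `sample`, `region`, `cell_type`, `fraction`; excluded
#'   cell types are absent from a sample's rows (not zero), and each
#'   sample's fractions sum to 1.
#' @export
estimate_fractions <- function(bulk, signature, meta,
                               region_classes = default_region_classes(),
                               panel_exclusions = default_panel_exclusions()) {
  S_full <- expr_to_matrix(signature)
  B <- expr_to_matrix(bulk)
  common <- intersect(rownames(S_full), rownames(B))
  if (length(common) < ncol(S_full)) {
    stop("fewer shared marker genes than cell types", call. = FALSE)
  }
  check_meta_alignment(colnames(B), meta)
  meta <- meta[match(colnames(B), meta$sample), ]
  purrr::map_dfr(seq_len(ncol(B)), function(i) {
    b <- B[common, i]
    if (all(b == 0)) {
      stop("all-zero bulk sample: ", colnames(B)[i], call. = FALSE)
    }
    region <- meta$region[i]
    cls <- region_classes[region]
    drop_types <- if (!is.na(cls)) panel_exclusions[[cls]] else character(0)
    types <- setdiff(colnames(S_full), drop_types)
    S <- S_full[common, types, drop = FALSE]
    if (length(common) < length(types)) {
      stop("region ", region, ": fewer markers than panel cell types",
           call. = FALSE)
    }
    f <- pracma::lsqnonneg(S, b)$x
    if (sum(f) == 0) f <- rep(1 / length(types), length(types))
    f <- f / sum(f)
    tibble::tibble(sample = colnames(B)[i], region = region,
                   cell_type = types, fraction = f)
  })
}

#' Across-region average cell-type fractions per subject
#'
#' Averages each subject's fractions over the regions in which the cell type
#' exists; a type present in only some of a subject's regions is averaged
#' over those regions alone (e.g. excitatory neurons over cortical regions
#' only).
#'
#' @param fractions Long fractions tibble from [estimate_fractions()].
#' @param meta Sample metadata mapping `sample` to `subject`.
#' @return Tibble `subject`, `cell_type`, `fraction`.
#' @export
global_average <- function(fractions, meta) {
  fractions |>
    dplyr::left_join(dplyr::select(meta, "sample", "subject"), by = "sample") |>
    dplyr::group_by(.data$subject, .data$cell_type) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
}

#' Compare cell-type fractions between diagnosis groups
#'
#' Per cell type, ordinary least squares of the fraction on diagnosis plus
#' covariates; the diagnosis coefficient estimates the case-minus-comparison
#' shift in the fraction. Raw two-sided p-values are reported (as is
#' conventional for cell-composition panels) together with BH q-values.
#'
#' @param fractions Tibble `subject` (or `sample`), `cell_type`, `fraction`
#'   (e.g. from [global_average()]).
#' @param meta Metadata supplying `diagnosis` and the covariates per subject
#'   or sample.
#' @param covariates Adjustment covariates (default sex and pH, mirroring
#'   the differential-expression model).
#' @return Tibble `cell_type`, `estimate`, `se`, `t`, `p`, `q`, `n`; a cell
#'   type with constant fractions gets `NA` statistics.
#' @export
compare_fractions <- function(fractions, meta, covariates = c("sex", "ph")) {
  key <- if ("subject" %in% names(fractions)) "subject" else "sample"
  meta_u <- dplyr::distinct(meta, .data[[key]], .keep_all = TRUE)
  dat <- dplyr::left_join(fractions, meta_u, by = key)
  if (length(unique(dat$diagnosis)) < 2) {
    stop("both diagnosis groups must be present", call. = FALSE)
  }
  dat$diagnosis <- factor(dat$diagnosis, levels = c("comparison", "case"))
  rhs <- paste(c("diagnosis", covariates), collapse = " + ")
  out <- dat |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(d, key_) {
      if (stats::sd(d$fraction) == 0) {
        return(tibble::tibble(estimate = NA_real_, se = NA_real_,
                              t = NA_real_, p = NA_real_, n = nrow(d)))
      }
      fit <- stats::lm(stats::as.formula(paste("fraction ~", rhs)), data = d)
      cf <- unname(summary(fit)$coefficients["diagnosiscase", ])
      tibble::tibble(estimate = cf[1], se = cf[2], t = cf[3], p = cf[4],
                     n = nrow(d))
    }) |>
    dplyr::ungroup()
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}
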