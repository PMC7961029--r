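#' Gene-set co-occurrence (Jaccard) similarity
#'
#' Pairwise similarity between gene sets defined as the fraction of genes
#' present in both sets over the unique genes present in either
#' (`|A ∩ B| / |A ∪ B|`). Sets are first intersected with `restrict_to`
#' (typically the DEG universe); sets left empty by the restriction are
#' dropped with a warning.
#'
#' @param sets Named list of gene sets (>= 2 after restriction).
#' @param restrict_to Optional gene ids to intersect every set with.
#' @return Symmetric numeric matrix `J` with unit diagonal, dimnames = set
#'   names.
#' @export
set_cooccurrence <- function(sets, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    sets <- lapply(sets, intersect, y = restrict_to)
    empty <- names(sets)[lengths(sets) == 0]
    if (length(empty) > 0) {
      warning("set(s) empty after restriction dropped: ",
              paste(empty, collapse = ", "))
      sets <- sets[lengths(sets) > 0]
    }
  }
  if (length(sets) < 2) stop("need >= 2 non-empty sets", call. = FALSE)
  sets <- lapply(sets, unique)
  nms <- names(sets)
  m <- length(sets)
  J <- diag(1, m)
  dimnames(J) <- list(nms, nms)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(sets[[i]]) + length(sets[[j]]) - inter
      J[i, j] <- J[j, i] <- inter / uni
    }
  }
  J
}

#' Cluster gene sets by co-occurrence
#'
#' Average-linkage agglomerative clustering on the distance `1 - J`, cut
#' into `k` clusters. Sets are ordered lexicographically by name before
#' clustering so the partition does not depend on input order; clusters are
#' numbered by first appearance in that order.
#'
#' @param J Co-occurrence matrix from [set_cooccurrence()].
#' @param k Number of clusters (default 4 main branches).
#' @return Tibble `set`, `cluster` (integer), with the `hclust` tree in
#'   attribute `dendrogram`.
#' @export
cluster_sets <- function(J, k = 4) {
  if (k < 1 || k > nrow(J)) {
    stop("k must be between 1 and the number of sets", call. = FALSE)
  }
  ord <- order(rownames(J))
  J <- J[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
  cl <- stats::cutree(hc, k = k)
  # renumber clusters by first appearance for label stability
  cl <- as.integer(factor(cl, levels = unique(cl)))
  out <- tibble::tibble(set = rownames(J), cluster = cl)
  attr(out, "dendrogram") <- hc
  out
}

#' Co-occurrence network edges
#'
#' Emits every pair of sets with positive co-occurrence as an undirected
#' edge; an edge is flagged `strong` when at least `strong_threshold` of the
#' union's genes co-occur (default half).
#'
#' @param J Co-occurrence matrix.
#' @param strong_threshold Similarity at or above which an edge is strong,
#'   in `[0, 1]`.
#' @return Tibble `from`, `to`, `jaccard`, `strong`; no self-edges.
#' @export
network_edges <- function(J, strong_threshold = 0.5) {
  stopifnot(strong_threshold >= 0, strong_threshold <= 1)
  nms <- rownames(J)
  idx <- which(upper.tri(J) & J > 0, arr.ind = TRUE)
  tibble::tibble(
    from = nms[idx[, 1]],
    to = nms[idx[, 2]],
    jaccard = J[idx],
    strong = J[idx] >= strong_threshold
  ) |>
    dplyr::arrange(dplyr::desc(.data$jaccard))
}
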