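#' Match two studies' DE tables and correlate log2 fold changes
#'
#' Inner-joins the internal DE results with a partner study's reported DEG
#' table on gene id and computes the Pearson correlation of the two log2FC
#' vectors, with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df.
#'
#' @param internal DE results tibble (`gene`, `log2fc`, `p`, ...).
#' @param partner Partner DEG tibble (`gene`, `log2fc`, `p`).
#' @return One-row tibble `n_matched`, `r`, `p_r`; the matched table
#'   (`gene`, `log2fc_internal`, `p_internal`, `log2fc_partner`,
#'   `p_partner`) is in attribute `matched`.
#' @export
match_and_correlate <- function(internal, partner) {
  if (anyDuplicated(partner$gene) > 0) {
    stop("duplicate gene ids in partner table", call. = FALSE)
  }
  matched <- dplyr::inner_join(
    dplyr::select(internal, "gene", log2fc_internal = "log2fc",
                  p_internal = "p"),
    dplyr::select(partner, "gene", log2fc_partner = "log2fc",
                  p_partner = "p"),
    by = "gene"
  )
  if (nrow(matched) < 3) stop("fewer than 3 matched genes", call. = FALSE)
  r <- stats::cor(matched$log2fc_internal, matched$log2fc_partner)
  out <- tibble::tibble(n_matched = nrow(matched), r = r,
                        p_r = cor_pvalue(r, nrow(matched)))
  attr(out, "matched") <- matched
  out
}

#' Two-sided p-value for a Pearson correlation
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p from the t transform on `n - 2` df.
#' @export
cor_pvalue <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), n - 2)
}

bum_loglik <- function(par, p) {
  lambda <- par[1]; a <- par[2]
  sum(log(lambda + (1 - lambda) * a * p^(a - 1)))
}

#' Fit a beta-uniform mixture model to p-values
#'
#' Maximum-likelihood fit of the density
#' `f(p) = lambda + (1 - lambda) * a * p^(a - 1)` on (0, 1], the standard
#' decomposition of a p-value distribution into a uniform (null) component
#' and a Beta(a, 1) signal component with `0 < a < 1`. The fitted upper
#' bound on the null proportion is `pihat = lambda + (1 - lambda) * a`
#' (the density's value at p = 1), and `1 - pihat` is the estimated signal
#' fraction. Optimization is bounded L-BFGS-B from a fixed lattice of six
#' starting points; p-values of exactly 0 are clamped to machine epsilon
#' with a warning (the Beta density diverges at 0), p = 1 is retained.
#'
#' @param p Vector of p-values in (0, 1], length >= 10.
#' @param eps Box margin keeping both parameters inside
#'   `(eps, 1 - eps)`.
#' @return Object of class `bum_fit`: list with `lambda`, `a`, `loglik`,
#'   `pihat`, `signal_fraction`, `n`.
#' @export
fit_bum <- function(p, eps = 1e-4) {
  if (length(p) < 10) stop("need >= 10 p-values", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to machine epsilon")
    p[p == 0] <- .Machine$double.eps
  }
  starts <- expand.grid(lambda = c(0.1, 0.5, 0.9), a = c(0.15, 0.7))
  objective <- function(par) bum_loglik(par, p)
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(as.numeric(starts[i, ]), fn = objective,
                   method = "L-BFGS-B",
                   lower = c(eps, eps), upper = c(1 - eps, 1 - eps),
                   control = list(fnscale = -1)),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    stop("beta-uniform mixture fit failed to converge from every start",
         call. = FALSE)
  }
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "value"))]]
  lambda <- best$par[1]; a <- best$par[2]
  pihat <- lambda + (1 - lambda) * a
  structure(
    list(lambda = lambda, a = a, loglik = best$value,
         pihat = pihat, signal_fraction = 1 - pihat, n = length(p)),
    class = "bum_fit"
  )
}

#' @export
print.bum_fit <- function(x, ...) {
  cat("Beta-uniform mixture fit (n =", x$n, "p-values)\n")
  cat(sprintf("  lambda = %.4f, a = %.4f, log-likelihood = %.2f\n",
              x$lambda, x$a, x$loglik))
  cat(sprintf("  pihat (null upper bound) = %.4f, signal fraction = %.4f\n",
              x$pihat, x$signal_fraction))
  invisible(x)
}

#' p-value threshold for a target FDR under a beta-uniform mixture
#'
#' Inverts the mixture's FDR expression in closed form:
#' `tau = ((pihat - fdr * lambda) / (fdr * (1 - lambda)))^(1 / (a - 1))`,
#' clipped to `[0, 1]`; when `pihat - fdr * lambda <= 0` the requested FDR
#' is achievable everywhere and `tau = 1`.
#'
#' @param fit A `bum_fit` (or any list with `lambda` and `a`).
#' @param fdr Target false discovery rate in (0, 1).
#' @return The p-value cutoff `tau`.
#' @export
fdr_threshold <- function(fit, fdr = 0.2) {
  stopifnot(fdr > 0, fdr < 1)
  lambda <- fit$lambda; a <- fit$a
  if (is.null(lambda) || is.null(a) || lambda <= 0 || lambda >= 1 ||
      a <= 0 || a >= 1) {
    stop("invalid beta-uniform mixture fit", call. = FALSE)
  }
  pihat <- lambda + (1 - lambda) * a
  num <- pihat - fdr * lambda
  if (num <= 0) return(1)
  tau <- (num / (fdr * (1 - lambda)))^(1 / (a - 1))
  min(max(tau, 0), 1)
}

#' Realized FDR at a p-value cutoff under a beta-uniform mixture
#'
#' `FDR(tau) = pihat * tau / (lambda * tau + (1 - lambda) * tau^a)`, the
#' expression [fdr_threshold()] inverts.
#'
#' @inheritParams fdr_threshold
#' @param tau p-value cutoff in (0, 1].
#' @return The mixture-model FDR at `tau`.
#' @export
bum_fdr <- function(fit, tau) {
  stopifnot(tau > 0, tau <= 1)
  pihat <- fit$lambda + (1 - fit$lambda) * fit$a
  pihat * tau / (fit$lambda * tau + (1 - fit$lambda) * tau^fit$a)
}

#' Direction-congruent genes below a p-value threshold
#'
#' Among matched genes with internal p <= `tau`, counts those whose log2FC
#' signs agree across studies; a zero log2FC in either study is
#' non-congruent.
#'
#' @param matched Matched table from [match_and_correlate()] (attribute
#'   `matched`): columns `gene`, `log2fc_internal`, `p_internal`,
#'   `log2fc_partner`.
#' @param tau p-value cutoff (e.g. from [fdr_threshold()]).
#' @return One-row tibble `n_below_tau`, `n_congruent`; the congruent gene
#'   ids are in attribute `congruent_genes`.
#' @export
congruent_set <- function(matched, tau) {
  below <- matched[matched$p_internal <= tau, , drop = FALSE]
  congruent <- below[sign(below$log2fc_internal) ==
                       sign(below$log2fc_partner) &
                       below$log2fc_internal != 0, , drop = FALSE]
  out <- tibble::tibble(n_below_tau = nrow(below),
                        n_congruent = nrow(congruent))
  attr(out, "congruent_genes") <- congruent$gene
  out
}

#' Full cross-study concordance analysis
#'
#' Matches genes, correlates log2 fold changes, fits the beta-uniform
#' mixture to the internal p-values of the matched genes, derives the
#' p-value cutoff for the requested FDR and counts direction-congruent
#' genes below it.
#'
#' @inheritParams match_and_correlate
#' @param fdr Target FDR for the congruence threshold (default 0.20).
#' @return List: `correlation` (one-row tibble), `bum` (`bum_fit`), `tau`,
#'   `congruence` (one-row tibble), `matched` (the matched table).
#' @export
concordance <- function(internal, partner, fdr = 0.2) {
  corr <- match_and_correlate(internal, partner)
  matched <- attr(corr, "matched")
  fit <- fit_bum(matched$p_internal)
  tau <- fdr_threshold(fit, fdr)
  cong <- congruent_set(matched, tau)
  list(correlation = corr, bum = fit, tau = tau, congruence = cong,
       matched = matched)
}
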