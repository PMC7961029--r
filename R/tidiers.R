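#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a beta-uniform mixture fit
#'
#' @param x A `bum_fit` from [fit_bum()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`lambda`, `a`) and columns
#'   `term`, `estimate`.
#' @method tidy bum_fit
#' @export
tidy.bum_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "a"),
                 estimate = c(x$lambda, x$a))
}

#' One-row summary of a beta-uniform mixture fit
#'
#' @param x A `bum_fit` from [fit_bum()].
#' @param ... Unused.
#' @return One-row tibble: `lambda`, `a`, `pihat`, `signal_fraction`,
#'   `logLik`, `nobs`.
#' @method glance bum_fit
#' @export
glance.bum_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, a = x$a, pihat = x$pihat,
                 signal_fraction = x$signal_fraction,
                 logLik = x$loglik, nobs = x$n)
}
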