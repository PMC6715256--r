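#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a t_c estimate
#'
#' @param x a `tc_estimate` from [estimate_tc()].
#' @param ... unused.
#' @return A tibble with one row per msh observation used, plus the shared
#'   estimate.
#' @exportS3Method generics::tidy
tidy.tc_estimate <- function(x, ...) {
  tibble::tibble(
    copy = seq_len(x$k),
    chi = x$chi,
    kernel = x$observations$kernel,
    t_c = x$t_c,
    loglik = x$loglik
  )
}

#' @rdname tidy.tc_estimate
#' @return `glance()` returns a one-row summary: `t_c`, `loglik`, `k`,
#'   `convergence`, `boundary`, `low_information`.
#' @exportS3Method generics::glance
glance.tc_estimate <- function(x, ...) {
  tibble::tibble(
    t_c = x$t_c, loglik = x$loglik, k = x$k,
    convergence = x$convergence, boundary = x$boundary,
    low_information = x$low_information
  )
}

#' Tidy performance metrics
#'
#' @param x a `tc_performance` from [evaluate_estimates()].
#' @param ... unused.
#' @return `tidy()` returns the per-stratum metric tibble; `glance()` the
#'   all-variants row.
#' @exportS3Method generics::tidy
tidy.tc_performance <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.tc_performance
#' @exportS3Method generics::glance
glance.tc_performance <- function(x, ...) {
  tb <- tibble::as_tibble(unclass(x))
  tb[tb$stratum == "all", c("n", "rmse", "bias", "r")]
}
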