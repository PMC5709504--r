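#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted cell-cycle-time distribution
#'
#' @param x A [fit_cctd()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy cct_fit
#' @export
tidy.cct_fit <- function(x, ...) {
  p <- x$params
  switch(x$family,
    exponential = tibble(term = "rate", estimate = p$rate),
    erlang = tibble(term = c("k", "rate"),
                    estimate = c(p$k, p$rate)),
    eme = tibble(term = c("k", "lam1", "lam2"),
                 estimate = c(p$k, p$lam1, p$lam2)))
}

#' One-row model summary of a fitted cell-cycle-time distribution
#'
#' @inheritParams tidy.cct_fit
#' @return A tibble with columns `family`, `k`, `mean`, `ssr`, `converged`.
#' @method glance cct_fit
#' @export
glance.cct_fit <- function(x, ...) {
  mom <- hypoexp_moments(x$params)
  tibble(family = x$family,
         k = if (x$family == "exponential") 1L else x$params$k,
         mean = mom$mean, variance = mom$variance,
         ssr = x$ssr, converged = x$converged)
}
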