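#' Tidy and glance methods for fitted objects
#'
#' Broom-style summaries: `tidy()` returns one row per parameter, `glance()`
#' one row of fit-level statistics.
#'
#' @param x A fitted object (`rog_fit`, `lnp_fit`, or `kernel_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name navlnp-tidiers
NULL

#' @rdname navlnp-tidiers
#' @export
tidy.rog_fit <- function(x, ...) {
  tibble(term = c("rbar", "mu", "sigma"),
         estimate = c(x$nl$rbar, x$nl$mu, x$nl$sigma))
}

#' @rdname navlnp-tidiers
#' @export
glance.rog_fit <- function(x, ...) {
  tibble(n_turn = x$n_turn, run_time_s = x$run_time_s)
}

#' @rdname navlnp-tidiers
#' @export
tidy.lnp_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @rdname navlnp-tidiers
#' @export
glance.lnp_fit <- function(x, ...) {
  tibble(mode = x$mode, logLik = x$loglik, k = x$k, AIC = x$aic,
         n_turn = x$n_turn, run_time_s = x$run_time_s,
         convergence = x$convergence)
}

#' @rdname navlnp-tidiers
#' @export
tidy.kernel_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @rdname navlnp-tidiers
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble(family = x$family, sse = x$sse, converged = x$converged)
}
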