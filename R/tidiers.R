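#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a boost-model fit
#'
#' `tidy()` returns the per-word residual table of a [fit_beta()] result;
#' `glance()` returns the one-row fit summary.
#'
#' @param x A `boost_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with columns `word`, `observed`, `predicted`,
#'   `residual`. `glance()`: a one-row tibble with `pair`, `beta`, `rmse`,
#'   `n_words`.
#' @examples
#' lk <- build_beta_lookup("0001", grid = seq(0, 1, 0.25),
#'                         sims_per_point = 1000, seed = 1)
#' fit <- fit_beta(tu_reference(), lk)
#' tidy(fit)
#' glance(fit)
#' @method tidy boost_fit
#' @export
tidy.boost_fit <- function(x, ...) {
  x$residuals
}

#' @rdname tidy.boost_fit
#' @method glance boost_fit
#' @export
glance.boost_fit <- function(x, ...) {
  tibble::tibble(
    pair = x$pair,
    beta = x$beta,
    rmse = x$rmse,
    n_words = nrow(x$residuals)
  )
}
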