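#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an equilibrium object
#'
#' @param x An `evodisp_equilibrium`.
#' @param ... Unused.
#' @return A tibble with one row per state component (`term`, `estimate`).
#' @method tidy evodisp_equilibrium
#' @export
tidy.evodisp_equilibrium <- function(x, ...) {
  tibble::tibble(term = names(x$state), estimate = unname(x$state))
}

#' One-row summary of an equilibrium
#'
#' @param x An `evodisp_equilibrium`.
#' @param ... Unused.
#' @return A one-row tibble: the dispersion metrics at the equilibrium plus
#'   `disease_free`, `evolution` and the root residual.
#' @method glance evodisp_equilibrium
#' @export
glance.evodisp_equilibrium <- function(x, ...) {
  dplyr::bind_cols(equilibrium_dispersion(x),
                   tibble::tibble(disease_free = x$disease_free,
                                  evolution = x$evolution,
                                  residual = x$residual))
}
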