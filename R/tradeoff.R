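#' Transmission-virulence trade-off functions
#'
#' Both the transmission rate and the virulence (parasite-induced mortality)
#' of an infection increase with the parasite's mean within-host growth rate
#' `eps`. Transmission is `rho * (c_j + eps^x)`: concave in `eps` when
#' `x < 1`, so marginal transmission gains diminish as the parasite grows
#' faster, while the mortality cost `y_j * eps` keeps rising linearly. The
#' set point `c_j` allows host types to differ in baseline infectiousness and
#' the slope `y_j` in how steeply virulence rises with the trait.
#'
#' @param eps Mean within-host growth rate (trait units, >= 0). Vectorized.
#' @param params An [model_params()] object.
#' @param host `"high"` or `"low"`: which host type's set point / slope to use.
#' @return Numeric vector: transmission rate (per host density per time) or
#'   virulence (added mortality, per time).
#' @examples
#' pars <- model_params()
#' transmission_rate(0.25, pars, "high")  # 0.01 * (1 + sqrt(0.25)) = 0.015
#' virulence_rate(0.25, pars, "low")      # 1 * 0.25
#' @export
transmission_rate <- function(eps, params, host = c("high", "low")) {
  host <- match.arg(host)
  params <- validate_params(params)
  check_eps(eps)
  cj <- if (host == "high") params$cH else params$cL
  params$rho * (cj + eps^params$x)
}

#' @rdname transmission_rate
#' @export
virulence_rate <- function(eps, params, host = c("high", "low")) {
  host <- match.arg(host)
  params <- validate_params(params)
  check_eps(eps)
  yj <- if (host == "high") params$yH else params$yL
  yj * eps
}

check_eps <- function(eps) {
  if (!is.numeric(eps) || any(!is.finite(eps))) {
    stop("eps must be finite numeric", call. = FALSE)
  }
  if (any(eps < 0)) {
    stop("eps must be >= 0 (fractional powers of negative trait values are undefined)",
         call. = FALSE)
  }
  invisible(eps)
}

# internal scalar helpers used by the right-hand sides (no revalidation)
beta_fun <- function(eps, cj, x, rho) rho * (cj + eps^x)
alpha_fun <- function(eps, yj) yj * eps
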