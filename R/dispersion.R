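#' Parasite fitness: the effective reproduction number
#'
#' Expected number of new infections produced by an infected host given the
#' current susceptible densities, summing the contributions of the two
#' susceptible host types:
#' `Re = betaH*sH/(delta+gamma+alphaH) + betaL*sL/(delta+gamma+alphaL)`,
#' with the transmission and virulence rates evaluated at the mean trait of
#' the corresponding host type.
#'
#' @param sH,sL Susceptible densities (>= 0). Vectorized.
#' @param epsH,epsL Mean within-host growth rates (>= 0).
#' @param params An [model_params()] object.
#' @return Numeric vector of `Re` values (dimensionless).
#' @examples
#' reproduction_number(1250, 1250, 0.25, 0.25, model_params())
#' @export
reproduction_number <- function(sH, sL, epsH, epsL, params) {
  params <- validate_params(params)
  check_eps(c(epsH, epsL))
  bH <- beta_fun(epsH, params$cH, params$x, params$rho)
  bL <- beta_fun(epsL, params$cL, params$x, params$rho)
  dH <- params$delta + params$gamma + alpha_fun(epsH, params$yH)
  dL <- params$delta + params$gamma + alpha_fun(epsL, params$yL)
  bH * sH / dH + bL * sL / dL
}

#' Transmission dispersion at one state
#'
#' Computes parasite fitness `Re`, the population-level per-type reproduction
#' numbers, the variance of `Re` across infected host types, and the
#' variance-to-mean ratio `vmr = var(Re)/Re` — the model's measure of
#' transmission dispersion (high vmr means few infections drive most new
#' cases).
#'
#' The default (`form = "expanded"`) weighs each host type's deviation from
#' `Re` by its share of infections, with the per-type value taken as
#' `Re_j = beta_j*(sH+sL)/(delta+gamma+alpha_j)` (the reproduction number a
#' type-`j` infection would achieve across the whole susceptible pool). With
#' `form = "compact"` the per-type value is `beta_j*s_j/(delta+gamma+alpha_j)`
#' instead; this variant is provided for sensitivity analysis. Note that with
#' the expanded form `Re` is the weighted mean of the two per-type values only
#' when `sH = sL`, so `var(Re)` is in general a second moment about `Re`, not
#' a central variance; the expanded expression is implemented as written.
#'
#' @param state Named vector `sH`, `sL`, `iH`, `iL`, `epsH`, `epsL` (an
#'   [evo_rhs()] state; for the fixed-trait model append the traits).
#' @param params An [model_params()] object.
#' @param form `"expanded"` (default) or `"compact"` per-type reproduction
#'   number (see Details).
#' @param i_floor Total infected density below which the dispersion is
#'   reported as 0 and flagged undefined.
#' @return A one-row tibble: `Re`, `ReH_pop`, `ReL_pop`, `varRe`, `vmr`,
#'   `vmr_defined`.
#' @examples
#' st <- c(sH = 1250, sL = 1250, iH = 1, iL = 1, epsH = 0.25, epsL = 0.25)
#' dispersion_summary(st, model_params())
#' @export
dispersion_summary <- function(state, params, form = c("expanded", "compact"),
                               i_floor = 1e-10) {
  form <- match.arg(form)
  params <- validate_params(params)
  state <- check_evo_state(state, eps_floor = -Inf)
  check_eps(state[c("epsH", "epsL")])
  disp_core(state[["sH"]], state[["sL"]], state[["iH"]], state[["iL"]],
            state[["epsH"]], state[["epsL"]], params, form, i_floor)
}

disp_core <- function(sH, sL, iH, iL, epsH, epsL, params, form, i_floor) {
  p <- params
  bH <- beta_fun(epsH, p$cH, p$x, p$rho)
  bL <- beta_fun(epsL, p$cL, p$x, p$rho)
  dH <- p$delta + p$gamma + alpha_fun(epsH, p$yH)
  dL <- p$delta + p$gamma + alpha_fun(epsL, p$yL)
  Re <- bH * sH / dH + bL * sL / dL
  ReH_pop <- bH * (sH + sL) / dH
  ReL_pop <- bL * (sH + sL) / dL
  itot <- iH + iL
  if (itot <= i_floor) {
    return(tibble::tibble(Re = Re, ReH_pop = ReH_pop, ReL_pop = ReL_pop,
                          varRe = 0, vmr = 0, vmr_defined = FALSE))
  }
  wH <- iH / itot
  wL <- iL / itot
  if (form == "expanded") {
    varRe <- wH * (Re - ReH_pop)^2 + wL * (Re - ReL_pop)^2
  } else {
    varRe <- wH * (Re - bH * sH / dH)^2 + wL * (Re - bL * sL / dL)^2
  }
  if (Re <= 0) {
    if (varRe > 0) {
      stop("vmr undefined: Re = 0 with positive var(Re)", call. = FALSE)
    }
    vmr <- 0
  } else {
    vmr <- varRe / Re
  }
  tibble::tibble(Re = Re, ReH_pop = ReH_pop, ReL_pop = ReL_pop,
                 varRe = varRe, vmr = vmr, vmr_defined = TRUE)
}

#' Annotate a trajectory with fitness and dispersion metrics
#'
#' Maps [dispersion_summary()] over every time point of a trajectory,
#' appending columns `Re`, `ReH_pop`, `ReL_pop`, `varRe`, `vmr` and
#' `vmr_defined`. Points with (numerically) no infections are flagged
#' `vmr_defined = FALSE` with `vmr = 0` rather than aborting the annotation.
#'
#' @param traj A trajectory tibble from [simulate_epi()] or [simulate_evo()]
#'   (columns `time`, `sH`, `sL`, `iH`, `iL`, `epsH`, `epsL`).
#' @param params An [model_params()] object; defaults to the parameter set
#'   attached to the trajectory.
#' @inheritParams dispersion_summary
#' @return The trajectory tibble with the six metric columns appended.
#' @examples
#' traj <- simulate_evo(model_params(), t_end = 50, n = 51)
#' annotate_dispersion(traj)
#' @export
annotate_dispersion <- function(traj, params = NULL,
                                form = c("expanded", "compact"),
                                i_floor = 1e-10) {
  form <- match.arg(form)
  if (is.null(params)) params <- attr(traj, "params")
  params <- validate_params(params)
  need <- c("time", "sH", "sL", "iH", "iL", "epsH", "epsL")
  if (!all(need %in% names(traj))) {
    stop("trajectory must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mets <- purrr::pmap(dplyr::select(tibble::as_tibble(traj),
                                    dplyr::all_of(need[-1])),
                      function(sH, sL, iH, iL, epsH, epsL) {
                        disp_core(sH, sL, iH, iL, epsH, epsL,
                                  params, form, i_floor)
                      })
  out <- dplyr::bind_cols(tibble::as_tibble(traj)[setdiff(names(traj),
                                                          names(mets[[1]]))],
                          dplyr::bind_rows(mets))
  new_traj(out, params)
}

#' Dispersion metrics at an equilibrium
#'
#' @param eq An `evodisp_equilibrium` object.
#' @inheritParams dispersion_summary
#' @return A one-row tibble as in [dispersion_summary()].
#' @export
equilibrium_dispersion <- function(eq, form = c("expanded", "compact")) {
  stopifnot(inherits(eq, "evodisp_equilibrium"))
  dispersion_summary(eq$state, eq$params, form = match.arg(form))
}
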