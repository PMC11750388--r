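#' Per-capita fitness rates of the parasite by transmission route
#'
#' The per-capita rate at which infections in one host type produce new
#' infections in each host type. Within-type rates (`rHH`, `rLL`) net out the
#' losses of the source class (natural death, recovery, virulence); the
#' between-type rates (`rHL`: high-yield infections seeding low-yield hosts,
#' `rLH`: the converse) are pure transmission terms.
#'
#' @param state Named numeric vector `sH`, `sL`, `iH`, `iL`, `epsH`, `epsL`.
#' @param params An [model_params()] object.
#' @return A one-row tibble with columns `rHH`, `rHL`, `rLL`, `rLH`
#'   (per time).
#' @examples
#' st <- c(sH = 1250, sL = 1250, iH = 1, iL = 1, epsH = 0.25, epsL = 0.25)
#' fitness_rates(st, model_params())
#' @export
fitness_rates <- function(state, params) {
  params <- validate_params(params)
  state <- check_evo_state(state)
  p <- params
  bH <- beta_fun(state[["epsH"]], p$cH, p$x, p$rho)
  bL <- beta_fun(state[["epsL"]], p$cL, p$x, p$rho)
  aH <- alpha_fun(state[["epsH"]], p$yH)
  aL <- alpha_fun(state[["epsL"]], p$yL)
  tibble::tibble(rHH = bH * state[["sH"]] - (p$delta + p$gamma + aH),
                 rHL = bL * state[["sH"]],
                 rLL = bL * state[["sL"]] - (p$delta + p$gamma + aL),
                 rLH = bH * state[["sL"]])
}

check_evo_state <- function(state, eps_floor = 0) {
  nm <- c("sH", "sL", "iH", "iL", "epsH", "epsL")
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 6) {
    stop("state must be numeric of length 6 (sH, sL, iH, iL, epsH, epsL)",
         call. = FALSE)
  }
  if (is.null(names(state)) || !all(nm %in% names(state))) names(state) <- nm
  state <- state[nm]
  if (any(!is.finite(state))) stop("state components must be finite", call. = FALSE)
  if (any(state[1:4] < 0)) stop("densities must be >= 0", call. = FALSE)
  if (any(state[5:6] <= eps_floor)) {
    stop("mean traits epsH, epsL must be positive", call. = FALSE)
  }
  state
}

#' Right-hand side of the coupled epidemiological-evolutionary system
#'
#' Six coupled equations: the four host-density equations of [epi_rhs()]
#' evaluated at the current mean traits, plus Price-equation dynamics of the
#' mean within-host growth rate in each host type. For the high-yield type
#' the trait changes as
#' `varH * (rho*x*epsH^(x-1)*sH - yH)
#'  + (iL/iH) * (betaL*sH*(epsL - epsH) + varL*rho*x*epsL^(x-1)*sH)`
#' (and symmetrically for the low-yield type): standing variance times the
#' local fitness gradient — susceptible abundance selecting the trait up,
#' virulence selecting it down — plus migration of trait values carried by
#' between-type transmission.
#'
#' When an infected class is below `i_floor` its mean trait is frozen
#' (derivative 0): the mean trait of an absent infection class is undefined,
#' and the `iL/iH` weighting is singular there.
#'
#' @inheritParams fitness_rates
#' @param i_floor Infected-density floor below which a class's trait dynamics
#'   are frozen.
#' @param eps_floor Positivity floor for the traits; an active class whose
#'   trait falls to or below this value is an error (`epsH^(x-1)` is singular
#'   at 0 for `x < 1`, and selection should never drive the trait to 0).
#' @return Named numeric vector of six time-derivatives.
#' @examples
#' st <- c(sH = 1250, sL = 1250, iH = 1, iL = 1, epsH = 0.25, epsL = 0.25)
#' evo_rhs(st, model_params())
#' @export
evo_rhs <- function(state, params, i_floor = 1e-10, eps_floor = 1e-6) {
  params <- validate_params(params)
  state <- check_evo_state(state)
  evo_deriv(state, list(params = params, i_floor = i_floor,
                        eps_floor = eps_floor))
}

evo_deriv <- function(y, ctx) {
  p <- ctx$params
  sH <- max(y[["sH"]], 0); sL <- max(y[["sL"]], 0)
  iH <- max(y[["iH"]], 0); iL <- max(y[["iL"]], 0)
  eH <- y[["epsH"]]; eL <- y[["epsL"]]
  H_active <- iH >= ctx$i_floor
  L_active <- iL >= ctx$i_floor
  if ((H_active && eH <= ctx$eps_floor) || (L_active && eL <= ctx$eps_floor)) {
    stop(sprintf("mean trait fell to the positivity floor (%.1e); selection is singular there",
                 ctx$eps_floor), call. = FALSE)
  }
  bH <- beta_fun(eH, p$cH, p$x, p$rho)
  bL <- beta_fun(eL, p$cL, p$x, p$rho)
  aH <- alpha_fun(eH, p$yH)
  aL <- alpha_fun(eL, p$yL)
  foi <- bH * iH + bL * iL
  dbH <- p$rho * p$x * eH^(p$x - 1)   # marginal transmission gain d(beta)/d(eps)
  dbL <- p$rho * p$x * eL^(p$x - 1)
  deH <- if (!H_active) 0 else {
    p$varH * (dbH * sH - p$yH) +
      (iL / iH) * (bL * sH * (eL - eH) + p$varL * dbL * sH)
  }
  deL <- if (!L_active) 0 else {
    p$varL * (dbL * sL - p$yL) +
      (iH / iL) * (bH * sL * (eH - eL) + p$varH * dbH * sL)
  }
  c(sH = p$lam * (1 - p$p) - foi * sH - p$delta * sH,
    sL = p$lam * p$p - foi * sL - p$delta * sL,
    iH = foi * sH - (p$delta + p$gamma + aH) * iH,
    iL = foi * sL - (p$delta + p$gamma + aL) * iL,
    epsH = deH, epsL = deL)
}

#' Default initial state of the coupled system
#'
#' Susceptibles at the disease-free equilibrium, a small infection seed in
#' each host type, and both mean traits at `eps0`.
#'
#' @param params An [model_params()] object.
#' @param iH0,iL0 Initial infected densities.
#' @param epsH0,epsL0 Initial mean within-host growth rates (> 0).
#' @return Named numeric state vector of length 6.
#' @export
evo_init <- function(params, iH0 = 0.1, iL0 = 0.1, epsH0 = 0.25, epsL0 = epsH0) {
  c(epi_init(params, iH0, iL0), epsH = epsH0, epsL = epsL0)
}

#' Simulate the coupled epidemiological-evolutionary dynamics
#'
#' Integrates the six-dimensional system of [evo_rhs()]. With `t_end = NULL`
#' the horizon is chosen adaptively by integrating until the state is
#' numerically stationary.
#'
#' @inheritParams simulate_epi
#' @inheritParams evo_rhs
#' @param init Initial state (named vector of length 6); default [evo_init()].
#' @return A tibble of class `evodisp_traj` with columns `time`, `sH`, `sL`,
#'   `iH`, `iL`, `epsH`, `epsL`.
#' @examples
#' traj <- simulate_evo(model_params(), t_end = 50, n = 101)
#' tail(traj)
#' @export
simulate_evo <- function(params, init = NULL, t_end = NULL, n = 501,
                         rtol = 1e-8, atol = 1e-10,
                         i_floor = 1e-10, eps_floor = 1e-6) {
  params <- validate_params(params)
  if (is.null(init)) init <- evo_init(params)
  init <- check_evo_state(init)
  ctx <- list(params = params, i_floor = i_floor, eps_floor = eps_floor)
  if (is.null(t_end)) {
    t_end <- integrate_to_stationary(evo_deriv, init, ctx, rtol, atol)$time
  }
  stopifnot(t_end > 0)
  times <- seq(0, t_end, length.out = n)
  m <- solve_ode(evo_deriv, init, times, ctx, rtol, atol)
  m <- clip_negatives(m, c("sH", "sL", "iH", "iL"), atol)
  new_traj(tibble::as_tibble(as.data.frame(m)), params)
}

#' Joint epidemiological-evolutionary equilibrium
#'
#' Finds a stationary state of the coupled system by Newton root-finding
#' seeded from a long integration, and verifies the residual. When both
#' phenotypic variances are zero and the initial traits are equal, the trait
#' dynamics vanish identically and the problem reduces to
#' [endemic_equilibrium()] at the fixed trait.
#'
#' @inheritParams simulate_evo
#' @param init Initial state used to seed the search; default [evo_init()].
#' @param deriv_tol Maximum absolute residual accepted at the root.
#' @return An `evodisp_equilibrium` object (see [endemic_equilibrium()]) with
#'   `evolution = TRUE`.
#' @examples
#' \donttest{
#' eq <- evo_equilibrium(model_params())
#' glance(eq)
#' }
#' @export
evo_equilibrium <- function(params, init = NULL, rtol = 1e-8, atol = 1e-10,
                            i_floor = 1e-10, eps_floor = 1e-6,
                            deriv_tol = 1e-8) {
  params <- validate_params(params)
  if (is.null(init)) init <- evo_init(params)
  init <- check_evo_state(init)
  if (params$varH == 0 && params$varL == 0 &&
      isTRUE(all.equal(init[["epsH"]], init[["epsL"]]))) {
    eq <- endemic_equilibrium(params, init[["epsH"]], init[["epsL"]],
                              rtol = rtol, atol = atol, deriv_tol = deriv_tol)
    eq$evolution <- TRUE
    return(eq)
  }
  ctx <- list(params = params, i_floor = i_floor, eps_floor = eps_floor)
  long <- integrate_to_stationary(evo_deriv, init, ctx, rtol, atol,
                                  deriv_tol = 1e-7)
  seed <- long$state
  dens <- active_components(params)
  traits <- c(if ("iH" %in% dens) "epsH", if ("iL" %in% dens) "epsL")
  active <- c(dens, traits)
  fn <- function(z) {
    y <- seed
    y[active] <- z
    y[setdiff(c("sH", "sL", "iH", "iL"), dens)] <- 0
    evo_deriv(y, ctx)[active]
  }
  root <- tryCatch(pracma::fsolve(fn, seed[active], tol = 1e-12)$x,
                   error = function(e) seed[active])
  y <- seed
  y[active] <- root
  y[setdiff(c("sH", "sL", "iH", "iL"), dens)] <- 0
  y[dens] <- pmax(y[dens], 0)
  resid <- max(abs(evo_deriv(y, ctx)))
  if (resid > deriv_tol) {
    stop(sprintf("joint equilibrium search did not converge (residual %.3e)", resid),
         call. = FALSE)
  }
  structure(list(state = y,
                 disease_free = (y[["iH"]] + y[["iL"]]) < 1e-8,
                 residual = resid, evolution = TRUE, params = params),
            class = "evodisp_equilibrium")
}
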