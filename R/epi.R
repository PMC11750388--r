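#' Right-hand side of the fixed-trait epidemic model
#'
#' The two-host-type susceptible-infected system. Susceptible hosts of each
#' type enter at rates `lam*(1-p)` (high-yield) and `lam*p` (low-yield), are
#' infected by the common force of infection `betaH*iH + betaL*iL` (the
#' transmission rate depends on the type of the *infecting* host), and die
#' naturally at rate `delta`. Infected hosts additionally recover at rate
#' `gamma` and suffer virulence mortality `alpha_j`. The within-host growth
#' rate is fixed at `epsH` (high-yield infections) and `epsL` (low-yield
#' infections).
#'
#' @param state Named numeric vector with components `sH`, `sL`, `iH`, `iL`
#'   (all >= 0, host density units).
#' @param epsH,epsL Fixed within-host growth rates in high- and low-yield
#'   infections (>= 0).
#' @param params An [model_params()] object.
#' @return Named numeric vector of time-derivatives `(sH, sL, iH, iL)`.
#' @examples
#' pars <- model_params()
#' epi_rhs(c(sH = 1250, sL = 1250, iH = 1, iL = 0), 0.25, 0.25, pars)
#' @export
epi_rhs <- function(state, epsH, epsL, params) {
  params <- validate_params(params)
  state <- check_epi_state(state)
  check_eps(c(epsH, epsL))
  unlist(epi_deriv(state, list(params = params, epsH = epsH, epsL = epsL)))
}

check_epi_state <- function(state) {
  nm <- c("sH", "sL", "iH", "iL")
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 4) {
    stop("state must be numeric of length 4 (sH, sL, iH, iL)", call. = FALSE)
  }
  if (is.null(names(state)) || !all(nm %in% names(state))) names(state) <- nm
  state <- state[nm]
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state components must be finite and >= 0", call. = FALSE)
  }
  state
}

# unchecked core, used by the solver
epi_deriv <- function(y, ctx) {
  p <- ctx$params
  y <- pmax(y, 0)
  bH <- beta_fun(ctx$epsH, p$cH, p$x, p$rho)
  bL <- beta_fun(ctx$epsL, p$cL, p$x, p$rho)
  aH <- alpha_fun(ctx$epsH, p$yH)
  aL <- alpha_fun(ctx$epsL, p$yL)
  foi <- bH * y[["iH"]] + bL * y[["iL"]]
  c(sH = p$lam * (1 - p$p) - foi * y[["sH"]] - p$delta * y[["sH"]],
    sL = p$lam * p$p - foi * y[["sL"]] - p$delta * y[["sL"]],
    iH = foi * y[["sH"]] - (p$delta + p$gamma + aH) * y[["iH"]],
    iL = foi * y[["sL"]] - (p$delta + p$gamma + aL) * y[["iL"]])
}

#' Default initial state
#'
#' Susceptible hosts start at the disease-free equilibrium
#' (`sH = (1-p)*lam/delta`, `sL = p*lam/delta`) and a small seed of
#' infections of each type is introduced.
#'
#' @param params An [model_params()] object.
#' @param iH0,iL0 Initial infected densities.
#' @return Named numeric state vector `(sH, sL, iH, iL)`.
#' @export
epi_init <- function(params, iH0 = 0.1, iL0 = 0.1) {
  params <- validate_params(params)
  c(sH = (1 - params$p) * params$lam / params$delta,
    sL = params$p * params$lam / params$delta,
    iH = iH0, iL = iL0)
}

#' Simulate the fixed-trait epidemic
#'
#' Integrates the two-host-type susceptible-infected system with the
#' within-host growth rate held constant, and returns the trajectory as a
#' tibble (one row per output time). When `t_end` is `NULL` the horizon is
#' chosen adaptively: the system is integrated until the state is numerically
#' stationary and the full trajectory up to that point is reported.
#'
#' @param params An [model_params()] object.
#' @param epsH,epsL Fixed within-host growth rates (default 0.25 in both
#'   host types).
#' @param init Initial state (named vector `sH`, `sL`, `iH`, `iL`); default
#'   [epi_init()].
#' @param t_end Integration horizon (model time units), or `NULL` for
#'   adaptive equilibrium detection.
#' @param n Number of output time points.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `evodisp_traj` with columns `time`, `sH`, `sL`,
#'   `iH`, `iL`, `epsH`, `epsL`; the parameter set is attached as attribute
#'   `"params"`.
#' @examples
#' traj <- simulate_epi(model_params(), t_end = 100)
#' tail(traj)
#' @export
simulate_epi <- function(params, epsH = 0.25, epsL = epsH, init = NULL,
                         t_end = NULL, n = 501, rtol = 1e-8, atol = 1e-10) {
  params <- validate_params(params)
  check_eps(c(epsH, epsL))
  if (is.null(init)) init <- epi_init(params)
  init <- check_epi_state(init)
  ctx <- list(params = params, epsH = epsH, epsL = epsL)
  if (is.null(t_end)) {
    t_end <- integrate_to_stationary(epi_deriv, init, ctx, rtol, atol)$time
  }
  stopifnot(t_end > 0)
  times <- seq(0, t_end, length.out = n)
  m <- solve_ode(epi_deriv, init, times, ctx, rtol, atol)
  m <- clip_negatives(m, c("sH", "sL", "iH", "iL"), atol)
  out <- tibble::as_tibble(as.data.frame(m))
  out$epsH <- epsH
  out$epsL <- epsL
  new_traj(out, params)
}

new_traj <- function(df, params) {
  structure(df, params = params,
            class = c("evodisp_traj", class(tibble::tibble())))
}

#' @export
print.evodisp_traj <- function(x, ...) {
  cat(sprintf("<evodisp trajectory: %d time points, t in [%g, %g]>\n",
              nrow(x), min(x$time), max(x$time)))
  NextMethod()
}

#' Endemic equilibrium of the fixed-trait epidemic
#'
#' Finds a stationary state of the fixed-trait system by Newton root-finding
#' on the right-hand side, seeded from a moderate-horizon integration. If the
#' effective reproduction number at the disease-free state is below 1 (or no
#' positive-infection root exists), the disease-free equilibrium is returned
#' and flagged.
#'
#' @inheritParams simulate_epi
#' @param deriv_tol Maximum absolute right-hand-side residual accepted at the
#'   root.
#' @return An object of class `evodisp_equilibrium`: a list with elements
#'   `state` (named vector `sH`, `sL`, `iH`, `iL`, `epsH`, `epsL`),
#'   `disease_free` (logical), `residual` (max abs derivative), `evolution`
#'   (`FALSE`) and `params`. Supports [tidy()] and [glance()].
#' @examples
#' eq <- endemic_equilibrium(model_params(), 0.25)
#' tidy(eq)
#' @export
endemic_equilibrium <- function(params, epsH = 0.25, epsL = epsH,
                                rtol = 1e-8, atol = 1e-10, deriv_tol = 1e-8) {
  params <- validate_params(params)
  check_eps(c(epsH, epsL))
  ctx <- list(params = params, epsH = epsH, epsL = epsL)
  dfe <- epi_init(params, 0, 0)
  re0 <- reproduction_number(dfe[["sH"]], dfe[["sL"]], epsH, epsL, params)
  mk <- function(state, df_flag, resid) {
    structure(list(state = c(state, epsH = epsH, epsL = epsL),
                   disease_free = df_flag, residual = resid,
                   evolution = FALSE, params = params),
              class = "evodisp_equilibrium")
  }
  if (re0 <= 1) {
    return(mk(dfe, TRUE, max(abs(epi_deriv(dfe, ctx)))))
  }
  seed <- integrate_to_stationary(epi_deriv, epi_init(params), ctx, rtol, atol,
                                  deriv_tol = 1e-6)$state
  active <- active_components(params)
  fn <- function(z) {
    y <- seed
    y[active] <- z
    y[setdiff(names(y), active)] <- 0
    epi_deriv(y, ctx)[active]
  }
  root <- tryCatch(pracma::fsolve(fn, seed[active], tol = 1e-12)$x,
                   error = function(e) seed[active])
  y <- seed
  y[active] <- root
  y[setdiff(names(y), active)] <- 0
  y <- pmax(y, 0)
  resid <- max(abs(epi_deriv(y, ctx)))
  if (resid > deriv_tol || (y[["iH"]] + y[["iL"]]) < 1e-8) {
    if ((y[["iH"]] + y[["iL"]]) < 1e-8) return(mk(dfe, TRUE, max(abs(epi_deriv(dfe, ctx)))))
    stop(sprintf("equilibrium root-finding did not converge (residual %.3e)", resid),
         call. = FALSE)
  }
  mk(y, FALSE, resid)
}

# components that can be nonzero at an endemic equilibrium: with p = 1 there
# is no high-yield influx, so sH = iH = 0 exactly (and symmetrically at p = 0)
active_components <- function(params) {
  if (params$p >= 1) return(c("sL", "iL"))
  if (params$p <= 0) return(c("sH", "iH"))
  c("sH", "sL", "iH", "iL")
}

#' @export
print.evodisp_equilibrium <- function(x, ...) {
  kind <- if (x$disease_free) "disease-free" else "endemic"
  evo <- if (isTRUE(x$evolution)) "evolving trait" else "fixed trait"
  cat(sprintf("<evodisp %s equilibrium (%s), residual %.2e>\n", kind, evo, x$residual))
  print(round(x$state, 6))
  invisible(x)
}
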