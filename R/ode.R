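# Shared numerical machinery: deSolve driver, negativity handling,
# equilibrium detection by chunked integration.

ode_defaults <- function() list(rtol = 1e-8, atol = 1e-10)

# Integrate a derivative function over `times`; deSolve's lsoda switches
# automatically between stiff and non-stiff methods.
solve_ode <- function(rhs, y0, times, params, rtol, atol) {
  fn <- function(t, y, parms) list(rhs(y, parms))
  out <- deSolve::ode(y = y0, times = times, func = fn, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop("ODE integration failed (lsoda istate = ", diag[1], ")", call. = FALSE)
  }
  m <- as.matrix(unclass(out))
  if (anyNA(m)) stop("ODE integration produced NA/NaN state values", call. = FALSE)
  m
}

# Densities can undershoot 0 by roughly the solver tolerance; clip small
# undershoot, refuse anything that signals a genuine model/solver problem.
clip_negatives <- function(m, cols, atol, hard = 1e-6) {
  vals <- m[, cols, drop = FALSE]
  worst <- min(vals, 0)
  if (worst < -hard) {
    stop(sprintf("state went negative beyond tolerance (min = %.3e)", worst),
         call. = FALSE)
  }
  if (worst < -atol) {
    warning(sprintf("clipped negative undershoot to 0 (min = %.3e)", worst),
            call. = FALSE)
  }
  m[, cols] <- pmax(vals, 0)
  m
}

# Integrate in chunks until the right-hand side is numerically stationary.
# Returns the terminal state and the time at which it was reached.
integrate_to_stationary <- function(rhs, y0, params, rtol, atol,
                                    chunk = 500, t_max = 2e5, deriv_tol = 1e-8) {
  t0 <- 0
  y <- y0
  while (t0 < t_max) {
    m <- solve_ode(rhs, y, c(t0, t0 + chunk), params, rtol, atol)
    y <- m[nrow(m), -1]
    t0 <- t0 + chunk
    scale <- pmax(abs(y), 1)
    if (max(abs(rhs(y, params)) / scale) < deriv_tol) {
      return(list(state = y, time = t0, converged = TRUE))
    }
  }
  list(state = y, time = t0, converged = FALSE)
}
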