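#' Discretized strain grid for the multi-strain oracle
#'
#' Builds an `N`-strain discretization of a polymorphic parasite population:
#' a normal trait distribution (given target mean and variance) truncated to
#' the interval from `eps_min` to `mean + width` standard deviations, split
#' into `N` equal cells; each strain sits at a cell midpoint and starts with
#' its cell's probability mass (the same frequencies in both host types).
#'
#' @param mean Target mean within-host growth rate of the initial strain
#'   distribution.
#' @param var Target variance of the initial strain distribution (trait^2).
#'   `var = 0` produces a single strain at `mean`.
#' @param n_strains Number of strains (grid cells).
#' @param width Half-width of the grid in standard deviations.
#' @param eps_min Lower truncation bound for trait values.
#' @return An object of class `evodisp_strain_grid`: list with `eps`
#'   (increasing trait values), `wH`, `wL` (initial frequencies per host
#'   type). Note the truncation shifts the realized moments away from
#'   (`mean`, `var`); use [grid_moments()] for the empirical values.
#' @examples
#' g <- strain_grid(0.25, 1, n_strains = 41)
#' grid_moments(g)
#' @export
strain_grid <- function(mean = 0.25, var = 1, n_strains = 41, width = 3,
                        eps_min = 1e-3) {
  stopifnot(mean > 0, var >= 0, n_strains >= 1, width > 0)
  if (var == 0) {
    return(new_strain_grid(mean, 1, 1))
  }
  sd <- sqrt(var)
  lo <- max(eps_min, mean - width * sd)
  hi <- mean + width * sd
  if (lo >= hi) stop("strain grid support is empty above eps_min", call. = FALSE)
  # discretize the normal truncated to (lo, hi]: N midpoint cells, each node
  # carrying its cell's probability mass, so refining N targets the same
  # continuous distribution
  edges <- seq(lo, hi, length.out = n_strains + 1)
  eps <- (edges[-1] + edges[-(n_strains + 1)]) / 2
  w <- diff(stats::pnorm(edges, mean, sd))
  w <- w / sum(w)
  new_strain_grid(eps, w, w)
}

new_strain_grid <- function(eps, wH, wL) {
  stopifnot(all(eps > 0), !is.unsorted(eps, strictly = TRUE),
            length(wH) == length(eps), length(wL) == length(eps),
            all(wH >= 0), all(wL >= 0),
            abs(sum(wH) - 1) < 1e-12, abs(sum(wL) - 1) < 1e-12)
  structure(list(eps = eps, wH = wH, wL = wL), class = "evodisp_strain_grid")
}

#' Empirical moments of a strain grid
#'
#' @param grid An [strain_grid()] object.
#' @return A one-row tibble: `n_strains`, `meanH`, `varH`, `meanL`, `varL`
#'   of the initial strain-frequency distributions.
#' @export
grid_moments <- function(grid) {
  stopifnot(inherits(grid, "evodisp_strain_grid"))
  mom <- function(w) {
    m <- sum(w * grid$eps)
    c(m, sum(w * (grid$eps - m)^2))
  }
  h <- mom(grid$wH); l <- mom(grid$wL)
  tibble::tibble(n_strains = length(grid$eps),
                 meanH = h[1], varH = h[2], meanL = l[1], varL = l[2])
}

#' Right-hand side of the explicit multi-strain model
#'
#' Strain-resolved version of the two-host-type epidemic: each strain `k`
#' carries a fixed trait `eps_k`, transmits from host type `j` at
#' `beta_j(eps_k)` and kills at `alpha_j(eps_k)`; susceptible classes lose
#' hosts to the summed force of infection over all strains and both source
#' types. With a single strain the system reduces exactly to [epi_rhs()].
#' Used as an independent brute-force oracle for the Price-equation trait
#' dynamics, which summarize this system by its per-type mean trait.
#'
#' @param state Named vector: `sH`, `sL`, then `iH1..iHN`, `iL1..iLN`.
#' @param eps Vector of strain trait values.
#' @param params An [model_params()] object.
#' @return Named vector of `2 + 2N` time-derivatives.
#' @export
multistrain_rhs <- function(state, eps, params) {
  params <- validate_params(params)
  n <- length(eps)
  stopifnot(length(state) == 2 + 2 * n, all(state >= 0), all(eps > 0))
  ms_deriv(state, list(params = params, eps = eps, n = n))
}

ms_deriv <- function(y, ctx) {
  p <- ctx$params
  n <- ctx$n
  y <- pmax(y, 0)
  sH <- y[1]; sL <- y[2]
  iH <- y[3:(2 + n)]
  iL <- y[(3 + n):(2 + 2 * n)]
  bH <- beta_fun(ctx$eps, p$cH, p$x, p$rho)
  bL <- beta_fun(ctx$eps, p$cL, p$x, p$rho)
  aH <- alpha_fun(ctx$eps, p$yH)
  aL <- alpha_fun(ctx$eps, p$yL)
  foi_k <- bH * iH + bL * iL        # per-strain force of infection
  foi <- sum(foi_k)
  dsH <- p$lam * (1 - p$p) - foi * sH - p$delta * sH
  dsL <- p$lam * p$p - foi * sL - p$delta * sL
  diH <- foi_k * sH - (p$delta + p$gamma + aH) * iH
  diL <- foi_k * sL - (p$delta + p$gamma + aL) * iL
  out <- c(dsH, dsL, diH, diL)
  names(out) <- names(y)
  out
}

#' Simulate the multi-strain oracle
#'
#' @param params An [model_params()] object.
#' @param grid An [strain_grid()] object giving strain traits and initial
#'   frequencies.
#' @param iH0,iL0 Initial total infected density per host type (split across
#'   strains by the grid frequencies).
#' @param t_end Integration horizon.
#' @param n Number of output time points.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `evodisp_ms_traj`: list with `times`, `sH`,
#'   `sL` (vectors), `iH`, `iL` (time-by-strain matrices), `eps`, `params`.
#' @examples
#' g <- strain_grid(0.25, 0.01, n_strains = 11)
#' ms <- simulate_multistrain(model_params(), g, t_end = 10, n = 11)
#' mean_trait_trajectory(ms)
#' @export
simulate_multistrain <- function(params, grid, iH0 = 0.1, iL0 = 0.1,
                                 t_end = 100, n = 201,
                                 rtol = 1e-8, atol = 1e-10) {
  params <- validate_params(params)
  stopifnot(inherits(grid, "evodisp_strain_grid"), t_end > 0)
  nstr <- length(grid$eps)
  y0 <- c(sH = (1 - params$p) * params$lam / params$delta,
          sL = params$p * params$lam / params$delta,
          stats::setNames(iH0 * grid$wH, paste0("iH", seq_len(nstr))),
          stats::setNames(iL0 * grid$wL, paste0("iL", seq_len(nstr))))
  ctx <- list(params = params, eps = grid$eps, n = nstr)
  times <- seq(0, t_end, length.out = n)
  m <- solve_ode(ms_deriv, y0, times, ctx, rtol, atol)
  m <- clip_negatives(m, setdiff(colnames(m), "time"), atol)
  structure(list(times = m[, "time"],
                 sH = m[, "sH"], sL = m[, "sL"],
                 iH = m[, paste0("iH", seq_len(nstr)), drop = FALSE],
                 iL = m[, paste0("iL", seq_len(nstr)), drop = FALSE],
                 eps = grid$eps, params = params),
            class = "evodisp_ms_traj")
}

#' Per-type mean-trait trajectory of a multi-strain run
#'
#' Strain-frequency-weighted mean and variance of the trait among infections
#' of each host type, at every output time. Host types whose total infected
#' density is below `i_floor` get `NA` moments (the mean trait of an absent
#' class is undefined).
#'
#' @param ms An `evodisp_ms_traj` from [simulate_multistrain()].
#' @param i_floor Total-infection floor below which moments are `NA`.
#' @return A tibble: `time`, `iH_tot`, `iL_tot`, `epsH_mean`, `epsL_mean`,
#'   `varH_emp`, `varL_emp`.
#' @export
mean_trait_trajectory <- function(ms, i_floor = 1e-10) {
  stopifnot(inherits(ms, "evodisp_ms_traj"))
  moments <- function(imat) {
    tot <- rowSums(imat)
    mu <- ifelse(tot > i_floor, as.vector(imat %*% ms$eps) / tot, NA_real_)
    ex2 <- ifelse(tot > i_floor, as.vector(imat %*% ms$eps^2) / tot, NA_real_)
    list(tot = tot, mean = mu, var = ex2 - mu^2)
  }
  h <- moments(ms$iH); l <- moments(ms$iL)
  tibble::tibble(time = ms$times, iH_tot = h$tot, iL_tot = l$tot,
                 epsH_mean = h$mean, epsL_mean = l$mean,
                 varH_emp = pmax(h$var, 0), varL_emp = pmax(l$var, 0))
}

#' Validate the Price-equation trait dynamics against the multi-strain oracle
#'
#' Runs the explicit multi-strain model and the Price-equation summary from
#' matched initial conditions (the Price run takes its initial mean traits
#' and its constant per-type variances from the grid's empirical moments at
#' t = 0) and reports the relative error of the Price mean-trait
#' trajectories. Because the Price approximation holds the trait variance
#' fixed while the oracle's variance genuinely evolves, agreement is only
#' expected while the oracle's empirical variance stays near its initial
#' value; the comparison horizon is therefore capped (unless given) at the
#' first time either type's empirical variance drifts more than `var_drift`
#' (relative) from its value at t = 0.
#'
#' @param params An [model_params()] object (its `varH`, `varL` are replaced
#'   by the grid's empirical variances for the Price run).
#' @param grid An [strain_grid()] object.
#' @param horizon Comparison horizon; `NULL` for the adaptive
#'   variance-drift cap.
#' @param t_end Oracle integration horizon used when searching for the
#'   adaptive cap.
#' @param var_drift Allowed relative drift of the oracle's empirical variance
#'   before the comparison stops.
#' @param iH0,iL0 Initial total infected densities.
#' @param n Output grid resolution.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `evodisp_price_report`: list with `n_strains`,
#'   `horizon`, `max_rel_err_epsH`, `max_rel_err_epsL`, `mean_rel_err`, and
#'   the compared trajectories in `$comparison` (a tibble).
#' @examples
#' \donttest{
#' rep <- compare_to_price(model_params(), strain_grid(0.25, 1))
#' rep
#' }
#' @export
compare_to_price <- function(params, grid, horizon = NULL, t_end = 25,
                             var_drift = 0.2, iH0 = 0.1, iL0 = 0.1,
                             n = 501, rtol = 1e-8, atol = 1e-10) {
  params <- validate_params(params)
  stopifnot(inherits(grid, "evodisp_strain_grid"))
  mom <- grid_moments(grid)
  if (mom$varH == 0 && (params$varH > 0 || params$varL > 0)) {
    stop("degenerate (zero-variance) strain grid cannot match a positive Price variance",
         call. = FALSE)
  }
  ms <- simulate_multistrain(params, grid, iH0, iL0, t_end = t_end, n = n,
                             rtol = rtol, atol = atol)
  mt <- mean_trait_trajectory(ms)
  if (is.null(horizon)) {
    drift_ok <- stable_variance_window(mt, var_drift)
    horizon <- mt$time[max(2, sum(drift_ok))]
  }
  stopifnot(horizon > 0)
  price_params <- validate_params(utils::modifyList(
    unclass(params), list(varH = mom$varH, varL = mom$varL)))
  init <- evo_init(price_params, iH0, iL0, epsH0 = mom$meanH, epsL0 = mom$meanL)
  keep <- mt$time <= horizon + 1e-12
  pr <- simulate_evo(price_params, init = init, t_end = horizon,
                     n = sum(keep), rtol = rtol, atol = atol)
  cmp <- tibble::tibble(
    time = mt$time[keep],
    oracle_epsH = mt$epsH_mean[keep], oracle_epsL = mt$epsL_mean[keep],
    price_epsH = pr$epsH, price_epsL = pr$epsL)
  cmp$rel_err_H <- abs(cmp$price_epsH - cmp$oracle_epsH) / abs(cmp$oracle_epsH)
  cmp$rel_err_L <- abs(cmp$price_epsL - cmp$oracle_epsL) / abs(cmp$oracle_epsL)
  structure(list(n_strains = length(grid$eps), horizon = horizon,
                 max_rel_err_epsH = max(cmp$rel_err_H, na.rm = TRUE),
                 max_rel_err_epsL = max(cmp$rel_err_L, na.rm = TRUE),
                 mean_rel_err = mean(c(cmp$rel_err_H, cmp$rel_err_L),
                                     na.rm = TRUE),
                 comparison = cmp),
            class = "evodisp_price_report")
}

# indices (from t = 0) over which both empirical variances stay within
# `drift` relative of their initial values; always keeps at least 2 points
stable_variance_window <- function(mt, drift) {
  ok_type <- function(v) {
    if (v[1] <= 0) return(rep(TRUE, length(v)))
    abs(v / v[1] - 1) <= drift
  }
  ok <- ok_type(mt$varH_emp) & ok_type(mt$varL_emp)
  ok[is.na(ok)] <- FALSE
  first_bad <- which(!ok)
  if (length(first_bad) == 0) return(rep(TRUE, nrow(mt)))
  seq_len(nrow(mt)) < min(first_bad)
}

#' @export
print.evodisp_price_report <- function(x, ...) {
  cat(sprintf(
    "<Price-equation validation: N = %d strains, horizon = %.4g>\n",
    x$n_strains, x$horizon))
  cat(sprintf("  max rel. error epsH: %.3e\n", x$max_rel_err_epsH))
  cat(sprintf("  max rel. error epsL: %.3e\n", x$max_rel_err_epsL))
  cat(sprintf("  mean rel. error:     %.3e\n", x$mean_rel_err))
  invisible(x)
}

#' Export a Price-validation report as JSON
#'
#' @param report An `evodisp_price_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "evodisp_price_report"))
  jsonlite::write_json(
    list(N = report$n_strains, horizon = report$horizon,
         max_rel_err_epsH = report$max_rel_err_epsH,
         max_rel_err_epsL = report$max_rel_err_epsL,
         mean_rel_err = report$mean_rel_err),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
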