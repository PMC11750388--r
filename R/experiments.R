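#' Run a scenario: trajectory plus equilibrium, with or without evolution
#'
#' Integrates a preset or user-supplied parameter set, annotates the
#' trajectory with fitness and dispersion metrics, and locates the
#' corresponding equilibrium. With `evolution = "off"` the within-host
#' growth rate is held fixed at `eps0`; with `"both"` the paired runs are
#' returned together for with/without-adaptation comparisons.
#'
#' @param params An [model_params()] object or a preset name (see
#'   [preset_params()]).
#' @param evolution `"on"`, `"off"`, or `"both"`.
#' @param eps0 Initial (and, without evolution, permanent) within-host
#'   growth rate.
#' @param iH0,iL0 Initial infected densities.
#' @param t_end Integration horizon (`NULL` = adaptive, run to equilibrium).
#' @param n Output time points.
#' @param form Dispersion form passed to [annotate_dispersion()].
#' @return For `"on"`/`"off"`: a list of class `evodisp_run` with elements
#'   `trajectory` (annotated tibble), `equilibrium`
#'   (`evodisp_equilibrium`), `equilibrium_metrics` (one-row tibble) and
#'   `evolution`. For `"both"`: list with elements `on` and `off`.
#' @examples
#' \donttest{
#' run <- run_scenario("baseline", evolution = "off", t_end = 200)
#' run$equilibrium_metrics
#' }
#' @export
run_scenario <- function(params = "baseline", evolution = c("on", "off", "both"),
                         eps0 = 0.25, iH0 = 0.1, iL0 = 0.1,
                         t_end = NULL, n = 501,
                         form = c("expanded", "compact")) {
  evolution <- match.arg(evolution)
  form <- match.arg(form)
  if (is.character(params)) params <- preset_params(params)
  params <- validate_params(params)
  if (evolution == "both") {
    return(list(
      on = run_scenario(params, "on", eps0, iH0, iL0, t_end, n, form),
      off = run_scenario(params, "off", eps0, iH0, iL0, t_end, n, form)))
  }
  if (evolution == "on") {
    # seed absent host types with no infections so their trait stays frozen
    if (params$p >= 1) iH0 <- 0
    if (params$p <= 0) iL0 <- 0
    init <- evo_init(params, iH0, iL0, epsH0 = eps0)
    traj <- simulate_evo(params, init = init, t_end = t_end, n = n)
    eq <- evo_equilibrium(params, init = init)
  } else {
    init <- epi_init(params, iH0, iL0)
    traj <- simulate_epi(params, epsH = eps0, epsL = eps0, init = init,
                         t_end = t_end, n = n)
    eq <- endemic_equilibrium(params, eps0, eps0)
  }
  traj <- annotate_dispersion(traj, params, form = form)
  structure(list(trajectory = traj, equilibrium = eq,
                 equilibrium_metrics = equilibrium_dispersion(eq, form = form),
                 evolution = (evolution == "on"), params = params),
            class = "evodisp_run")
}

#' @export
print.evodisp_run <- function(x, ...) {
  cat(sprintf("<evodisp run (%s evolution)>\n",
              if (x$evolution) "with" else "without"))
  print(x$equilibrium)
  cat("equilibrium metrics:\n")
  print(x$equilibrium_metrics)
  invisible(x)
}

# evolved (or fixed-trait) equilibrium dispersion for one influx split p;
# returns a one-row tibble used by the scan drivers
eq_row <- function(params, p, evolution, eps0, form) {
  pars <- validate_params(utils::modifyList(unclass(params), list(p = p)))
  iH0 <- if (p >= 1) 0 else 0.1
  iL0 <- if (p <= 0) 0 else 0.1
  eq <- if (evolution) {
    evo_equilibrium(pars, init = evo_init(pars, iH0, iL0, epsH0 = eps0))
  } else {
    endemic_equilibrium(pars, eps0, eps0)
  }
  met <- equilibrium_dispersion(eq, form = form)
  st <- eq$state
  s_tot <- st[["sH"]] + st[["sL"]]
  tibble::tibble(p = p,
                 pct_sL = if (s_tot > 0) st[["sL"]] / s_tot else NA_real_,
                 sH = st[["sH"]], sL = st[["sL"]],
                 iH = st[["iH"]], iL = st[["iL"]],
                 epsH = st[["epsH"]], epsL = st[["epsL"]],
                 Re = met$Re, vmr = met$vmr,
                 disease_free = eq$disease_free)
}

#' Scan the host-population composition
#'
#' Computes the evolved endemic equilibrium and its transmission dispersion
#' across a grid of influx compositions `p` (the proportion of hosts born
#' low-yield). `pct_sL` reports the realized composition at equilibrium,
#' `sL/(sH+sL)`.
#'
#' @param params Base [model_params()] object or preset name.
#' @param p_grid Vector of influx proportions in `[0, 1]`.
#' @param evolution Logical: adapt the trait (default) or hold it at `eps0`.
#' @param eps0 Initial / fixed within-host growth rate.
#' @param form Dispersion form.
#' @return A tibble with one row per `p`: `p`, `pct_sL`, equilibrium
#'   densities and traits, `Re`, `vmr`, `disease_free`. Rows whose
#'   equilibrium computation fails are flagged with `NA` metrics.
#' @examples
#' \donttest{
#' scan_host_composition("baseline", p_grid = c(0, 0.5, 1))
#' }
#' @export
scan_host_composition <- function(params = "baseline",
                                  p_grid = seq(0, 1, by = 0.1),
                                  evolution = TRUE, eps0 = 0.25,
                                  form = c("expanded", "compact")) {
  form <- match.arg(form)
  if (is.character(params)) params <- preset_params(params)
  params <- validate_params(params)
  stopifnot(all(p_grid >= 0 & p_grid <= 1))
  purrr::map_dfr(p_grid, function(p) {
    tryCatch(eq_row(params, p, evolution, eps0, form),
             error = function(e) {
               tibble::tibble(p = p, pct_sL = NA_real_, sH = NA_real_,
                              sL = NA_real_, iH = NA_real_, iL = NA_real_,
                              epsH = NA_real_, epsL = NA_real_, Re = NA_real_,
                              vmr = NA_real_, disease_free = NA)
             })
  })
}

#' Scan a host-quality gap against the host composition
#'
#' For every combination of influx proportion `p` and a value of one
#' quality parameter (`cH`, the high-yield transmission set point, or `yL`,
#' the low-yield virulence slope), computes the equilibrium transmission
#' dispersion with adaptation (`vmr_evolved`) and with the trait fixed at
#' `eps_fixed` (`vmr_fixed`), and their difference `delta_vmr` — the
#' contribution of parasite adaptation to transmission dispersion.
#'
#' @param params Base [model_params()] object or preset name
#'   (default `"quality_grid"`).
#' @param p_grid Influx proportions.
#' @param axis Which parameter spans the quality gap: `"cH"` or `"yL"`.
#' @param values Values of the `axis` parameter.
#' @param eps_fixed Trait value of the no-evolution comparator.
#' @param form Dispersion form.
#' @return A tibble with one row per grid cell: `p`, `axis`, `value`,
#'   `vmr_evolved`, `vmr_fixed`, `delta_vmr`; per-cell failures yield `NA`
#'   rows and the scan continues.
#' @examples
#' \donttest{
#' scan_quality_grid(p_grid = c(0.25, 0.75), axis = "cH", values = c(0.1, 0.5))
#' }
#' @export
scan_quality_grid <- function(params = "quality_grid", p_grid = seq(0.1, 0.9, by = 0.2),
                              axis = c("cH", "yL"), values,
                              eps_fixed = 0.25,
                              form = c("expanded", "compact")) {
  axis <- match.arg(axis)
  form <- match.arg(form)
  if (is.character(params)) params <- preset_params(params)
  params <- validate_params(params)
  stopifnot(length(values) >= 1, all(p_grid >= 0 & p_grid <= 1))
  cells <- tidyr::expand_grid(value = values, p = p_grid)
  purrr::pmap_dfr(cells, function(value, p) {
    pars <- utils::modifyList(unclass(params), stats::setNames(list(value), axis))
    tryCatch({
      on <- eq_row(validate_params(pars), p, TRUE, eps_fixed, form)
      off <- eq_row(validate_params(pars), p, FALSE, eps_fixed, form)
      tibble::tibble(p = p, axis = axis, value = value,
                     vmr_evolved = on$vmr, vmr_fixed = off$vmr,
                     delta_vmr = on$vmr - off$vmr)
    }, error = function(e) {
      tibble::tibble(p = p, axis = axis, value = value,
                     vmr_evolved = NA_real_, vmr_fixed = NA_real_,
                     delta_vmr = NA_real_)
    })
  })
}

#' Scan the phenotypic variance of the within-host growth rate
#'
#' Varies the standing trait variance (set equally in both host types) and
#' summarizes, per value: the early epidemic peak of transmission dispersion
#' (the maximum vmr before the first local minimum of total infected
#' density), its timing, the time for the high-yield trait to cover half its
#' total change (an adaptation-speed measure), and the equilibrium
#' dispersion and traits.
#'
#' @param params Base [model_params()] object or preset name.
#' @param var_grid Nonnegative variance values.
#' @param eps0 Initial trait value.
#' @param t_end Trajectory horizon used for the early-epidemic summaries.
#' @param n Output time points.
#' @param form Dispersion form.
#' @return A tibble with one row per variance: `var`, `vmr_early_peak`,
#'   `t_peak`, `t_half_epsH`, `vmr_eq`, `epsH_eq`, `epsL_eq`.
#' @examples
#' \donttest{
#' scan_variance("baseline", var_grid = c(0, 1))
#' }
#' @export
scan_variance <- function(params = "baseline", var_grid = c(0, 0.5, 1, 2),
                          eps0 = 0.25, t_end = 50, n = 2001,
                          form = c("expanded", "compact")) {
  form <- match.arg(form)
  if (is.character(params)) params <- preset_params(params)
  params <- validate_params(params)
  stopifnot(all(var_grid >= 0))
  purrr::map_dfr(var_grid, function(v) {
    tryCatch({
      pars <- validate_params(utils::modifyList(unclass(params),
                                                list(varH = v, varL = v)))
      traj <- annotate_dispersion(
        simulate_evo(pars, init = evo_init(pars, epsH0 = eps0),
                     t_end = t_end, n = n),
        pars, form = form)
      i_tot <- traj$iH + traj$iL
      dip <- first_local_min(i_tot)
      early <- traj[seq_len(dip), ]
      k <- which.max(early$vmr)
      eq <- evo_equilibrium(pars, init = evo_init(pars, epsH0 = eps0))
      met <- equilibrium_dispersion(eq, form = form)
      tibble::tibble(var = v,
                     vmr_early_peak = early$vmr[k], t_peak = early$time[k],
                     t_half_epsH = half_change_time(traj$time, traj$epsH,
                                                    eq$state[["epsH"]]),
                     vmr_eq = met$vmr,
                     epsH_eq = eq$state[["epsH"]], epsL_eq = eq$state[["epsL"]])
    }, error = function(e) {
      tibble::tibble(var = v, vmr_early_peak = NA_real_, t_peak = NA_real_,
                     t_half_epsH = NA_real_, vmr_eq = NA_real_,
                     epsH_eq = NA_real_, epsL_eq = NA_real_)
    })
  })
}

# index of the first interior local minimum (after the series has risen);
# falls back to the last index if the series is monotone
first_local_min <- function(v) {
  n <- length(v)
  if (n < 3) return(n)
  rising <- FALSE
  for (k in 2:(n - 1)) {
    if (v[k] > v[k - 1]) rising <- TRUE
    if (rising && v[k] < v[k - 1] && v[k] <= v[k + 1]) return(k)
  }
  n
}

# first time the trait covers half the distance from its start to `target`,
# linearly interpolated between output points
half_change_time <- function(time, eps, target) {
  if (abs(target - eps[1]) < 1e-12) return(0)
  half <- eps[1] + (target - eps[1]) / 2
  hit <- if (target > eps[1]) which(eps >= half) else which(eps <= half)
  if (length(hit) == 0) return(NA_real_)
  k <- min(hit)
  if (k == 1) return(time[1])
  frac <- (half - eps[k - 1]) / (eps[k] - eps[k - 1])
  time[k - 1] + frac * (time[k] - time[k - 1])
}
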