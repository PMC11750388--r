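# shared fixtures: small states and parameter sets used across test files

baseline <- model_params()

# the reference state used in hand-derived arithmetic checks
ref_state <- c(sH = 1250, sL = 1250, iH = 1, iL = 1, epsH = 0.25, epsL = 0.25)

# identical host types (no quality gap)
identical_hosts <- model_params(cH = 0.1, cL = 0.1, yH = 0.3, yL = 0.3)

# swap the host-type labels of a parameter set (and the influx split)
swap_types <- function(params) {
  model_params(cH = params$cL, cL = params$cH, yH = params$yL, yL = params$yH,
               x = params$x, rho = params$rho, lam = params$lam,
               p = 1 - params$p, delta = params$delta, gamma = params$gamma,
               varH = params$varL, varL = params$varH)
}

# build a strain grid directly (bypassing the constructor's strictly-increasing
# check so degenerate grids with tied trait values can be exercised)
new_grid_for_test <- function(eps, w = rep(1 / length(eps), length(eps))) {
  structure(list(eps = eps, wH = w, wL = w), class = "evodisp_strain_grid")
}

swap_state <- function(state) {
  c(sH = unname(state[["sL"]]), sL = unname(state[["sH"]]),
    iH = unname(state[["iL"]]), iL = unname(state[["iH"]]),
    epsH = unname(state[["epsL"]]), epsL = unname(state[["epsH"]]))
}
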