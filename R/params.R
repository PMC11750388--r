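#' Model parameters for the heterogeneous host-parasite system
#'
#' Bundles every rate constant and trade-off parameter of the two-host-type
#' model. The host population receives a constant influx `lam` of susceptible
#' hosts, a proportion `p` of which are low-yield; all hosts die naturally at
#' rate `delta` and recover from infection at rate `gamma`. Each host type `j`
#' has a transmission set point `c_j` and a virulence slope `y_j`; together
#' with the concavity exponent `x` and scaling `rho` these define the
#' transmission and virulence trade-off functions of the parasite within-host
#' growth rate (see [transmission_rate()] and [virulence_rate()]). `varH` and
#' `varL` are the standing phenotypic variances of the within-host growth rate
#' in each host type, which scale the strength of selection in the
#' Price-equation trait dynamics; they are held constant in time.
#'
#' Densities and time are in the model units implied by `lam`/`delta`
#' (the disease-free total host density is `lam/delta`).
#'
#' @param cH,cL Transmission set points of high- and low-yield hosts
#'   (dimensionless, >= 0).
#' @param yH,yL Virulence slopes of high- and low-yield hosts (per unit trait
#'   per time, >= 0).
#' @param x Concavity exponent of the transmission function (0 < x <= 1).
#' @param rho Transmission scaling (per host density per time, > 0).
#' @param lam Susceptible influx rate (hosts per time, > 0).
#' @param p Proportion of influx that is low-yield (0 <= p <= 1).
#' @param delta Natural mortality rate (per time, > 0).
#' @param gamma Recovery rate (per time, >= 0).
#' @param varH,varL Phenotypic variance of the within-host growth rate in each
#'   host type (trait^2, >= 0).
#'
#' @return An object of class `evodisp_params`: a validated named list with
#'   the twelve fields above.
#'
#' @details Defaults are the baseline parameter set used throughout the
#'   package's worked examples: `cH = 1`, `cL = 0.1`, `yH = 0.1`, `yL = 1`,
#'   `x = 0.5`, `rho = 0.01`, `lam = 50`, `p = 0.5`, `delta = 0.02`,
#'   `gamma = 0.6`, `varH = varL = 1`.
#'
#' @examples
#' pars <- model_params()
#' pars
#' model_params(p = 0.9, yL = 2)
#' @export
model_params <- function(cH = 1, cL = 0.1, yH = 0.1, yL = 1,
                         x = 0.5, rho = 1e-2, lam = 50, p = 0.5,
                         delta = 0.02, gamma = 0.6, varH = 1, varL = 1) {
  pars <- list(cH = cH, cL = cL, yH = yH, yL = yL, x = x, rho = rho,
               lam = lam, p = p, delta = delta, gamma = gamma,
               varH = varH, varL = varL)
  validate_params(pars)
}

validate_params <- function(pars) {
  stopifnot(is.list(pars))
  needed <- c("cH", "cL", "yH", "yL", "x", "rho", "lam", "p",
              "delta", "gamma", "varH", "varL")
  missing <- setdiff(needed, names(pars))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pars <- pars[needed]
  bad <- !vapply(pars, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                 logical(1))
  if (any(bad)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(needed[bad], collapse = ", "), call. = FALSE)
  }
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(pars$cH >= 0 && pars$cL >= 0, "transmission set points cH, cL must be >= 0")
  chk(pars$yH >= 0 && pars$yL >= 0, "virulence slopes yH, yL must be >= 0")
  chk(pars$x > 0 && pars$x <= 1, "concavity exponent x must satisfy 0 < x <= 1")
  chk(pars$rho > 0, "transmission scaling rho must be > 0")
  chk(pars$lam > 0, "influx rate lam must be > 0")
  chk(pars$p >= 0 && pars$p <= 1, "influx proportion p must lie in [0, 1]")
  chk(pars$delta > 0, "mortality rate delta must be > 0")
  chk(pars$gamma >= 0, "recovery rate gamma must be >= 0")
  chk(pars$varH >= 0 && pars$varL >= 0, "trait variances varH, varL must be >= 0")
  structure(pars, class = "evodisp_params")
}

#' @export
print.evodisp_params <- function(x, ...) {
  cat("<evodisp_params>\n")
  cat(sprintf("  high-yield host: c = %g, y = %g (var = %g)\n", x$cH, x$yH, x$varH))
  cat(sprintf("  low-yield host:  c = %g, y = %g (var = %g)\n", x$cL, x$yL, x$varL))
  cat(sprintf("  trade-off: x = %g, rho = %g\n", x$x, x$rho))
  cat(sprintf("  demography: lam = %g, p = %g, delta = %g, gamma = %g\n",
              x$lam, x$p, x$delta, x$gamma))
  invisible(x)
}

# Scenario presets. "baseline" is the parameter set of the package's worked
# examples (heterogeneous hosts differing in both transmission and virulence);
# the "quality_gap_*" pair isolates a small vs large gap in host quality with
# cL = 0; "quality_grid" is the base set for quality-gap scans.
preset_table <- function() {
  list(
    baseline = model_params(),
    quality_gap_small = model_params(cH = 0.1, cL = 0, yH = 0.1, yL = 0.2),
    quality_gap_large = model_params(cH = 1, cL = 0, yH = 0.1, yL = 1),
    quality_grid = model_params(cH = 0.5, cL = 0, yH = 0.1, yL = 1)
  )
}

#' Named parameter presets
#'
#' Retrieve one of the built-in scenario parameter sets: `"baseline"` (hosts
#' differ in both transmission set point and virulence slope),
#' `"quality_gap_small"` and `"quality_gap_large"` (no transmission from the
#' parasite-free set point in low-yield hosts, small vs large host-quality
#' gap), and `"quality_grid"` (base set for quality-gap scans).
#'
#' @param name Preset name.
#' @return An `evodisp_params` object.
#' @examples
#' preset_params("quality_gap_large")
#' @export
preset_params <- function(name) {
  tab <- preset_table()
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab)) {
    stop("unknown preset '", paste(name, collapse = ","), "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  tab[[name]]
}

#' Serialize parameters to and from flat YAML configs
#'
#' Parameters round-trip through a flat YAML mapping whose keys are exactly
#' the field names of [model_params()] (`cH`, `cL`, `yH`, `yL`, `x`, `rho`,
#' `lam`, `p`, `delta`, `gamma`, `varH`, `varL`).
#'
#' @param params An `evodisp_params` object.
#' @param path File path.
#' @return `write_params_config()` returns `params` invisibly;
#'   `read_params_config()` returns an `evodisp_params` object.
#' @examples
#' tmp <- tempfile(fileext = ".yml")
#' write_params_config(model_params(p = 0.8), tmp)
#' read_params_config(tmp)
#' @export
write_params_config <- function(params, path) {
  params <- validate_params(params)
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(params)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$params) && is.list(raw$params)) raw <- raw$params
  validate_params(raw)
}
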