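#' Plot an annotated trajectory
#'
#' One panel per requested facet: host densities, mean traits, and
#' fitness/dispersion metrics over time.
#'
#' @param object An `evodisp_traj` tibble (ideally from
#'   [annotate_dispersion()]).
#' @param vars Which panels to draw: any of `"densities"`, `"traits"`,
#'   `"dispersion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' traj <- annotate_dispersion(simulate_evo(model_params(), t_end = 60, n = 121))
#' autoplot(traj)
#' @method autoplot evodisp_traj
#' @export
autoplot.evodisp_traj <- function(object,
                                  vars = c("densities", "traits", "dispersion"),
                                  ...) {
  vars <- match.arg(vars, several.ok = TRUE)
  df <- tibble::as_tibble(object)
  pick <- c(
    if ("densities" %in% vars) intersect(c("sH", "sL", "iH", "iL"), names(df)),
    if ("traits" %in% vars) intersect(c("epsH", "epsL"), names(df)),
    if ("dispersion" %in% vars) intersect(c("Re", "vmr"), names(df)))
  panel_of <- function(v) {
    dplyr::case_when(v %in% c("sH", "sL", "iH", "iL") ~ "host densities",
                     v %in% c("epsH", "epsL") ~ "mean trait",
                     TRUE ~ "fitness / dispersion")
  }
  long <- tidyr::pivot_longer(df[, c("time", pick)], -"time",
                              names_to = "series", values_to = "value")
  long$panel <- panel_of(long$series)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (model units)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a host-composition scan
#'
#' Equilibrium transmission dispersion against the realized proportion of
#' low-yield susceptible hosts.
#'
#' @param scan A tibble from [scan_host_composition()].
#' @return A ggplot object.
#' @export
plot_composition_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$pct_sL, y = .data$vmr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "proportion of susceptible hosts that are low-yield",
                  y = "equilibrium vmr(Re)") +
    ggplot2::theme_minimal()
}

#' Plot a quality-gap grid scan
#'
#' Tile map of the adaptation-driven change in equilibrium transmission
#' dispersion over the composition-by-quality grid.
#'
#' @param scan A tibble from [scan_quality_grid()].
#' @return A ggplot object.
#' @export
plot_quality_grid <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$p, y = .data$value,
                                     fill = .data$delta_vmr)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "proportion born low-yield (p)",
                  y = unique(scan$axis)[1],
                  fill = "Δ vmr(Re)") +
    ggplot2::theme_minimal()
}
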