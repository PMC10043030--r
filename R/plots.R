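#' Plot a dispersal sweep
#'
#' Growth rate against the proportion of animal-dispersed seeds, one line
#' per scenario.
#'
#' @param sweeps output of [dispersal_sweep()] (rows may mix scenarios).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweeps) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(sweeps, ggplot2::aes(
    x = .data$f_rel_anim_disp, y = .data$lambda,
    linetype = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "proportion of seeds dispersed by animals",
                  y = expression(lambda)) +
    ggplot2::theme_minimal()
}

#' Plot the effectiveness landscape
#'
#' Quantity (relative interaction frequency) against quality (per-seed
#' probability of producing a reproductive adult), per species.
#'
#' @param sde an [sde_table()] result.
#' @return A ggplot object.
#' @export
plot_sde_landscape <- function(sde) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(sde, ggplot2::aes(
    x = .data$quality, y = .data$quantity, label = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "quality (seed to reproductive adult)",
                  y = "quantity (relative interaction frequency)") +
    ggplot2::theme_minimal()
}
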