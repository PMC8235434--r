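# ggplot2 graphics for the package's result types.

#' Plot an RMSD probability density
#'
#' @param object An `rmsd_density` from [density_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rmsd_density
#' @export
autoplot.rmsd_density <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$summary$median, linetype = "dashed") +
    ggplot2::labs(
      x = "backbone RMSD to reference (Å)", y = "probability density",
      subtitle = sprintf("n = %d, bandwidth = %.3f Å",
                         length(object$values), object$bandwidth)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay RMSD densities of several ligands
#'
#' Draws the per-ligand probability densities of backbone RMSD to the
#' antagonist-bound reference on one panel, the standard visual comparison
#' for agonist/antagonist tendency: curves shifted toward higher RMSD stay
#' away from the open conformation (agonist-like), curves extending to lower
#' values approach it (antagonist-like).
#'
#' @param densities Named list of `rmsd_density` objects (names are ligand
#'   labels).
#' @return A ggplot object.
#' @export
plot_rmsd_densities <- function(densities) {
  if (is.null(names(densities))) stop_config("`densities` must be a named list.")
  df <- purrr::imap_dfr(densities, function(d, nm) {
    dplyr::mutate(d$grid, ligand = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$ligand)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "backbone RMSD to antagonist reference (Å)",
                  y = "probability density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a lambda-derivative series
#'
#' Node means of `dH/dlambda` with standard-error bars, one panel per
#' decoupling stage. The area under each curve is the stage's
#' thermodynamic-integration free energy.
#'
#' @param object A `lambda_series` from [sample_dhdl()] or
#'   [gen_lambda_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lambda_series
#' @export
autoplot.lambda_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$dhdl_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$dhdl_mean - .data$dhdl_se,
      ymax = .data$dhdl_mean + .data$dhdl_se
    )) +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = expression(lambda),
                  y = expression(paste(langle, partialdiff * H / partialdiff * lambda,
                                       rangle, " (kcal/mol)"))) +
    ggplot2::theme_minimal()
}

#' Plot per-frame helix-12 state calls
#'
#' @param object The tibble returned by [h12_state()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_h12_states <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("rmsd_active", "rmsd_inactive"),
                            names_to = "reference", values_to = "rmsd")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$rmsd,
                                   colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = dplyr::filter(object, .data$state == "open"),
      ggplot2::aes(x = .data$frame), inherit.aes = FALSE, sides = "b"
    ) +
    ggplot2::labs(x = "frame", y = "helix-12 RMSD (Å)", colour = NULL,
                  subtitle = "rug marks frames called open") +
    ggplot2::theme_minimal()
}
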