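#' Plot a per-residue topology map
#'
#' Relative PEGylation against residue index, points coloured by label,
#' with the called embedded segment shaded.
#'
#' @param object a `topology_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.topology_map <- function(object, ...) {
  seg <- attr(object, "embedded_segment")
  p <- ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$residue_index, y = .data$relative_pegylation_pct)
  )
  if (!is.null(seg)) {
    p <- p + ggplot2::annotate("rect",
      xmin = seg[1] - 0.5, xmax = seg[2] + 0.5, ymin = -Inf, ymax = Inf,
      alpha = 0.12, fill = "steelblue"
    )
  }
  p +
    ggplot2::geom_line(colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), na.rm = TRUE) +
    ggplot2::labs(
      x = "residue", y = "relative PEGylation (%)",
      colour = NULL, title = "Solvent-accessibility topology map"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a power-saturation fit
#'
#' Amplitude against the square root of microwave power (the conventional
#' axis), with the fitted saturation curve overlaid.
#'
#' @param object a `saturation_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = sqrt(.data$power_mW), y = .data$amplitude)) +
    ggplot2::geom_point()
  if (isTRUE(object$converged)) {
    grid <- tibble(power_mW = exp(seq(log(min(dat$power_mW)),
                                      log(max(dat$power_mW)), length.out = 200)))
    grid$amplitude <- saturation_model(grid$power_mW, object$I, object$P_half,
                                       object$epsilon)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p +
    ggplot2::labs(
      x = expression(sqrt(P) ~ (sqrt(mW))), y = "peak-to-peak amplitude",
      title = if (!is.na(object$site)) paste("Power saturation,", object$site) else "Power saturation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-site membrane depth-parameter profile
#'
#' @param object a `phi_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phi_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$residue_index, y = .data$phi)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), size = 2, na.rm = TRUE) +
    ggplot2::labs(
      x = "residue", y = expression(Phi),
      colour = NULL, title = "Membrane depth parameter profile"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a free-energy profile with its bootstrap SEM band
#'
#' @param object a `pmf_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  dat <- as_tibble(object) |> filter(.data$occupied)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_center_nm,
                                         y = .data$free_energy_kJmol))
  if (any(!is.na(dat$sem_kJmol))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy_kJmol - .data$sem_kJmol,
                   ymax = .data$free_energy_kJmol + .data$sem_kJmol),
      alpha = 0.25, fill = "steelblue", na.rm = TRUE
    )
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = expression(xi ~ (nm)), y = "G (kJ/mol)",
      title = "Potential of mean force"
    ) +
    ggplot2::theme_minimal()
}
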