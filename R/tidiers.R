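#' Tidy a saturation fit into a term/estimate table
#'
#' @param x a `saturation_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(
    term = c("I", "P_half", "epsilon"),
    estimate = c(x$I, x$P_half, x$epsilon),
    std.error = unname(x$std_errors[c("I", "P_half", "epsilon")])
  )
}

#' One-row summary of a saturation fit
#'
#' @param x a `saturation_fit`.
#' @param ... unused.
#' @return tibble with `site`, `condition`, `residual_norm`, `converged`,
#'   `epsilon_mode`, `n_points`.
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(
    site = x$site, condition = x$condition,
    residual_norm = x$residual_norm, converged = x$converged,
    epsilon_mode = x$epsilon_mode, n_points = nrow(x$data)
  )
}

#' Tidy a PMF profile into its per-bin table
#'
#' @param x a `pmf_profile`.
#' @param ... unused.
#' @return tibble with `bin_center_nm`, `free_energy_kJmol`, `sem_kJmol`,
#'   `occupied`.
#' @export
tidy.pmf_profile <- function(x, ...) {
  as_tibble(x)[, c("bin_center_nm", "free_energy_kJmol", "sem_kJmol", "occupied")]
}

#' One-row summary of a PMF profile
#'
#' @param x a `pmf_profile`.
#' @param ... unused.
#' @return tibble with `n_bins`, `n_occupied`, `kT`, `converged`,
#'   `iterations`, `max_free_energy`.
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_occupied = sum(x$occupied),
    kT = attr(x, "kT"),
    converged = attr(x, "converged"),
    iterations = attr(x, "iterations"),
    max_free_energy = if (all(is.na(x$free_energy_kJmol))) NA_real_
                      else max(x$free_energy_kJmol, na.rm = TRUE)
  )
}

#' One-row summary of a topology map
#'
#' @param x a `topology_map`.
#' @param ... unused.
#' @return tibble with residue counts per label and the embedded segment
#'   call.
#' @export
glance.topology_map <- function(x, ...) {
  seg <- attr(x, "embedded_segment")
  tibble(
    n_residues = nrow(x),
    n_exposed = sum(x$label == "exposed"),
    n_interface = sum(x$label == "interface"),
    n_embedded = sum(x$label == "embedded"),
    embedded_start = if (is.null(seg)) NA_integer_ else seg[1],
    embedded_end = if (is.null(seg)) NA_integer_ else seg[2],
    embedded_length = attr(x, "embedded_length")
  )
}
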