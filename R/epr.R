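#' Convert microwave attenuation to incident power
#'
#' @param dB attenuation in decibels (>= 0).
#' @param source_power_mW full source power in mW. The default of 200 mW is
#'   the unique value under which a 2-30 dB attenuation grid spans exactly
#'   126.2 down to 0.2 mW.
#' @return power in mW.
#' @export
attenuation_to_power <- function(dB, source_power_mW = 200) {
  if (any(dB < 0)) abort("attenuation dB must be >= 0")
  if (source_power_mW <= 0) abort("source_power_mW must be > 0")
  source_power_mW * 10^(-dB / 10)
}

#' Standard power-saturation attenuation grid
#'
#' The 2-30 dB in 2 dB steps grid of a 200 mW source, returned as ascending
#' powers in mW (0.2 ... 126.2 mW).
#'
#' @inheritParams attenuation_to_power
#' @param dB_steps attenuation values in dB.
#' @export
default_power_grid <- function(source_power_mW = 200, dB_steps = seq(2, 30, by = 2)) {
  sort(attenuation_to_power(dB_steps, source_power_mW))
}

#' Continuous-wave EPR power-saturation model
#'
#' Peak-to-peak amplitude of the central EPR line as a function of incident
#' microwave power:
#' \deqn{A = I \sqrt{P} \left[1 + (2^{1/\varepsilon} - 1) P / P_{1/2}\right]^{-\varepsilon}}
#' where \eqn{I} is a scaling factor, \eqn{P_{1/2}} the power at which the
#' amplitude falls to half its unsaturated extrapolation, and \eqn{\varepsilon}
#' the saturation-homogeneity exponent (1.5 for homogeneous, 0.5 for
#' inhomogeneous saturation).
#'
#' @param P power in mW (> 0), vectorised.
#' @param I amplitude scaling factor.
#' @param P_half half-saturation power in mW (> 0).
#' @param epsilon homogeneity exponent (> 0).
#' @return amplitude in the units of `I`.
#' @export
saturation_model <- function(P, I, P_half, epsilon) {
  if (any(P <= 0)) abort("P must be > 0")
  if (P_half <= 0) abort("P_half must be > 0")
  if (epsilon <= 0) abort("epsilon must be > 0")
  I * sqrt(P) * (1 + (2^(1 / epsilon) - 1) * P / P_half)^(-epsilon)
}

check_saturation_curve <- function(curve) {
  if (!all(c("power_mW", "amplitude") %in% names(curve))) {
    abort("curve needs columns power_mW and amplitude")
  }
  if (any(curve$power_mW <= 0)) abort("powers must be strictly positive")
  if (any(!is.finite(curve$amplitude))) abort("amplitudes must be finite")
  if (nrow(curve) < 5) abort("need >= 5 points for a saturation fit")
  if (max(curve$power_mW) / min(curve$power_mW) < 10) {
    abort("powers must span at least one decade")
  }
  invisible(curve)
}

#' Fit the power-saturation model to a measured curve
#'
#' Least-squares fit of [saturation_model()] over `(I, P_half, epsilon)` by
#' Levenberg-Marquardt with box bounds. Initial guesses: `I` from the median
#' of `A / sqrt(P)` over the three lowest powers; `P_half` from the power
#' where `A / sqrt(P)` first drops below half its low-power value (falling
#' back to the geometric mean of the power range); `epsilon` starts at 1.0
#' within `[0.5, 1.5]`. Standard errors come from the Gauss-Newton curvature
#' of the residual surface. Optimiser failure is reported via
#' `converged = FALSE`, never an exception.
#'
#' @param curve data frame with columns `power_mW` and `amplitude` (>= 5
#'   points spanning >= 1 decade of power).
#' @param epsilon `"free"` (default) to fit the homogeneity exponent within
#'   `[0.5, 1.5]`, or a fixed numeric value.
#' @param site,condition optional labels carried into the result.
#' @return object of class `saturation_fit` with elements `I`, `P_half`,
#'   `epsilon`, `std_errors`, `residual_norm`, `converged`, `data`.
#' @export
fit_saturation <- function(curve, epsilon = "free", site = NA_character_,
                           condition = NA_character_) {
  curve <- as_tibble(curve)
  check_saturation_curve(curve)
  eps_free <- identical(epsilon, "free")
  if (!eps_free && (!is.numeric(epsilon) || epsilon <= 0)) {
    abort("epsilon must be \"free\" or a positive number")
  }
  n_par <- if (eps_free) 3L else 2L
  if (nrow(curve) <= n_par) abort("fewer points than parameters")

  ord <- order(curve$power_mW)
  P <- curve$power_mW[ord]
  A <- curve$amplitude[ord]
  ratio <- A / sqrt(P)
  I0 <- median(ratio[seq_len(min(3, length(ratio)))])
  below <- which(ratio < I0 / 2)
  Ph0 <- if (length(below) > 0) P[below[1]] else sqrt(min(P) * max(P))
  I0 <- max(I0, .Machine$double.eps)

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  dat <- data.frame(P = P, A = A)
  fit <- tryCatch(
    {
      if (eps_free) {
        minpack.lm::nlsLM(
          A ~ saturation_model(P, I, Ph, eps), data = dat,
          start = list(I = I0, Ph = Ph0, eps = 1.0),
          lower = c(I = 1e-12, Ph = min(P) * 1e-3, eps = 0.5),
          upper = c(I = Inf, Ph = Inf, eps = 1.5),
          control = ctrl
        )
      } else {
        minpack.lm::nlsLM(
          A ~ saturation_model(P, I, Ph, epsilon), data = dat,
          start = list(I = I0, Ph = Ph0),
          lower = c(I = 1e-12, Ph = min(P) * 1e-3),
          upper = c(I = Inf, Ph = Inf),
          control = ctrl
        )
      }
    },
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    res <- list(
      site = site, condition = condition,
      I = NA_real_, P_half = NA_real_,
      epsilon = if (eps_free) NA_real_ else epsilon,
      epsilon_mode = if (eps_free) "free" else "fixed",
      std_errors = c(I = NA_real_, P_half = NA_real_, epsilon = NA_real_),
      residual_norm = NA_real_, converged = FALSE,
      failure = conditionMessage(fit), data = curve
    )
    return(structure(res, class = "saturation_fit"))
  }

  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, length(est))
  )
  res <- list(
    site = site, condition = condition,
    I = unname(est["I"]), P_half = unname(est["Ph"]),
    epsilon = if (eps_free) unname(est["eps"]) else epsilon,
    epsilon_mode = if (eps_free) "free" else "fixed",
    std_errors = c(
      I = unname(se["I"]), P_half = unname(se["Ph"]),
      epsilon = if (eps_free) unname(se["eps"]) else NA_real_
    ),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    converged = TRUE, failure = NULL, data = curve
  )
  structure(res, class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit>", if (!is.na(x$site)) paste0(" site ", x$site), "\n")
  cat(sprintf(
    "  I = %.4g  P_1/2 = %.4g mW  epsilon = %.3f (%s)  converged: %s\n",
    x$I, x$P_half, x$epsilon, x$epsilon_mode, x$converged
  ))
  invisible(x)
}

#' Membrane depth parameter from per-condition saturation fits
#'
#' Computes the depth parameter
#' \deqn{\Phi = \ln\left[\frac{P_{1/2}(\mathrm{O_2}) - P_{1/2}(\mathrm{N_2})}
#' {P_{1/2}(\mathrm{NiEDDA}) - P_{1/2}(\mathrm{N_2})}\right]}
#' contrasting the accessibility increments of the lipid-soluble relaxant
#' (O2) and the water-soluble relaxant (NiEDDA) over the nitrogen control.
#' Positive \eqn{\Phi} indicates membrane embedding, negative solvent
#' exposure, and values near 0 proximity to the membrane-solvent interface.
#'
#' @param fit_O2,fit_NiEDDA,fit_N2 `saturation_fit` objects, or bare numeric
#'   `P_half` values in mW.
#' @param phi_tol half-width of the interface band on \eqn{\Phi}
#'   (default 0.3).
#' @param site optional site label; taken from `fit_O2` when absent.
#' @return one-row tibble with `site`, `dP_oxygen`, `dP_niedda`, `phi`,
#'   `call` (embedded/interface/exposed/indeterminate), `reason`.
#' @export
depth_parameter <- function(fit_O2, fit_NiEDDA, fit_N2, phi_tol = 0.3,
                            site = NULL) {
  get_ph <- function(f) {
    if (inherits(f, "saturation_fit")) {
      list(P = f$P_half, ok = isTRUE(f$converged), site = f$site)
    } else {
      list(P = as.numeric(f), ok = TRUE, site = NA_character_)
    }
  }
  o2 <- get_ph(fit_O2); ni <- get_ph(fit_NiEDDA); n2 <- get_ph(fit_N2)
  if (is.null(site)) site <- o2$site
  row <- function(dpo, dpn, phi, call, reason = NA_character_) {
    tibble(
      site = site, dP_oxygen = dpo, dP_niedda = dpn,
      phi = phi, call = call, reason = reason
    )
  }
  if (!o2$ok || !ni$ok || !n2$ok) {
    return(row(NA_real_, NA_real_, NA_real_, "indeterminate", "non-converged input fit"))
  }
  dpo <- o2$P - n2$P
  dpn <- ni$P - n2$P
  if (dpo <= 0 || dpn <= 0) {
    return(row(dpo, dpn, NA_real_, "indeterminate", "non-positive collision increment"))
  }
  phi <- log(dpo / dpn)
  call <- if (phi > phi_tol) "embedded" else if (phi < -phi_tol) "exposed" else "interface"
  row(dpo, dpn, phi, call)
}

#' Assemble an ordered per-site depth-parameter profile
#'
#' Sorts per-site depth results by residue index and flags the monotopic
#' hairpin signature: at least one positive-\eqn{\Phi} core site with a
#' negative-\eqn{\Phi} site on each flank (two hydrophilic moieties flanking
#' one hydrophobic core).
#'
#' @param results tibble of rows from [depth_parameter()] (or an rbind of
#'   them); `site` must be coercible to a residue index.
#' @return tibble of class `phi_profile`, sorted by residue, with attribute
#'   `hairpin_signature` (logical).
#' @export
phi_depth_profile <- function(results) {
  if (nrow(results) < 1) abort("need at least one site")
  out <- results |>
    mutate(residue_index = as.integer(gsub("[^0-9]", "", .data$site))) |>
    arrange(.data$residue_index)
  phi <- out$phi[!is.na(out$phi)]
  sig <- FALSE
  if (length(phi) >= 3) {
    pos <- which(phi > 0)
    sig <- any(vapply(
      pos,
      function(j) any(phi[seq_len(j - 1)] < 0) && any(phi[seq(j, length(phi))[-1]] < 0),
      logical(1)
    ))
  }
  structure(out, class = c("phi_profile", class(out)), hairpin_signature = sig)
}

#' Fit saturation curves and compute depth parameters for many sites
#'
#' Convenience wrapper over [fit_saturation()] and [depth_parameter()] for a
#' long table of power-saturation measurements. Sites lacking any of the
#' three relaxant conditions are reported as indeterminate.
#'
#' @param measurements tibble with columns `site`, `condition`
#'   (`N2`/`O2`/`NiEDDA`), `power_mW`, `amplitude`.
#' @param epsilon passed to [fit_saturation()].
#' @param phi_tol passed to [depth_parameter()].
#' @return a `phi_profile` tibble; the per-condition fits are attached as
#'   attribute `fits`.
#' @export
epr_depth_analysis <- function(measurements, epsilon = "free", phi_tol = 0.3) {
  need <- c("site", "condition", "power_mW", "amplitude")
  if (!all(need %in% names(measurements))) {
    abort(paste("measurements needs columns", paste(need, collapse = ", ")))
  }
  fits <- measurements |>
    group_by(.data$site, .data$condition) |>
    group_map(function(df, key) {
      f <- fit_saturation(df, epsilon = epsilon,
                          site = key$site, condition = key$condition)
      f
    })
  key <- vapply(fits, function(f) paste(f$site, f$condition), character(1))
  names(fits) <- key
  sites <- unique(measurements$site)
  rows <- map(sites, function(s) {
    pick <- function(cond) fits[[paste(s, cond)]]
    o2 <- pick("O2"); ni <- pick("NiEDDA"); n2 <- pick("N2")
    if (is.null(o2) || is.null(ni) || is.null(n2)) {
      return(tibble(
        site = s, dP_oxygen = NA_real_, dP_niedda = NA_real_,
        phi = NA_real_, call = "indeterminate", reason = "missing condition"
      ))
    }
    depth_parameter(o2, ni, n2, phi_tol = phi_tol, site = s)
  })
  prof <- phi_depth_profile(dplyr::bind_rows(rows))
  attr(prof, "fits") <- fits
  prof
}
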