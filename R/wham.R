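#' Thermal energy from temperature
#'
#' @param temperature_K temperature in Kelvin (default 310).
#' @return kT in kJ/mol.
#' @export
kT_from_temperature <- function(temperature_K = 310) {
  0.00831446261815324 * temperature_K
}

#' Plan umbrella-window centers along a pulled span
#'
#' Centers are placed every `spacing` nm from `start`, covering the span
#' `pull_rate * duration` inclusive of both endpoints:
#' `floor(span / spacing) + 1` windows. A spacing wider than the span yields
#' a single window at `start`.
#'
#' @param pull_rate pulling rate in nm/ns.
#' @param duration pulling time in ns.
#' @param spacing window spacing in nm.
#' @param start first center in nm (default 0).
#' @return numeric vector of centers in nm.
#' @export
plan_windows <- function(pull_rate, duration, spacing, start = 0) {
  if (pull_rate <= 0 || duration <= 0 || spacing <= 0) {
    abort("pull_rate, duration and spacing must be > 0")
  }
  span <- pull_rate * duration
  if (spacing > span) return(start)
  n <- floor(span / spacing + 1e-9) + 1
  start + (seq_len(n) - 1) * spacing
}

#' Bin umbrella-window samples onto a shared grid
#'
#' Removes the leading `burn_in` fraction of each window's samples (in row
#' order), then counts the remainder into equal-width bins shared by all
#' windows.
#'
#' @param samples long tibble with columns `window_id`, `center_nm`, `k`
#'   (force constant, kJ mol-1 nm-2), `xi_nm`.
#' @param bin_width bin width in nm (default 0.02).
#' @param range optional `c(lo, hi)` bin range in nm; defaults to the span
#'   of the retained samples. Samples outside an explicit range are an
#'   error.
#' @param burn_in fraction of each window's leading samples to discard
#'   (default 0.4, matching equilibration removal from biased simulation
#'   windows; use 0 for independent synthetic samples).
#' @return object of class `wham_histograms`: list with `counts` (window x
#'   bin matrix), `bin_centers`, `bin_width`, `windows` (tibble of
#'   `window_id`, `center_nm`, `k`, `n`).
#' @export
build_histograms <- function(samples, bin_width = 0.02, range = NULL,
                             burn_in = 0.4) {
  need <- c("window_id", "center_nm", "k", "xi_nm")
  if (!all(need %in% names(samples))) {
    abort(paste("samples needs columns", paste(need, collapse = ", ")))
  }
  if (bin_width <= 0) abort("bin_width must be > 0")
  if (burn_in < 0 || burn_in >= 1) abort("burn_in must lie in [0, 1)")
  kept <- samples |>
    group_by(.data$window_id) |>
    mutate(.row = dplyr::row_number(), .n = dplyr::n()) |>
    filter(.data$.row > floor(burn_in * .data$.n)) |>
    ungroup()
  if (nrow(kept) == 0) abort("no samples retained after burn-in removal")
  if (is.null(range)) {
    range <- base::range(kept$xi_nm)
  } else if (any(kept$xi_nm < range[1] | kept$xi_nm > range[2])) {
    abort("samples fall outside the supplied range; widen it first")
  }
  lo <- floor(range[1] / bin_width) * bin_width
  n_bins <- ceiling((range[2] - lo) / bin_width + 1e-9)
  n_bins <- max(n_bins, 1L)
  breaks <- lo + (0:n_bins) * bin_width
  bin_centers <- lo + (seq_len(n_bins) - 0.5) * bin_width

  windows <- kept |>
    group_by(.data$window_id) |>
    summarise(
      center_nm = .data$center_nm[1], k = .data$k[1], n = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$center_nm)
  counts <- do.call(rbind, lapply(windows$window_id, function(w) {
    xi <- kept$xi_nm[kept$window_id == w]
    idx <- pmin(pmax(floor((xi - lo) / bin_width) + 1, 1L), n_bins)
    tabulate(idx, nbins = n_bins)
  }))
  structure(
    list(
      counts = counts, bin_centers = bin_centers,
      bin_width = bin_width, windows = windows
    ),
    class = "wham_histograms"
  )
}

#' Solve the weighted-histogram (WHAM) equations for a 1-D PMF
#'
#' Self-consistent iteration of the coupled WHAM equations. With per-window
#' counts \eqn{n_i(b)}, totals \eqn{N_i}, and harmonic biases
#' \eqn{U_i(b) = \tfrac{1}{2} k_i (\xi_b - \xi_i)^2}, the unbiased bin
#' probability and window free energies are iterated as
#' \deqn{P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i e^{(f_i - U_i(b))/kT}},
#' \qquad f_i = -kT \ln \sum_b P(b)\, e^{-U_i(b)/kT}}
#' until the largest change in any \eqn{f_i} falls below `tolerance` (in kT
#' units). The free energy is \eqn{G(b) = -kT \ln P(b)}, anchored so its
#' minimum over occupied bins is 0. Bins with no counts are reported as
#' `NA`, not 0. Adjacent windows (by center) must share at least one
#' occupied bin; otherwise the profile is withheld with `converged = FALSE`
#' and the gap is reported.
#'
#' @param histograms a [build_histograms()] result.
#' @param kT thermal energy in kJ/mol (default 310 K).
#' @param tolerance convergence threshold on `max |delta f_i| / kT`
#'   (default 1e-7).
#' @param max_iterations iteration cap (default 1e5).
#' @param check_overlap logical; withhold the profile when adjacent windows
#'   share no occupied bin (default TRUE). Bootstrap replicates solve with
#'   the check off, since resampling the window set legitimately drops
#'   windows.
#' @param f_init initial window free energies in kJ/mol (default all 0);
#'   the converged profile is invariant to a constant shift of the
#'   initialisation (the equations fix the f only up to a gauge).
#' @return tibble of class `pmf_profile` with columns `bin_center_nm`,
#'   `free_energy_kJmol`, `sem_kJmol` (NA until [bootstrap_sem()] fills it),
#'   `occupied`; attributes `kT`, `converged`, `iterations`, `f_windows`,
#'   `gaps`.
#' @export
wham_solve <- function(histograms, kT = kT_from_temperature(310),
                       tolerance = 1e-7, max_iterations = 1e5,
                       check_overlap = TRUE, f_init = NULL) {
  h <- histograms
  ord <- order(h$windows$center_nm)
  counts <- h$counts[ord, , drop = FALSE]
  w <- h$windows[ord, ]
  xi <- h$bin_centers
  n_win <- nrow(counts)
  occ <- colSums(counts) > 0

  empty_profile <- function(gaps) {
    out <- tibble(
      bin_center_nm = xi,
      free_energy_kJmol = NA_real_,
      sem_kJmol = NA_real_,
      occupied = occ
    )
    structure(out,
      class = c("pmf_profile", class(out)),
      kT = kT, converged = FALSE, iterations = 0L,
      f_windows = rep(NA_real_, n_win), gaps = gaps
    )
  }

  if (check_overlap && n_win > 1) {
    # aggregate duplicate centers before the adjacency check
    centers_u <- unique(w$center_nm)
    agg <- t(vapply(centers_u, function(cc) {
      colSums(counts[w$center_nm == cc, , drop = FALSE])
    }, numeric(ncol(counts))))
    gaps <- list()
    for (i in seq_len(length(centers_u) - 1)) {
      if (!any(agg[i, ] > 0 & agg[i + 1, ] > 0)) {
        gaps[[length(gaps) + 1]] <- c(centers_u[i], centers_u[i + 1])
      }
    }
    if (length(gaps) > 0) {
      warn(paste(
        "histogram overlap gap between window center pair(s):",
        paste(vapply(gaps, paste, character(1), collapse = "/"), collapse = ", ")
      ))
      return(empty_profile(gaps))
    }
  }

  U <- 0.5 * outer(w$k, rep(1, length(xi))) *
    (outer(rep(1, n_win), xi) - outer(w$center_nm, rep(1, length(xi))))^2
  B <- exp(-U / kT)                 # n_win x n_bin
  N <- w$n
  tot <- colSums(counts)
  f <- if (is.null(f_init)) rep(0, n_win) else rep_len(f_init, n_win)

  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    denom <- as.vector(crossprod(N * exp(f / kT), B))
    P <- tot / denom
    f_new <- -kT * log(as.vector(B %*% P))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f)) / kT
    f <- f_new
    if (delta < tolerance) { converged <- TRUE; break }
    if (iterations >= max_iterations) break
  }

  G <- -kT * log(P)
  G[!occ] <- NA_real_
  G <- G - min(G, na.rm = TRUE)
  out <- tibble(
    bin_center_nm = xi,
    free_energy_kJmol = G,
    sem_kJmol = NA_real_,
    occupied = occ
  )
  structure(out,
    class = c("pmf_profile", class(out)),
    kT = kT, converged = converged, iterations = iterations,
    f_windows = f, gaps = list()
  )
}

#' Bootstrap SEM of a WHAM profile by resampling whole windows
#'
#' Resamples the set of umbrella-window histograms with replacement
#' (preserving the window count), re-solves WHAM per replicate, and reports
#' the per-bin standard deviation over replicates. Bins missing (or whole
#' replicates that fail to converge, e.g. through a lost overlap) are
#' skipped for that replicate.
#'
#' @param histograms a [build_histograms()] result.
#' @param kT thermal energy in kJ/mol.
#' @param n_boot number of bootstrap replicates (>= 2, default 50).
#' @param seed integer seed; fixes the resampling exactly.
#' @param tolerance,max_iterations per-replicate WHAM stopping rule; looser
#'   than the main solve by default, since the replicate spread, not the
#'   replicate profiles, is the quantity of interest.
#' @param ... passed to [wham_solve()].
#' @return numeric vector of per-bin SEM (kJ/mol), aligned with
#'   `histograms$bin_centers`; attribute `n_replicates_used`.
#' @export
bootstrap_sem <- function(histograms, kT = kT_from_temperature(310),
                          n_boot = 50, seed = 1L, tolerance = 1e-5,
                          max_iterations = 2e4, ...) {
  if (n_boot < 2) abort("n_boot must be >= 2")
  h <- histograms
  n_win <- nrow(h$counts)
  picks <- with_seed(
    substream_seed(seed, 307L),
    replicate(n_boot, sample.int(n_win, n_win, replace = TRUE), simplify = FALSE)
  )
  profiles <- map(picks, function(idx) {
    hb <- h
    hb$counts <- h$counts[idx, , drop = FALSE]
    hb$windows <- h$windows[idx, ]
    prof <- suppressWarnings(wham_solve(hb, kT = kT, check_overlap = FALSE,
                                        tolerance = tolerance,
                                        max_iterations = max_iterations, ...))
    if (!attr(prof, "converged")) return(NULL)
    prof$free_energy_kJmol
  })
  mat <- do.call(rbind, profiles[!vapply(profiles, is.null, logical(1))])
  if (is.null(mat) || nrow(mat) < 2) {
    warn("fewer than 2 bootstrap replicates converged; SEM is NA")
    return(structure(rep(NA_real_, length(h$bin_centers)), n_replicates_used = 0L))
  }
  sem <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) else NA_real_
  })
  structure(sem, n_replicates_used = nrow(mat))
}

#' Umbrella samples to free-energy profile in one call
#'
#' Convenience wrapper: [build_histograms()], [wham_solve()], and optionally
#' [bootstrap_sem()].
#'
#' @inheritParams build_histograms
#' @inheritParams wham_solve
#' @param n_boot bootstrap replicates for the SEM band; 0 skips it.
#' @param seed bootstrap seed.
#' @return a `pmf_profile` tibble with `sem_kJmol` filled when
#'   `n_boot >= 2`.
#' @export
wham_pmf <- function(samples, bin_width = 0.02, range = NULL, burn_in = 0.4,
                     kT = kT_from_temperature(310), tolerance = 1e-7,
                     max_iterations = 1e5, n_boot = 0, seed = 1L) {
  h <- build_histograms(samples, bin_width = bin_width, range = range,
                        burn_in = burn_in)
  prof <- wham_solve(h, kT = kT, tolerance = tolerance,
                     max_iterations = max_iterations)
  if (n_boot >= 2 && attr(prof, "converged")) {
    prof$sem_kJmol <- bootstrap_sem(h, kT = kT, n_boot = n_boot, seed = seed)
  }
  attr(prof, "histograms") <- h
  prof
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- sum(x$occupied)
  cat(sprintf(
    "<pmf_profile> %d bins (%d occupied), kT = %.3f kJ/mol, converged: %s (%d iterations)\n",
    nrow(x), occ, attr(x, "kT"), attr(x, "converged"), attr(x, "iterations")
  ))
  if (occ > 0 && any(!is.na(x$free_energy_kJmol))) {
    cat(sprintf("  range of G: 0 .. %.2f kJ/mol\n",
                max(x$free_energy_kJmol, na.rm = TRUE)))
  }
  invisible(x)
}
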