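# shared fixture builders

# minimal membrane frame: CA atoms at given coordinates (Angstrom) plus a
# flat cytoplasmic phosphate plane at plane_z
toy_frame <- function(ca_xyz, residues = seq_len(nrow(ca_xyz)), plane_z = 0,
                      lumenal_z = NULL) {
  ca <- tibble::tibble(
    residue_index = as.integer(residues),
    residue_name = "ALA", atom_name = "CA",
    x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3],
    leaflet = NA_character_
  )
  grid <- expand.grid(px = c(-20, 0, 20), py = c(-20, 0, 20))
  p <- tibble::tibble(
    residue_index = 500L + seq_len(nrow(grid)),
    residue_name = "POP", atom_name = "P",
    x = grid$px, y = grid$py, z = plane_z,
    leaflet = "cytoplasmic"
  )
  atoms <- dplyr::bind_rows(ca, p)
  if (!is.null(lumenal_z)) {
    p2 <- p
    p2$residue_index <- 700L + seq_len(nrow(grid))
    p2$z <- lumenal_z
    p2$leaflet <- "lumenal"
    atoms <- dplyr::bind_rows(atoms, p2)
  }
  membrane_frame(atoms)
}

# hand-built accessibility records for one residue/replicate from lane
# fractions (native and detergent PEGylated fractions)
toy_access_records <- function(residue, f_native, f_detergent, total = 100,
                               replicate = 1L) {
  tibble::tibble(
    residue_index = as.integer(residue), wt_aa = "X",
    lane = rep(c("no_mPEG", "mPEG", "detergent_mPEG"), each = 2),
    band = rep(c("PEG0", "PEG1"), 3),
    intensity = total * c(1, 0, 1 - f_native, f_native,
                          1 - f_detergent, f_detergent),
    replicate_id = as.integer(replicate)
  )
}

# independent dominant-period oracle: least-squares fit of a sinusoid at each
# candidate period on a fine grid, taking the period with the smallest
# residual sum of squares (no Fourier transform involved)
oracle_dominant_period <- function(values, periods = seq(2, length(values) / 2, by = 0.01)) {
  y <- values - mean(values)
  n <- seq_along(y)
  rss <- vapply(periods, function(p) {
    X <- cbind(sin(2 * pi * n / p), cos(2 * pi * n / p))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  periods[which.min(rss)]
}
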