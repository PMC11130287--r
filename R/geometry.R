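#' Construct a membrane frame from a per-atom table
#'
#' A membrane frame is a per-atom coordinate table with the membrane normal
#' along z and phosphate (P) pseudo-atoms defining the headgroup reference
#' plane. Coordinates are stored in Angstrom; depth observables are reported
#' in nm, distances in Angstrom, angles in degrees.
#'
#' @param atoms data frame with columns `residue_index`, `residue_name`,
#'   `atom_name`, `x`, `y`, `z` (Angstrom) and optionally `leaflet`
#'   (`"cytoplasmic"` / `"lumenal"` for P atoms).
#' @return tibble of class `membrane_frame`.
#' @export
membrane_frame <- function(atoms) {
  need <- c("residue_index", "residue_name", "atom_name", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(paste("atoms needs columns", paste(need, collapse = ", ")))
  }
  out <- as_tibble(atoms)
  if (!"leaflet" %in% names(out)) out$leaflet <- NA_character_
  ca <- out |> filter(.data$atom_name == "CA")
  if (anyDuplicated(ca$residue_index)) {
    abort("every analyzed residue must have exactly one CA atom")
  }
  structure(out, class = c("membrane_frame", class(out)))
}

frame_ca <- function(frame) filter(frame, .data$atom_name == "CA")

frame_p <- function(frame) {
  p <- filter(frame, .data$atom_name == "P")
  if (nrow(p) == 0) abort("frame has no phosphate (P) atoms")
  if (all(is.na(p$leaflet))) {
    # assign leaflets by z-sign around the global P midplane; a thin P slab
    # (span < 10 A) is treated as a single cytoplasmic leaflet (monolayer)
    if (diff(range(p$z)) < 10) {
      p$leaflet <- "cytoplasmic"
    } else {
      midz <- mean(p$z)
      upper <- p$z >= midz
      ca_mean <- mean(frame_ca(frame)$z)
      up_closer <- abs(mean(p$z[upper]) - ca_mean) <= abs(mean(p$z[!upper]) - ca_mean)
      p$leaflet <- ifelse(upper == up_closer, "cytoplasmic", "lumenal")
    }
  }
  p
}

#' Phosphate reference-plane level
#'
#' Arithmetic mean z of the cytoplasmic-leaflet phosphate atoms, in nm.
#'
#' @param frame a [membrane_frame()].
#' @return z-level of the headgroup plane in nm.
#' @export
phosphate_plane <- function(frame) {
  p <- frame_p(frame) |> filter(.data$leaflet == "cytoplasmic")
  if (nrow(p) < 3) abort("need >= 3 cytoplasmic-leaflet P atoms to define a plane")
  mean(p$z) / 10
}

#' Signed per-residue insertion depth
#'
#' Depth of each residue's CA below the cytoplasmic phosphate plane, in nm;
#' positive = inserted into the membrane, negative = on the solvent side.
#' The insertion direction is taken as the side of the plane holding the
#' peptide's mean CA, so the sign convention is independent of how the
#' structure is oriented along z.
#'
#' @param frame a [membrane_frame()].
#' @param residues residue indices to measure (default: all CA-bearing).
#' @return tibble with `residue_index`, `depth_nm`.
#' @export
residue_depth <- function(frame, residues = NULL) {
  plane <- phosphate_plane(frame)
  ca <- frame_ca(frame)
  if (is.null(residues)) residues <- ca$residue_index
  missing <- setdiff(residues, ca$residue_index)
  if (length(missing) > 0) {
    abort(paste("missing CA for residue(s):", paste(missing, collapse = ", ")))
  }
  flip <- mean(ca$z) / 10 > plane
  ca <- ca[match(residues, ca$residue_index), ]
  depth <- plane - ca$z / 10
  if (flip) depth <- -depth
  tibble(residue_index = as.integer(residues), depth_nm = depth)
}

#' Distance between two atoms of a frame
#'
#' @param frame a [membrane_frame()].
#' @param residue_a,residue_b residue indices.
#' @param atom atom name (default CA).
#' @return Euclidean distance in Angstrom.
#' @export
pair_distance <- function(frame, residue_a, residue_b, atom = "CA") {
  pick <- function(res) {
    a <- filter(frame, .data$residue_index == res, .data$atom_name == atom)
    if (nrow(a) != 1) abort(paste0("atom ", atom, " of residue ", res, " not found (or not unique)"))
    c(a$x, a$y, a$z)
  }
  sqrt(sum((pick(residue_a) - pick(residue_b))^2))
}

principal_axis <- function(coords) {
  if (nrow(unique(round(coords, 6))) < 3) {
    abort("degenerate geometry: need >= 3 distinct points")
  }
  pc <- prcomp(coords, center = TRUE, scale. = FALSE)
  pc$rotation[, 1]
}

#' Helix tilt angle relative to the membrane plane
#'
#' Angle between the first principal axis of the selected CA coordinates and
#' the membrane (xy) plane: 90 deg = perpendicular to the plane, 0 deg = flat
#' in the plane. Axis orientation sign is discarded.
#'
#' @param frame a [membrane_frame()].
#' @param residue_range optional inclusive `c(lo, hi)` selection of residues.
#' @return tilt in degrees, in `[0, 90]`.
#' @export
tilt_angle <- function(frame, residue_range = NULL) {
  ca <- frame_ca(frame)
  if (!is.null(residue_range)) {
    ca <- filter(ca, .data$residue_index >= residue_range[1],
                 .data$residue_index <= residue_range[2])
  }
  if (nrow(ca) < 3) abort("need >= 3 CA atoms for a tilt axis")
  v <- principal_axis(as.matrix(ca[, c("x", "y", "z")]))
  ang_from_normal <- acos(pmin(1, abs(v[3]) / sqrt(sum(v^2)))) * 180 / pi
  90 - ang_from_normal
}

#' Opening angle of a hairpin at its kink
#'
#' Angle between the two arm principal axes, each oriented away from the kink
#' residue's CA; 180 deg = straight, small angles = closed V.
#'
#' @param frame a [membrane_frame()].
#' @param arm1_range,arm2_range inclusive residue intervals for the two arms
#'   (each >= 3 CA).
#' @param kink_residue residue index of the kink.
#' @return angle in degrees, in `[0, 180]`.
#' @export
opening_angle <- function(frame, arm1_range, arm2_range, kink_residue) {
  ca <- frame_ca(frame)
  kink <- ca[ca$residue_index == kink_residue, c("x", "y", "z")]
  if (nrow(kink) != 1) abort("kink residue CA not found")
  kink <- as.numeric(kink)
  arm_axis <- function(rng) {
    sel <- filter(ca, .data$residue_index >= rng[1], .data$residue_index <= rng[2])
    if (nrow(sel) < 3) abort("each arm needs >= 3 CA atoms")
    m <- as.matrix(sel[, c("x", "y", "z")])
    v <- principal_axis(m)
    away <- colMeans(m) - kink
    if (sum(v * away) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  v1 <- arm_axis(arm1_range)
  v2 <- arm_axis(arm2_range)
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}

#' Classify the hairpin conformation from kink depth and tilt
#'
#' `deep_V` when the kink is inserted >= 1.0 nm below the phosphate plane and
#' the hairpin stands steeply (tilt >= 55 deg); `open_shallow` when the kink
#' sits within 0.5 nm of the plane and the hairpin lies flat (tilt <= 45
#' deg); otherwise `ambiguous`.
#'
#' @param kink_depth_nm signed kink insertion depth in nm.
#' @param tilt_deg tilt angle in degrees.
#' @return one of `"deep_V"`, `"open_shallow"`, `"ambiguous"`.
#' @export
classify_conformation <- function(kink_depth_nm, tilt_deg) {
  if (!is.finite(kink_depth_nm) || !is.finite(tilt_deg)) {
    abort("kink depth and tilt must be finite")
  }
  if (kink_depth_nm >= 1.0 && tilt_deg >= 55) return("deep_V")
  if (kink_depth_nm <= 0.5 && tilt_deg <= 45) return("open_shallow")
  "ambiguous"
}

#' Scalar geometry observables of a hairpin frame
#'
#' Measures the kink insertion depth, hairpin tilt, arm-tip CA distance,
#' V-opening angle, and the resulting conformation call in one row.
#'
#' @param frame a [membrane_frame()].
#' @param kink_residue kink residue index (default 102).
#' @param arm1_range,arm2_range residue intervals of the two helical arms.
#' @param tip_pair residue pair for the arm-tip distance (default
#'   `c(91, 118)`).
#' @param residue_range selection for the tilt axis (default: all CA).
#' @return one-row tibble with `kink_depth_nm`, `tilt_deg`,
#'   `tip_distance_A`, `opening_angle_deg`, `conformation`.
#' @export
membrane_observables <- function(frame, kink_residue = 102L,
                                 arm1_range = c(90L, 101L),
                                 arm2_range = c(103L, 122L),
                                 tip_pair = c(91L, 118L),
                                 residue_range = NULL) {
  depth <- residue_depth(frame, kink_residue)$depth_nm
  tilt <- tilt_angle(frame, residue_range)
  tibble(
    kink_depth_nm = depth,
    tilt_deg = tilt,
    tip_distance_A = pair_distance(frame, tip_pair[1], tip_pair[2]),
    opening_angle_deg = opening_angle(frame, arm1_range, arm2_range, kink_residue),
    conformation = classify_conformation(depth, tilt)
  )
}

#' Average observables over the trailing window of a trajectory
#'
#' Computes a scalar (or named-vector) observable per frame, then averages
#' over the trailing fraction of frames with the SEM across frames.
#'
#' @param frames list of [membrane_frame()] objects, in time order.
#' @param fun function of one frame returning a numeric scalar or named
#'   vector.
#' @param window trailing fraction of frames to use (default 0.25).
#' @return tibble with `observable`, `mean`, `sem`, `n_frames`.
#' @export
frame_average <- function(frames, fun, window = 0.25) {
  if (length(frames) < 1) abort("need at least one frame")
  n_use <- max(1L, floor(window * length(frames) + 1e-9))
  use <- tail(frames, n_use)
  vals <- map(use, fun)
  m <- do.call(rbind, map(vals, function(v) {
    if (is.null(names(v))) names(v) <- paste0("obs", seq_along(v))
    v
  }))
  tibble(
    observable = colnames(m),
    mean = unname(colMeans(m)),
    sem = unname(apply(m, 2, function(x) {
      if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
    })),
    n_frames = n_use
  )
}
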