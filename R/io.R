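#' Read and write the tabular interchange formats
#'
#' Plain-CSV schemas shared by the generators and the analysis stages:
#' accessibility tables (`residue_index`, `wt_aa`, `lane`, `band`,
#' `intensity`, `replicate_id`), power-saturation tables (`site`,
#' `condition`, `power_mW` or `attenuation_dB`, `amplitude`), umbrella
#' samples (`window_id`, `center_nm`, `k`, `xi_nm`), and PMF profiles
#' (`bin_center_nm`, `G_kJmol`, `sem_kJmol`).
#'
#' @param path file path.
#' @param x table to write.
#' @param source_power_mW used to convert an `attenuation_dB` column to
#'   `power_mW` when present.
#' @name memtopo_io
NULL

#' @rdname memtopo_io
#' @export
read_accessibility_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname memtopo_io
#' @export
write_accessibility_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname memtopo_io
#' @export
read_saturation_csv <- function(path, source_power_mW = 200) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"power_mW" %in% names(x) && "attenuation_dB" %in% names(x)) {
    x$power_mW <- attenuation_to_power(x$attenuation_dB, source_power_mW)
  }
  x
}

#' @rdname memtopo_io
#' @export
write_saturation_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname memtopo_io
#' @export
read_umbrella_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname memtopo_io
#' @export
write_umbrella_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname memtopo_io
#' @export
write_pmf_csv <- function(x, path) {
  readr::write_csv(
    tibble(
      bin_center_nm = x$bin_center_nm,
      G_kJmol = x$free_energy_kJmol,
      sem_kJmol = x$sem_kJmol
    ),
    path
  )
  invisible(path)
}

#' Read a coordinate file into a membrane frame
#'
#' Accepts PDB (via bio3d), GRO (fixed-width, nm converted to Angstrom), or
#' a plain per-atom CSV with the [membrane_frame()] columns.
#'
#' @param path coordinate file (`.pdb`, `.gro`, or `.csv`).
#' @return a [membrane_frame()].
#' @export
read_membrane_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    frame <- membrane_frame(tibble(
      residue_index = as.integer(a$resno),
      residue_name = a$resid,
      atom_name = trimws(a$elety),
      x = a$x, y = a$y, z = a$z
    ))
  } else if (ext == "gro") {
    frame <- read_gro(path)
  } else if (ext == "csv") {
    frame <- membrane_frame(readr::read_csv(path, show_col_types = FALSE))
  } else {
    abort(paste0("unsupported coordinate format: .", ext))
  }
  frame
}

# Minimal GROMACS .gro reader: fixed-width records, coordinates in nm.
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  membrane_frame(tibble(
    residue_index = as.integer(substr(rec, 1, 5)),
    residue_name = trimws(substr(rec, 6, 10)),
    atom_name = trimws(substr(rec, 11, 15)),
    x = 10 * as.numeric(substr(rec, 21, 28)),
    y = 10 * as.numeric(substr(rec, 29, 36)),
    z = 10 * as.numeric(substr(rec, 37, 44))
  ))
}

#' Write a membrane frame as a PDB file
#'
#' @param frame a [membrane_frame()].
#' @param path output path.
#' @export
write_frame_pdb <- function(frame, path) {
  xyz <- as.numeric(t(as.matrix(frame[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = ifelse(is.na(frame$residue_index), 9999L, frame$residue_index),
    resid = frame$residue_name,
    elety = frame$atom_name,
    chain = ifelse(frame$atom_name == "P", "M", "A")
  )
  invisible(path)
}

#' Write a ground-truth sidecar JSON next to a generated dataset
#'
#' @param truth the `ground_truth` attribute of a generated dataset.
#' @param path output `.json` path.
#' @export
write_ground_truth_json <- function(truth, path) {
  drop_funs <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(purrr::compact(lapply(x, drop_funs)))
    x
  }
  jsonlite::write_json(drop_funs(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
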