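# Partial wild-type identity map for the UBXD8 hairpin region; positions the
# source experiments name explicitly. Unknown positions fall back to "X".
.wt_aa_map <- c(
  `80` = "S", `81` = "Y", `85` = "R", `88` = "P", `89` = "R", `90` = "G", `91` = "L",
  `92` = "L", `93` = "G", `94` = "W", `96` = "Y", `101` = "L", `102` = "P",
  `104` = "R", `107` = "Y", `109` = "T", `113` = "I", `114` = "F",
  `115` = "R", `118` = "L", `119` = "R", `122` = "R", `123` = "P",
  `124` = "D", `127` = "S", `128` = "R"
)

wt_aa_for <- function(residues) {
  aa <- .wt_aa_map[as.character(residues)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Ground-truth specification for a synthetic accessibility experiment
#'
#' Describes the scanning single-cysteine PEGylation experiment the generator
#' emulates: which hairpin conformation the membrane context imposes, the
#' residue window scanned, the segment plan (which residues are solvent
#' exposed, interfacial, or membrane embedded), and the densitometry noise
#' level.
#'
#' The default segment plan encodes the bilayer ground truth: exposed N- and
#' C-terminal stretches (80-89 and 124-128), short interfacial transitions
#' (90-93 and 123), and a 29-residue embedded hairpin core (94-122). In the
#' `open_shallow` conformation the embedded core additionally carries a
#' sinusoidal partial-exposure component with a period of 3.6 residues per
#' helical turn, emulating one helix face lifting toward solvent.
#'
#' The default residue window 80-128 contains 49 positions. The source
#' experiments describe a library of 48 mutants over the same interval; the
#' generator covers all 49 positions and records this discrepancy in the
#' ground-truth attribute rather than silently dropping one.
#'
#' @param conformation `"deep_V"` (bilayer-like) or `"open_shallow"`
#'   (monolayer-like).
#' @param residue_range inclusive integer interval scanned, default `c(80, 128)`.
#' @param segments named list of inclusive residue intervals labelled
#'   `exposed`, `interface`, or `embedded` (label prefix decides the class).
#'   Must be disjoint and jointly cover `residue_range`.
#' @param noise_sd_fraction multiplicative log-normal noise sd as a fraction
#'   of band intensity; 0 gives noise-free tables.
#' @param n_replicates independent replicate lanes per residue.
#' @param low_control_residues residues whose detergent positive-control lane
#'   is made inefficient (emulating positions whose local structure blocks the
#'   label even after solubilisation); default `c(102, 113, 114)`.
#' @param seed integer; fully determines all stochastic output.
#' @return a list of class `accessibility_spec`.
#' @export
accessibility_spec <- function(conformation = c("deep_V", "open_shallow"),
                               residue_range = c(80L, 128L),
                               segments = NULL,
                               noise_sd_fraction = 0,
                               n_replicates = 2L,
                               low_control_residues = c(102L, 113L, 114L),
                               seed = 1L) {
  conformation <- match.arg(conformation)
  stopifnot(length(residue_range) == 2, residue_range[2] >= residue_range[1])
  if (is.null(segments)) {
    segments <- list(
      exposed_n   = c(80L, 89L),
      interface_n = c(90L, 93L),
      embedded    = c(94L, 122L),
      interface_c = c(123L, 123L),
      exposed_c   = c(124L, 128L)
    )
  }
  covered <- sort(unlist(lapply(segments, function(iv) seq(iv[1], iv[2]))))
  wanted <- seq(residue_range[1], residue_range[2])
  if (anyDuplicated(covered) || !identical(as.integer(covered), as.integer(wanted))) {
    abort("segment intervals must be disjoint and jointly cover residue_range")
  }
  if (noise_sd_fraction < 0) abort("noise_sd_fraction must be >= 0")
  structure(
    list(
      conformation = conformation,
      residue_range = as.integer(residue_range),
      segments = segments,
      noise_sd_fraction = noise_sd_fraction,
      n_replicates = as.integer(n_replicates),
      low_control_residues = as.integer(low_control_residues),
      seed = as.integer(seed)
    ),
    class = "accessibility_spec"
  )
}

segment_class <- function(label) {
  if (grepl("^exposed", label)) return("exposed")
  if (grepl("^interface", label)) return("interface")
  if (grepl("^embedded", label)) return("embedded")
  abort(paste0("segment label '", label, "' must start with exposed/interface/embedded"))
}

# True relative accessibility (%) per residue under a spec's segment plan.
true_accessibility <- function(spec) {
  residues <- seq(spec$residue_range[1], spec$residue_range[2])
  acc <- numeric(length(residues))
  for (lab in names(spec$segments)) {
    iv <- spec$segments[[lab]]
    idx <- residues >= iv[1] & residues <= iv[2]
    cls <- segment_class(lab)
    base <- switch(cls, exposed = 100, interface = 50, embedded = 5)
    vals <- rep(base, sum(idx))
    if (cls == "embedded" && spec$conformation == "open_shallow") {
      # one helix face periodically lifts toward solvent: 3.6 residues/turn
      pos <- residues[idx] - iv[1]
      vals <- 35 + 25 * sin(2 * pi * pos / 3.6)
    }
    acc[idx] <- vals
  }
  tibble(
    residue_index = as.integer(residues),
    wt_aa = wt_aa_for(residues),
    true_accessibility_pct = pmin(pmax(acc, 0), 100)
  )
}

#' Generate a synthetic per-residue PEGylation gel-band table
#'
#' Emulates the scanning single-cysteine solvent-accessibility assay: for each
#' residue and replicate, three lanes are produced (`no_mPEG` negative
#' control, `mPEG` native labelling, `detergent_mPEG` positive control after
#' membrane solubilisation), each resolved into unshifted (`PEG0`) and
#' singly-shifted (`PEG1`) band intensities. The native labelled fraction is
#' the detergent-lane fraction scaled by the residue's true accessibility, so
#' the relative PEGylation recovered downstream equals the ground truth at
#' zero noise. Noise is multiplicative log-normal (densitometry noise scales
#' with band intensity). Each residue draws from its own seed sub-stream, so
#' extending the residue window does not reshuffle other residues.
#'
#' @param spec an [accessibility_spec()].
#' @param detergent_fraction labelled fraction achieved in the positive
#'   control lane (default 0.9); residues in `spec$low_control_residues` get
#'   0.05 instead.
#' @param total_intensity total lane intensity in arbitrary densitometry units.
#' @return tibble with columns `residue_index`, `wt_aa`, `lane`, `band`,
#'   `intensity`, `replicate_id`; ground truth attached as attribute
#'   `ground_truth`.
#' @export
gen_accessibility_profile <- function(spec, detergent_fraction = 0.9,
                                      total_intensity = 100) {
  if (!inherits(spec, "accessibility_spec")) {
    abort("spec must be an accessibility_spec (unknown conformation labels are rejected there)")
  }
  truth <- true_accessibility(spec)
  sdlog <- spec$noise_sd_fraction

  one_residue <- function(res, acc) {
    f_det <- if (res %in% spec$low_control_residues) 0.05 else detergent_fraction
    f_nat <- f_det * acc / 100
    lanes <- crossing(
      replicate_id = seq_len(spec$n_replicates),
      lane = c("no_mPEG", "mPEG", "detergent_mPEG"),
      band = c("PEG0", "PEG1")
    )
    frac <- dplyr::case_when(
      lanes$lane == "no_mPEG" ~ ifelse(lanes$band == "PEG0", 1, 0),
      lanes$lane == "mPEG" ~ ifelse(lanes$band == "PEG0", 1 - f_nat, f_nat),
      TRUE ~ ifelse(lanes$band == "PEG0", 1 - f_det, f_det)
    )
    intensity <- total_intensity * frac
    if (sdlog > 0) {
      intensity <- with_seed(
        substream_seed(spec$seed, res),
        intensity * exp(rnorm(length(intensity), 0, sdlog))
      )
    }
    tibble(
      residue_index = as.integer(res),
      wt_aa = wt_aa_for(res),
      lane = lanes$lane, band = lanes$band,
      intensity = intensity, replicate_id = lanes$replicate_id
    )
  }

  out <- purrr::map2(truth$residue_index, truth$true_accessibility_pct, one_residue)
  out <- dplyr::bind_rows(out)
  n_pos <- nrow(truth)
  attr(out, "ground_truth") <- list(
    conformation = spec$conformation,
    segments = spec$segments,
    true_accessibility = truth,
    low_control_residues = spec$low_control_residues,
    note = if (n_pos == 49L) {
      "residue window holds 49 positions; the emulated mutant library is described as 48 -- all 49 are generated"
    } else {
      NULL
    },
    seed = spec$seed
  )
  out
}

#' Generate synthetic crosslinking/PEGylation lane intensities
#'
#' Emulates the combined intramolecular-crosslinking + PEGylation readout for
#' a double-cysteine construct. In the solvent-control (DMSO) lane every
#' molecule carries two labellable cysteines, each labelled independently with
#' probability `label_efficiency`, giving a binomial 0/1/2-PEG band pattern.
#' In the crosslinker (BMH) lane a fraction `true_crosslinked_fraction` of
#' molecules is intramolecularly crosslinked and therefore rendered fully
#' non-PEGylatable (all of it lands in the 0-PEG band); the remainder labels
#' as in the control lane.
#'
#' @param true_crosslinked_fraction named numeric vector in `[0,1]`, one entry
#'   per membrane context (e.g. `c(bilayer = 0.9, monolayer = 0.45)`).
#' @param label_efficiency per-site labelling probability after
#'   solubilisation (default 0.8).
#' @param noise_sd_fraction multiplicative log-normal noise sd fraction.
#' @param seed integer seed.
#' @param total_intensity total lane intensity, arbitrary units.
#' @return tibble with columns `context`, `lane` (`DMSO`/`BMH`), `band`
#'   (`PEG0`/`PEG1`/`PEG2`), `intensity`.
#' @export
gen_crosslink_lanes <- function(true_crosslinked_fraction = c(bilayer = 0.9, monolayer = 0.45),
                                label_efficiency = 0.8,
                                noise_sd_fraction = 0,
                                seed = 1L,
                                total_intensity = 100) {
  x <- true_crosslinked_fraction
  if (any(x < 0 | x > 1)) abort("true_crosslinked_fraction must lie in [0, 1]")
  if (is.null(names(x))) names(x) <- paste0("context", seq_along(x))
  p <- label_efficiency
  dmso <- c(PEG0 = (1 - p)^2, PEG1 = 2 * p * (1 - p), PEG2 = p^2)

  rows <- imap(as.list(x), function(xc, ctx) {
    bmh <- xc * c(PEG0 = 1, PEG1 = 0, PEG2 = 0) + (1 - xc) * dmso
    tibble(
      context = ctx,
      lane = rep(c("DMSO", "BMH"), each = 3),
      band = rep(names(dmso), 2),
      intensity = unname(total_intensity * c(dmso, bmh))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (noise_sd_fraction > 0) {
    out$intensity <- with_seed(
      substream_seed(seed, 17L),
      out$intensity * exp(rnorm(nrow(out), 0, noise_sd_fraction))
    )
  }
  attr(out, "ground_truth") <- list(
    true_crosslinked_fraction = x,
    label_efficiency = p, seed = seed
  )
  out
}
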