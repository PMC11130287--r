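#' Fraction of a lane's protein carrying at least one label
#'
#' Lane-level normalisation of the gel shift assay: the PEGylated fraction
#' is `(PEG1 + PEG2) / (PEG0 + PEG1 + PEG2)`.
#'
#' @param peg0,peg1,peg2 band intensities (vectorised; `peg2` defaults to 0).
#' @param lane optional lane label used in error messages.
#' @return fraction in `[0, 1]`.
#' @export
pegylated_fraction <- function(peg0, peg1, peg2 = 0, lane = "lane") {
  if (any(c(peg0, peg1, peg2) < 0)) abort("band intensities must be >= 0")
  total <- peg0 + peg1 + peg2
  if (any(total <= 0)) {
    abort(paste0("all-zero band intensities in ", lane))
  }
  (peg1 + peg2) / total
}

#' Relative PEGylation efficiency of a residue
#'
#' Native-lane labelled fraction as a percentage of the detergent
#' positive-control fraction (the maximum achievable labelling, set to
#' 100 %), clipped to `[0, 100]`. A detergent fraction at or below
#' `control_floor` means the positive control failed (the label cannot reach
#' the cysteine even after solubilisation); the value is withheld and the
#' residue flagged `low_positive_control`.
#'
#' @param native_fraction labelled fraction in the native membrane lane.
#' @param detergent_fraction labelled fraction in the detergent lane.
#' @param control_floor positive-control floor on the detergent fraction
#'   (default 0.2).
#' @return tibble with `relative_pegylation_pct` (NA when withheld) and
#'   `reliability_flag` (`"ok"` / `"low_positive_control"`).
#' @export
relative_pegylation <- function(native_fraction, detergent_fraction,
                                control_floor = 0.2) {
  n <- max(length(native_fraction), length(detergent_fraction))
  native_fraction <- rep_len(native_fraction, n)
  detergent_fraction <- rep_len(detergent_fraction, n)
  low <- detergent_fraction <= control_floor
  pct <- ifelse(low, NA_real_,
                pmin(pmax(100 * native_fraction / detergent_fraction, 0), 100))
  tibble(
    relative_pegylation_pct = pct,
    reliability_flag = ifelse(low, "low_positive_control", "ok")
  )
}

#' Mean, sample SD and count of replicate values
#'
#' @param values numeric vector of per-replicate values (NA dropped).
#' @return one-row tibble with `mean`, `sd` (NA for a single replicate),
#'   `n`.
#' @export
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) {
    return(tibble(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  tibble(
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else NA_real_,
    n = length(values)
  )
}

#' Per-residue relative PEGylation profile from gel-band records
#'
#' Runs the full lane-level quantification: per residue and replicate, the
#' PEGylated fractions of the native (`mPEG`) and positive-control
#' (`detergent_mPEG`) lanes are formed, the relative PEGylation percentage is
#' computed, and replicates are aggregated.
#'
#' @param records tibble in the accessibility schema (`residue_index`,
#'   `wt_aa`, `lane`, `band`, `intensity`, `replicate_id`); `PEG1`/`PEG2`
#'   rows absent for a lane are treated as zero intensity.
#' @param control_floor passed to [relative_pegylation()].
#' @return tibble with one row per residue: `residue_index`, `wt_aa`,
#'   `relative_pegylation_pct`, `sd`, `n_replicates`, `reliability_flag`.
#' @export
pegylation_profile <- function(records, control_floor = 0.2) {
  need <- c("residue_index", "lane", "band", "intensity", "replicate_id")
  if (!all(need %in% names(records))) {
    abort(paste("records needs columns", paste(need, collapse = ", ")))
  }
  if (any(records$intensity < 0)) abort("intensities must be >= 0")
  wide <- records |>
    filter(.data$lane %in% c("mPEG", "detergent_mPEG")) |>
    group_by(.data$residue_index, .data$replicate_id, .data$lane, .data$band) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    pivot_wider(names_from = "band", values_from = "intensity", values_fill = 0)
  for (b in c("PEG1", "PEG2")) if (!b %in% names(wide)) wide[[b]] <- 0

  per_rep <- wide |>
    mutate(fraction = pegylated_fraction(.data$PEG0, .data$PEG1, .data$PEG2,
                                         lane = paste(.data$lane, "lane"))) |>
    select("residue_index", "replicate_id", "lane", "fraction") |>
    pivot_wider(names_from = "lane", values_from = "fraction")
  rel <- relative_pegylation(per_rep$mPEG, per_rep$detergent_mPEG,
                             control_floor = control_floor)
  per_rep <- bind_cols(per_rep, rel)

  aa <- records |> distinct(.data$residue_index, .data$wt_aa)
  per_rep |>
    group_by(.data$residue_index) |>
    summarise(
      stats = aggregate_replicates(.data$relative_pegylation_pct),
      reliability_flag = if (any(.data$reliability_flag == "low_positive_control")) {
        "low_positive_control"
      } else {
        "ok"
      },
      .groups = "drop"
    ) |>
    tidyr::unpack("stats") |>
    rename(relative_pegylation_pct = "mean", n_replicates = "n") |>
    left_join(aa, by = "residue_index") |>
    select("residue_index", "wt_aa", "relative_pegylation_pct", "sd",
           "n_replicates", "reliability_flag") |>
    arrange(.data$residue_index)
}

#' Classify residues as exposed / interface / embedded and call the
#' embedded segment
#'
#' Labels each residue by its mean relative PEGylation: `exposed` at or
#' above `exposed_min`, `embedded` at or below `embedded_max`, `interface`
#' in between. Residues whose positive control failed
#' (`low_positive_control`) inherit the label of their flanking reliable
#' residues when both flanks agree (bridging, on by default), otherwise they
#' are called `interface`. The embedded segment is the longest contiguous
#' run labelled `embedded`; bridged residues count as embedded, interface
#' residues always break a run.
#'
#' @param profile a [pegylation_profile()] result (columns `residue_index`,
#'   `relative_pegylation_pct`, `reliability_flag`; `wt_aa`, `sd`,
#'   `n_replicates` carried through if present).
#' @param exposed_min,embedded_max classification thresholds in percent
#'   (defaults 75 and 25; must satisfy `0 <= embedded_max < exposed_min <=
#'   100`).
#' @param bridge logical; bridge unreliable residues between agreeing
#'   flanks (default TRUE).
#' @return tibble of class `topology_map` with a `label` column; attributes
#'   `embedded_segment` (`c(start, end)` or NULL) and `embedded_length`.
#' @export
classify_topology <- function(profile, exposed_min = 75, embedded_max = 25,
                              bridge = TRUE) {
  if (nrow(profile) == 0) abort("empty accessibility map")
  if (!(embedded_max >= 0 && embedded_max < exposed_min && exposed_min <= 100)) {
    abort("thresholds must satisfy 0 <= embedded_max < exposed_min <= 100")
  }
  out <- profile |> arrange(.data$residue_index)
  base_label <- function(x) {
    ifelse(is.na(x), NA_character_,
      ifelse(x >= exposed_min, "exposed",
        ifelse(x <= embedded_max, "embedded", "interface")
      )
    )
  }
  lab <- base_label(out$relative_pegylation_pct)
  unreliable <- out$reliability_flag == "low_positive_control" | is.na(lab)
  reliable_idx <- which(!unreliable)
  for (i in which(unreliable)) {
    if (!bridge) { lab[i] <- "interface"; next }
    left <- reliable_idx[reliable_idx < i]
    right <- reliable_idx[reliable_idx > i]
    if (length(left) > 0 && length(right) > 0 &&
        lab[max(left)] == lab[min(right)]) {
      lab[i] <- lab[max(left)]
    } else {
      lab[i] <- "interface"
    }
  }
  out$label <- lab

  runs <- rle(lab == "embedded")
  seg <- NULL
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    emb <- which(runs$values)
    best <- emb[which.max(runs$lengths[emb])]
    seg <- as.integer(c(out$residue_index[starts[best]],
                        out$residue_index[ends[best]]))
  }
  structure(out,
    class = c("topology_map", class(out)),
    embedded_segment = seg,
    embedded_length = if (is.null(seg)) 0L else as.integer(seg[2] - seg[1] + 1L),
    thresholds = c(exposed_min = exposed_min, embedded_max = embedded_max),
    bridge = bridge
  )
}

#' @export
print.topology_map <- function(x, ...) {
  seg <- attr(x, "embedded_segment")
  cat(sprintf("<topology_map> %d residues (%d-%d)\n",
              nrow(x), min(x$residue_index), max(x$residue_index)))
  cat("  labels:", paste(names(table(x$label)), table(x$label), collapse = ", "), "\n")
  if (is.null(seg)) {
    cat("  no embedded segment called\n")
  } else {
    cat(sprintf("  embedded segment: %d-%d (%d residues)\n",
                seg[1], seg[2], attr(x, "embedded_length")))
  }
  invisible(x)
}

#' Dominant helical periodicity of an accessibility sub-profile
#'
#' Mean-subtracted discrete Fourier transform of a profile segment; the
#' dominant period is the reciprocal of the frequency with maximal spectral
#' power over periods in `[2, n/2]` residues, and `relative_power` is that
#' peak's share of the total non-DC power. An alpha-helical face exposed
#' every turn shows up as a dominant period near 3.6 residues.
#'
#' @param values numeric accessibility values of the segment, in residue
#'   order (length >= 8).
#' @return one-row tibble with `dominant_period` (residues; NA for a
#'   constant profile) and `relative_power` (0 for a constant profile).
#' @export
periodicity_score <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 8) abort("segment too short for periodicity analysis (need >= 8)")
  centred <- values - mean(values)
  spec <- Mod(fft(centred))^2
  k <- seq_len(floor(n / 2))
  power <- spec[k + 1]
  total <- sum(power)
  if (total <= .Machine$double.eps * n) {
    return(tibble(dominant_period = NA_real_, relative_power = 0))
  }
  period <- n / k
  valid <- period >= 2 & period <= n / 2
  kv <- k[valid]
  pv <- power[valid]
  best <- which.max(pv)
  tibble(
    dominant_period = n / kv[best],
    relative_power = pv[best] / total
  )
}

#' Quantify intramolecular crosslinking efficiency across membrane contexts
#'
#' Per context, the 0-PEG band under crosslinker is expressed relative to
#' the solvent (DMSO) control (control = 100 %); the relative increase is
#' that value minus 100, floored at 0 (an unchanged band scores 0). Across
#' contexts the increases are normalised so the maximum is 100 % (all-zero
#' increases stay 0).
#'
#' @param lanes tibble with columns `context`, `lane`, `band`, `intensity`.
#' @param control_lane,crosslinker_lane lane labels (defaults `"DMSO"`,
#'   `"BMH"`).
#' @return tibble of class `crosslink_quant` with `context`,
#'   `relative_peg0_pct`, `increase_pct`, `normalized_pct`.
#' @export
crosslink_efficiency <- function(lanes, control_lane = "DMSO",
                                 crosslinker_lane = "BMH") {
  need <- c("context", "lane", "band", "intensity")
  if (!all(need %in% names(lanes))) {
    abort(paste("lanes needs columns", paste(need, collapse = ", ")))
  }
  peg0 <- lanes |>
    filter(.data$band == "PEG0",
           .data$lane %in% c(control_lane, crosslinker_lane)) |>
    group_by(.data$context, .data$lane) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    pivot_wider(names_from = "lane", values_from = "intensity")
  if (!all(c(control_lane, crosslinker_lane) %in% names(peg0)) ||
      anyNA(peg0[[control_lane]]) || anyNA(peg0[[crosslinker_lane]])) {
    abort("both control and crosslinker lanes must be present for every context")
  }
  if (any(peg0[[control_lane]] <= 0)) {
    abort("zero control-lane PEG0 band; cannot normalise")
  }
  out <- peg0 |>
    mutate(
      relative_peg0_pct = 100 * .data[[crosslinker_lane]] / .data[[control_lane]],
      increase_pct = pmax(.data$relative_peg0_pct - 100, 0)
    )
  max_inc <- max(out$increase_pct)
  out$normalized_pct <- if (max_inc > 0) 100 * out$increase_pct / max_inc else 0
  out <- out |> select("context", "relative_peg0_pct", "increase_pct", "normalized_pct")
  structure(out, class = c("crosslink_quant", class(out)))
}
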