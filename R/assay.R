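#' Percent-of-controls normalization
#'
#' Linear rescaling of a signal between a negative control (0%) and a
#' full control (100%):
#' `100 * (sample - negative) / (full - negative)`.
#' This is the LDH cell-lysis formula (full control = 100% lysis) and,
#' identically, the propidium-iodide uptake formula (full control =
#' 100% permeable, Triton X-100). Values outside \[0, 100\] are reported
#' unclamped and flagged.
#'
#' @param sample Sample signal(s); vectorized.
#' @param negative_control Negative-control signal.
#' @param full_control Full (100%) control signal; must differ from the
#'   negative control.
#'
#' @return A tibble with `percent` and logical `out_of_range`.
#' @export
#' @examples
#' percent_of_controls(55, 10, 100)  # 50%
percent_of_controls <- function(sample, negative_control, full_control) {
  if (!is.finite(full_control) || !is.finite(negative_control) ||
      full_control == negative_control) {
    stop("full and negative controls must be finite and distinct", call. = FALSE)
  }
  pct <- 100 * (sample - negative_control) / (full_control - negative_control)
  tibble::tibble(percent = pct, out_of_range = pct < 0 | pct > 100)
}

#' Percent-of-controls for a tidy plate table
#'
#' Applies [percent_of_controls()] to a plate-reader table with one row
#' per well and a `role` column marking `"sample"`, `"negative"` and
#' `"full"` wells; control values are averaged across their wells.
#'
#' @param plate Data frame with columns `value`, `role` and any
#'   identifier columns (kept in the output).
#' @return The sample rows with `percent` and `out_of_range` appended.
#' @export
plate_percent <- function(plate) {
  plate <- tibble::as_tibble(plate)
  stopifnot(all(c("value", "role") %in% names(plate)))
  neg <- mean(plate$value[plate$role == "negative"])
  full <- mean(plate$value[plate$role == "full"])
  out <- plate[plate$role == "sample", ]
  dplyr::bind_cols(out, percent_of_controls(out$value, neg, full))
}

# Plateau of a phase: median of the final `tail_frac` of its samples (by
# time order).
#' @noRd
phase_plateau <- function(time, signal, tail_frac = 0.2) {
  ord <- order(time)
  signal <- signal[ord]
  n <- length(signal)
  k <- max(1L, ceiling(tail_frac * n))
  stats::median(signal[(n - k + 1L):n])
}

#' Dithionite-quench permeability of proteoliposomes
#'
#' Quantifies membrane permeability from a three-phase fluorescence
#' trace of NBD-labelled proteoliposomes: a baseline, a phase after
#' adding dithionite (which quenches NBD only on solvent-accessible
#' leaflets) and a phase after adding Triton X-100 (full disruption).
#' The permeability is
#' `100 - 200 * (F_dit - F_triton) / (F_initial - F_triton)`,
#' where the three levels are plateau estimates of the respective
#' phases (median of the final 20% of each phase). A sealed liposome
#' (only the outer leaflet quenched, F_dit at the midpoint) gives 0%;
#' full quenching gives 100%.
#'
#' @param trace Data frame with columns `time` (s, strictly
#'   increasing), `signal` and `phase` (values `"baseline"`,
#'   `"post_dithionite"`, `"post_triton"`).
#' @param tail_frac Fraction of each phase used for the plateau
#'   estimate (default 0.2).
#'
#' @return A one-row tibble with `f_initial`, `f_dit`, `f_triton` and
#'   `permeability` (percent).
#' @export
liposome_permeability <- function(trace, tail_frac = 0.2) {
  trace <- tibble::as_tibble(trace)
  stopifnot(all(c("time", "signal", "phase") %in% names(trace)))
  if (any(diff(trace$time) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  needed <- c("baseline", "post_dithionite", "post_triton")
  missing_ph <- setdiff(needed, unique(trace$phase))
  if (length(missing_ph) > 0) {
    stop("trace lacks phase(s): ", paste(missing_ph, collapse = ", "),
         call. = FALSE)
  }
  lvl <- vapply(needed, function(ph) {
    sel <- trace$phase == ph
    phase_plateau(trace$time[sel], trace$signal[sel], tail_frac)
  }, numeric(1))
  f_initial <- unname(lvl[1]); f_dit <- unname(lvl[2]); f_triton <- unname(lvl[3])
  if (f_initial == f_triton) {
    stop("F_initial equals F_triton: permeability undefined", call. = FALSE)
  }
  tibble::tibble(f_initial = f_initial, f_dit = f_dit, f_triton = f_triton,
                 permeability = 100 - 200 * (f_dit - f_triton) / (f_initial - f_triton))
}

#' Percent dye release from liposomes
#'
#' Endpoint dequenching readout of dye-filled liposomes, normalized to
#' the emission after Triton X-100 addition (complete release):
#' `100 * (sample - diluent) / (triton - diluent)`.
#'
#' @param sample_signal Endpoint fluorescence of the sample(s);
#'   vectorized.
#' @param diluent_signal Fluorescence of the diluent-only control.
#' @param triton_signal Fluorescence after Triton X-100 (must exceed
#'   the diluent signal).
#'
#' @return A tibble with `percent` and `out_of_range`.
#' @export
dye_release_percent <- function(sample_signal, diluent_signal, triton_signal) {
  if (!is.finite(triton_signal) || !is.finite(diluent_signal) ||
      triton_signal == diluent_signal) {
    stop("triton and diluent signals must be finite and distinct", call. = FALSE)
  }
  pct <- 100 * (sample_signal - diluent_signal) / (triton_signal - diluent_signal)
  tibble::tibble(percent = pct, out_of_range = pct < 0 | pct > 100)
}

#' DRAQ7 normalization and lysis-onset detection
#'
#' Normalizes a nuclear DRAQ7 fluorescence trace to its initial value,
#' `(F_t - F_i) / F_i`, and defines the onset of plasma-membrane
#' permeabilization (time 0) as the first time point where the
#' normalized value strictly exceeds 1. When an onset is found, times
#' are re-expressed relative to it.
#'
#' @param trace Data frame with columns `time` (s, strictly increasing)
#'   and `signal`; the first signal value is `F_i` and must be non-zero.
#'
#' @return The trace tibble with `normalized` and (when an onset
#'   exists) `time_rel` columns; attribute `onset` is the onset time or
#'   `NA`.
#' @export
#' @examples
#' tr <- data.frame(time = 0:5 * 60, signal = c(100, 100, 120, 201, 320, 400))
#' attr(draq7_normalize_and_onset(tr), "onset")
draq7_normalize_and_onset <- function(trace) {
  trace <- tibble::as_tibble(trace)
  stopifnot(all(c("time", "signal") %in% names(trace)))
  if (any(diff(trace$time) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  f_i <- trace$signal[1]
  if (f_i == 0) stop("initial fluorescence F_i must be non-zero", call. = FALSE)
  trace$normalized <- (trace$signal - f_i) / f_i
  hit <- which(trace$normalized > 1)
  onset <- if (length(hit) > 0) trace$time[hit[1]] else NA_real_
  if (!is.na(onset)) trace$time_rel <- trace$time - onset
  attr(trace, "onset") <- onset
  trace
}

#' Baseline an inhomogeneity time series
#'
#' Normalizes a distribution-inhomogeneity series (e.g. the spatial
#' inhomogeneity of membrane protein fluorescence over time) to its
#' initial value by subtraction: `D_t - D_i`, so the first value is
#' exactly 0.
#'
#' @param series Data frame with columns `time` and `d` (inhomogeneity
#'   values, first row = initial time point).
#'
#' @return The tibble with a `d_normalized` column.
#' @export
inhomogeneity_normalize <- function(series) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("time", "d") %in% names(series)))
  if (nrow(series) == 0) stop("series must be non-empty", call. = FALSE)
  series$d_normalized <- series$d - series$d[1]
  series
}
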