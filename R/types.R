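## Domain containers. Each constructor validates the stated invariants and
## fails with a message naming the violated rule, so that readers and
## simulators share one set of checks.

#' Single fluorescence emission spectrum at one condition
#'
#' @param wavelengths emission wavelength grid, nm; strictly increasing,
#'   at least 3 points.
#' @param intensities fluorescence intensities, arbitrary units; finite.
#' @param condition_value temperature (K) or denaturant concentration (mol/L).
#' @param condition_kind `"thermal"` or `"chemical"`.
#' @param replicate_id replicate label.
#' @return object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, condition_value,
                              condition_kind = c("thermal", "chemical"),
                              replicate_id = "r1") {
  condition_kind <- match.arg(condition_kind)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("emission_spectrum: wavelengths and intensities must have equal length")
  if (length(wavelengths) < 3L)
    stop("emission_spectrum: at least 3 wavelength points are required")
  if (any(!is.finite(wavelengths)))
    stop("emission_spectrum: wavelengths must be finite")
  if (any(diff(wavelengths) <= 0))
    stop("emission_spectrum: wavelength grid must be strictly increasing")
  if (any(!is.finite(intensities)))
    stop("emission_spectrum: intensities must be finite")
  if (!is.finite(condition_value))
    stop("emission_spectrum: condition_value must be finite")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         condition_value = condition_value, condition_kind = condition_kind,
         replicate_id = as.character(replicate_id)),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "emission_spectrum: %d points, %.0f-%.0f nm, %s = %g, replicate %s\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    if (x$condition_kind == "thermal") "T/K" else "[den]/M",
    x$condition_value, x$replicate_id))
  invisible(x)
}

#' Relaxation decay curve for one residue
#'
#' @param residue_id residue label (number or string).
#' @param delays relaxation delays in seconds; strictly increasing,
#'   non-negative.
#' @param intensities peak heights, arbitrary units.
#' @param experiment `"T1"` or `"T2"`.
#' @return object of class `decay_curve`.
#' @export
decay_curve <- function(residue_id, delays, intensities,
                        experiment = c("T1", "T2")) {
  experiment <- match.arg(experiment)
  delays <- as.numeric(delays)
  intensities <- as.numeric(intensities)
  if (length(delays) != length(intensities))
    stop("decay_curve: delays and intensities must have equal length")
  if (any(!is.finite(delays)) || any(delays < 0))
    stop("decay_curve: delays must be finite and non-negative")
  if (any(diff(delays) <= 0))
    stop("decay_curve: delays must be strictly increasing")
  if (any(!is.finite(intensities)))
    stop("decay_curve: intensities must be finite")
  structure(
    list(residue_id = as.character(residue_id), delays = delays,
         intensities = intensities, experiment = experiment),
    class = "decay_curve"
  )
}

#' Saturated/unsaturated intensity pair for the heteronuclear NOE
#'
#' @param residue_id residue label.
#' @param i_sat peak intensity with 1H saturation.
#' @param i_eq peak intensity without saturation; must be nonzero.
#' @param replicate_id replicate label.
#' @return object of class `noe_pair`.
#' @export
noe_pair <- function(residue_id, i_sat, i_eq, replicate_id = "r1") {
  if (!is.finite(i_sat) || !is.finite(i_eq))
    stop("noe_pair: intensities must be finite")
  if (i_eq == 0)
    stop("noe_pair: i_eq must be nonzero")
  structure(
    list(residue_id = as.character(residue_id), i_sat = i_sat, i_eq = i_eq,
         replicate_id = as.character(replicate_id)),
    class = "noe_pair"
  )
}

#' Differential scanning calorimetry trace
#'
#' @param temperatures temperature axis in K; strictly increasing, at least
#'   20 points.
#' @param heat_capacity heat capacity, kJ K^-1 mol^-1.
#' @param scan_label `"first_heat"` or `"reheat"`.
#' @param scan_rate scan rate in K/min; positive (instrument default 1).
#' @return object of class `dsc_trace`.
#' @export
dsc_trace <- function(temperatures, heat_capacity,
                      scan_label = c("first_heat", "reheat"), scan_rate = 1) {
  scan_label <- match.arg(scan_label)
  temperatures <- as.numeric(temperatures)
  heat_capacity <- as.numeric(heat_capacity)
  if (length(temperatures) != length(heat_capacity))
    stop("dsc_trace: temperatures and heat_capacity must have equal length")
  if (length(temperatures) < 20L)
    stop("dsc_trace: at least 20 points are required")
  if (any(!is.finite(temperatures)) || any(!is.finite(heat_capacity)))
    stop("dsc_trace: values must be finite")
  if (any(diff(temperatures) <= 0))
    stop("dsc_trace: temperature axis must be strictly increasing (monotonicity rule)")
  if (!is.finite(scan_rate) || scan_rate <= 0)
    stop("dsc_trace: scan_rate must be positive")
  structure(
    list(temperatures = temperatures, heat_capacity = heat_capacity,
         scan_label = scan_label, scan_rate = scan_rate),
    class = "dsc_trace"
  )
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("dsc_trace (%s): %d points, %.1f-%.1f K, scan rate %g K/min\n",
              x$scan_label, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), x$scan_rate))
  invisible(x)
}

#' Assigned 2D 1H-15N peak list
#'
#' @param residue_id residue labels, unique within the list.
#' @param h_ppm 1H chemical shifts, ppm.
#' @param n_ppm 15N chemical shifts, ppm.
#' @param intensity peak heights (optional, default NA).
#' @return data.frame of class `peak_list`.
#' @export
peak_list <- function(residue_id, h_ppm, n_ppm, intensity = NA_real_) {
  residue_id <- as.character(residue_id)
  if (anyDuplicated(residue_id))
    stop("peak_list: residue_id must be unique within a list")
  if (any(!is.finite(h_ppm)) || any(!is.finite(n_ppm)))
    stop("peak_list: chemical shifts must be finite")
  out <- data.frame(residue_id = residue_id, h_ppm = as.numeric(h_ppm),
                    n_ppm = as.numeric(n_ppm),
                    intensity = as.numeric(intensity),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_list", "data.frame")
  out
}

# long-format melt series: one row per (replicate, condition, wavelength)
as_melt_series <- function(df, condition_kind = "thermal") {
  need <- c("replicate", "condition", "wavelength", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("melt series is missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$replicate, df$condition, df$wavelength), need, drop = FALSE]
  rownames(df) <- NULL
  # validate every (replicate, condition) group as a spectrum
  for (key in split(seq_len(nrow(df)), paste(df$replicate, df$condition))) {
    emission_spectrum(df$wavelength[key], df$intensity[key],
                      condition_value = df$condition[key][1],
                      condition_kind = condition_kind,
                      replicate_id = df$replicate[key][1])
  }
  structure(df, class = c("melt_series", "data.frame"),
            condition_kind = condition_kind)
}

# split a melt_series into emission_spectrum objects
split_spectra <- function(series) {
  kind <- attr(series, "condition_kind") %||% "thermal"
  keys <- split(seq_len(nrow(series)), paste(series$replicate, series$condition))
  lapply(unname(keys), function(i) {
    emission_spectrum(series$wavelength[i], series$intensity[i],
                      condition_value = series$condition[i][1],
                      condition_kind = kind,
                      replicate_id = series$replicate[i][1])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
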