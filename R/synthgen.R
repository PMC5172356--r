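## Synthetic-data generators. Each simulator consumes a validated parameter
## object, seeds R's RNG (Mersenne-Twister) from `seed`, and emits exactly
## the data structures the corresponding analysis stage reads, alongside the
## generating ground truth where applicable. Fixed seed => bit-identical
## output.

R_GAS <- 8.31446261815324e-3  # kJ mol^-1 K^-1

#' Parameters for the two-state melting-spectra simulator
#'
#' @param t_half_true true transition midpoint: K (thermal) or mol/L
#'   (chemical mode).
#' @param rate_true sigmoid slope parameter in condition units (default 2 K).
#'   Ignored when `delta_h_vh` is given, in which case
#'   `rate = R T_half^2 / delta_h_vh` (the van't Hoff mapping).
#' @param delta_h_vh optional van't Hoff enthalpy, kJ/mol.
#' @param native_band_center,denatured_band_center Gaussian emission band
#'   centers, nm; the denatured band must lie red of the native one.
#' @param band_width common Gaussian band SD, nm.
#' @param baseline_slopes length-2 numeric: linear drift of the native and
#'   denatured band centers per condition unit (nm/K or nm/M).
#' @param noise_sd additive Gaussian noise SD as a fraction of the peak
#'   intensity (default 0.03).
#' @param n_replicates number of independent replicates (default 3).
#' @param condition_grid condition values, K or mol/L.
#' @param wavelength_grid emission wavelength grid, nm (default 310-400 nm,
#'   1 nm steps).
#' @param condition_kind `"thermal"` or `"chemical"`.
#' @param seed integer RNG seed.
#' @return validated list of class `melt_sim_params`.
#' @export
melt_sim_params <- function(t_half_true, rate_true = 2, delta_h_vh = NULL,
                            native_band_center = 340,
                            denatured_band_center = 355,
                            band_width = 12,
                            baseline_slopes = c(0, 0),
                            noise_sd = 0.03, n_replicates = 3,
                            condition_grid = seq(300, 360, by = 2),
                            wavelength_grid = seq(310, 400, by = 1),
                            condition_kind = c("thermal", "chemical"),
                            seed = 1L) {
  condition_kind <- match.arg(condition_kind)
  if (denatured_band_center <= native_band_center)
    stop("denatured_band_center must exceed native_band_center (red shift on unfolding)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  if (band_width <= 0) stop("band_width must be positive")
  if (!is.null(delta_h_vh)) {
    if (delta_h_vh <= 0) stop("delta_h_vh must be positive")
    rate_true <- R_GAS * t_half_true^2 / delta_h_vh
  }
  structure(list(
    t_half_true = t_half_true, rate_true = rate_true,
    native_band_center = native_band_center,
    denatured_band_center = denatured_band_center,
    band_width = band_width, baseline_slopes = baseline_slopes,
    noise_sd = noise_sd, n_replicates = n_replicates,
    condition_grid = sort(condition_grid),
    wavelength_grid = wavelength_grid,
    condition_kind = condition_kind, seed = as.integer(seed)),
    class = "melt_sim_params")
}

#' Simulate a replicate series of two-state melting spectra
#'
#' At each condition the spectrum is the population-weighted sum of a native
#' and a denatured Gaussian emission band plus additive Gaussian noise:
#' \deqn{F(\lambda) = p_N B(\lambda;\mu_N) + (1-p_N) B(\lambda;\mu_D) +
#'   \epsilon}
#' with the native population following the two-state logistic
#' \eqn{p_N = 1/(1+\exp\{(x - T_{half})/rate\})} in the condition variable.
#' The denatured band sits red of the native band, so the barycentric mean
#' red-shifts through the transition. Replicates differ only in the noise
#' stream. A midpoint outside the condition grid is allowed but warned
#' about (any downstream fit becomes extrapolative).
#'
#' @param params a [melt_sim_params()] object.
#' @return a `melt_series` data.frame (columns `replicate`, `condition`,
#'   `wavelength`, `intensity`) with attribute `truth` = `params`.
#' @export
simulate_melt_series <- function(params) {
  stopifnot(inherits(params, "melt_sim_params"))
  p <- params
  grid <- p$condition_grid
  if (p$t_half_true < min(grid) || p$t_half_true > max(grid))
    warning("true midpoint lies outside the condition grid; fits will be extrapolative")
  set.seed(p$seed)
  lam <- p$wavelength_grid
  peak <- 100
  # bands are normalized to equal integrated intensity on the recorded grid
  # (equal apparent quantum yield), so the barycentric mean is exactly the
  # population-weighted mean of the two band centroids and the sigmoid
  # midpoint coincides with the thermodynamic midpoint
  band <- function(center) {
    b <- exp(-(lam - center)^2 / (2 * p$band_width^2))
    b / sum(b)
  }
  scale <- peak / max(band(p$native_band_center))
  rows <- list()
  for (r in seq_len(p$n_replicates)) {
    for (x in grid) {
      pn <- 1 / (1 + exp((x - p$t_half_true) / p$rate_true))
      mu_n <- p$native_band_center + p$baseline_slopes[1] * (x - grid[1])
      mu_d <- p$denatured_band_center + p$baseline_slopes[2] * (x - grid[1])
      f <- scale * (pn * band(mu_n) + (1 - pn) * band(mu_d))
      if (p$noise_sd > 0)
        f <- f + stats::rnorm(length(lam), sd = p$noise_sd * peak)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = sprintf("rep%d", r), condition = x,
        wavelength = lam, intensity = f, stringsAsFactors = FALSE)
    }
  }
  out <- as_melt_series(do.call(rbind, rows), condition_kind = p$condition_kind)
  attr(out, "truth") <- p
  out
}

#' Per-residue model-free ground truth table
#'
#' @param residue_id residue labels.
#' @param s2 order parameters in `[0, 1]` (recycled).
#' @param tau_m overall rotational correlation time, ns (recycled).
#' @param tau_e internal correlation times, ps (recycled, default 0).
#' @param rex exchange contributions to R2, 1/s (recycled, default 0).
#' @return data.frame of class `model_free_params`.
#' @export
model_free_params <- function(residue_id, s2 = 0.85, tau_m = 8,
                              tau_e = 0, rex = 0) {
  n <- length(residue_id)
  out <- data.frame(residue = as.character(residue_id),
                    s2 = rep_len(s2, n), tau_m = rep_len(tau_m, n),
                    tau_e = rep_len(tau_e, n), rex = rep_len(rex, n),
                    stringsAsFactors = FALSE)
  if (any(out$s2 < 0 | out$s2 > 1)) stop("s2 must lie in [0, 1]")
  if (any(out$tau_m <= 0)) stop("tau_m must be positive")
  if (any(out$tau_e < 0)) stop("tau_e must be non-negative")
  if (any(out$rex < 0)) stop("rex must be non-negative")
  class(out) <- c("model_free_params", "data.frame")
  out
}

#' Parameters for the relaxation-dataset simulator
#'
#' @param residues a [model_free_params()] table.
#' @param field_mhz spectrometer 1H frequency, MHz (default 600.13).
#' @param noise_fraction multiplicative Gaussian noise on intensities,
#'   relative (default 0.02).
#' @param t1_delays,t2_delays relaxation delay grids in seconds; defaults
#'   are the standard grids 10-1000 ms (T1) and 10-150 ms (T2). Each needs
#'   at least 4 points.
#' @param noe_replicates number of independent NOE experiments (default 2,
#'   the duplicate convention whose SD provides the NOE error).
#' @param seed integer RNG seed.
#' @param constants optional [spin_constants()]; built from `field_mhz`
#'   when absent.
#' @return validated list of class `relax_sim_params`.
#' @export
relax_sim_params <- function(residues, field_mhz = 600.13,
                             noise_fraction = 0.02,
                             t1_delays = c(10, 20, 40, 180, 300, 500, 1000) / 1000,
                             t2_delays = c(10, 30, 50, 70, 90, 110, 150) / 1000,
                             noe_replicates = 2, seed = 1L,
                             constants = NULL) {
  stopifnot(inherits(residues, "model_free_params"))
  if (field_mhz <= 0) stop("field_mhz must be positive")
  if (length(t1_delays) < 4L || length(t2_delays) < 4L)
    stop("each delay grid needs at least 4 points")
  if (noise_fraction < 0) stop("noise_fraction must be non-negative")
  if (is.null(constants)) constants <- spin_constants(field_mhz = field_mhz)
  structure(list(residues = residues, field_mhz = field_mhz,
                 noise_fraction = noise_fraction,
                 t1_delays = sort(t1_delays), t2_delays = sort(t2_delays),
                 noe_replicates = as.integer(noe_replicates),
                 seed = as.integer(seed), constants = constants),
            class = "relax_sim_params")
}

#' Simulate a per-residue 15N relaxation dataset
#'
#' For every residue the model-free spectral density (see [model_free_j()])
#' is pushed through the full five-frequency forward relaxation equations
#' ([forward_rates()], including Rex in R2) to obtain the true R1, R2 and
#' NOE. T1 and T2 decay curves are mono-exponentials at those rates sampled
#' on the delay grids with multiplicative Gaussian noise; NOE
#' saturated/unsaturated pairs are generated independently per replicate
#' with the same relative noise.
#'
#' @param params a [relax_sim_params()] object.
#' @return list with `t1_curves`, `t2_curves` (lists of [decay_curve()]),
#'   `noe` (data.frame residue/replicate/i_sat/i_eq) and `truth`
#'   (data.frame with the generating model-free parameters, rates, NOE and
#'   relaxation times per residue).
#' @export
simulate_relaxation_dataset <- function(params) {
  stopifnot(inherits(params, "relax_sim_params"))
  p <- params
  set.seed(p$seed)
  i0 <- 100
  noisy <- function(x) {
    if (p$noise_fraction <= 0) return(x)
    x * (1 + stats::rnorm(length(x), sd = p$noise_fraction))
  }
  t1_curves <- list(); t2_curves <- list(); noe_rows <- list(); truth <- list()
  for (i in seq_len(nrow(p$residues))) {
    rr <- p$residues[i, ]
    j <- function(w) model_free_j(w, rr$s2, rr$tau_m, rr$tau_e)
    rates <- forward_rates(j, p$constants, rex = rr$rex)
    t1_curves[[i]] <- decay_curve(
      rr$residue, p$t1_delays,
      noisy(i0 * exp(-p$t1_delays * rates$r1)), experiment = "T1")
    t2_curves[[i]] <- decay_curve(
      rr$residue, p$t2_delays,
      noisy(i0 * exp(-p$t2_delays * rates$r2)), experiment = "T2")
    for (k in seq_len(p$noe_replicates)) {
      noe_rows[[length(noe_rows) + 1L]] <- data.frame(
        residue = rr$residue, replicate = sprintf("exp%d", k),
        i_sat = noisy(i0 * rates$noe), i_eq = noisy(i0),
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(
      residue = rr$residue, s2 = rr$s2, tau_m = rr$tau_m, tau_e = rr$tau_e,
      rex = rr$rex, r1 = rates$r1, r2 = rates$r2, noe = rates$noe,
      t1 = 1 / rates$r1, t2 = 1 / rates$r2, stringsAsFactors = FALSE)
  }
  list(t1_curves = t1_curves, t2_curves = t2_curves,
       noe = do.call(rbind, noe_rows), truth = do.call(rbind, truth))
}

#' Parameters for the van't Hoff DSC simulator
#'
#' @param components data.frame with one row per transition: `t_m` (K,
#'   inside the temperature grid), `delta_h_vh` (kJ/mol) and `amplitude`
#'   (dimensionless scale).
#' @param baseline polynomial coefficients (intercept first) of the shared
#'   instrumental baseline in the temperature, kJ/K/mol.
#' @param reversibility_fraction per-component fraction (0-1, recycled) of
#'   the excess heat capacity recovered on reheat.
#' @param noise_sd additive Gaussian noise SD, kJ/K/mol (default 0).
#' @param temperature_grid K, strictly increasing.
#' @param scan_rate K/min.
#' @param seed integer RNG seed.
#' @return validated list of class `dsc_sim_params`.
#' @export
dsc_sim_params <- function(components, baseline = 0,
                           reversibility_fraction = 1, noise_sd = 0,
                           temperature_grid = seq(300, 360, by = 0.1),
                           scan_rate = 1, seed = 1L) {
  components <- as.data.frame(components)
  need <- c("t_m", "delta_h_vh", "amplitude")
  miss <- setdiff(need, names(components))
  if (length(miss))
    stop("components is missing column(s): ", paste(miss, collapse = ", "))
  if (any(components$t_m < min(temperature_grid) |
            components$t_m > max(temperature_grid)))
    stop("each t_m must lie inside the temperature grid")
  if (any(components$delta_h_vh <= 0)) stop("delta_h_vh must be positive")
  rev_frac <- rep_len(reversibility_fraction, nrow(components))
  if (any(rev_frac < 0 | rev_frac > 1))
    stop("reversibility_fraction must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(components = components, baseline = baseline,
                 reversibility_fraction = rev_frac, noise_sd = noise_sd,
                 temperature_grid = sort(temperature_grid),
                 scan_rate = scan_rate, seed = as.integer(seed)),
            class = "dsc_sim_params")
}

# two-state van't Hoff excess heat capacity for one component
vant_hoff_cp <- function(tt, t_m, delta_h_vh) {
  k <- exp(-(delta_h_vh / R_GAS) * (1 / tt - 1 / t_m))
  delta_h_vh^2 / (R_GAS * tt^2) * k / (1 + k)^2
}

#' Simulate a DSC first-heat / reheat trace pair
#'
#' Each component contributes a two-state van't Hoff excess heat capacity
#' peak
#' \deqn{C_p^{ex}(T) = \frac{\Delta H_{vH}^2}{R T^2}\frac{K}{(1+K)^2},
#'   \quad K = \exp\left[-\frac{\Delta H_{vH}}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_m}\right)\right]}
#' scaled by its amplitude. The reheat trace multiplies each component by
#' its reversibility fraction - a fraction of 0 reproduces the signature of
#' irreversible unfolding (the endotherm vanishes on reheating). The shared
#' polynomial baseline and additive noise are applied to both scans.
#'
#' @param params a [dsc_sim_params()] object.
#' @return list with `first_heat` and `reheat`, both [dsc_trace()] objects.
#' @export
simulate_dsc_trace <- function(params) {
  stopifnot(inherits(params, "dsc_sim_params"))
  p <- params
  set.seed(p$seed)
  tt <- p$temperature_grid
  base <- rowSums(sapply(seq_along(p$baseline),
                         function(k) p$baseline[k] * tt^(k - 1)))
  cp_first <- base
  cp_reheat <- base
  for (i in seq_len(nrow(p$components))) {
    comp <- p$components$amplitude[i] *
      vant_hoff_cp(tt, p$components$t_m[i], p$components$delta_h_vh[i])
    cp_first <- cp_first + comp
    cp_reheat <- cp_reheat + p$reversibility_fraction[i] * comp
  }
  if (p$noise_sd > 0) {
    cp_first <- cp_first + stats::rnorm(length(tt), sd = p$noise_sd)
    cp_reheat <- cp_reheat + stats::rnorm(length(tt), sd = p$noise_sd)
  }
  list(first_heat = dsc_trace(tt, cp_first, scan_label = "first_heat",
                              scan_rate = p$scan_rate),
       reheat = dsc_trace(tt, cp_reheat, scan_label = "reheat",
                          scan_rate = p$scan_rate))
}
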