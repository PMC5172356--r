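#' Fit a mono-exponential relaxation decay with Monte Carlo errors
#'
#' Fits \eqn{I(t) = I_0 \exp(-t/T_\alpha)} (\eqn{\alpha} = 1 or 2) to peak
#' intensities versus relaxation delay by Levenberg-Marquardt least squares.
#' The uncertainty on \eqn{T_\alpha} is estimated by the Monte Carlo method:
#' `mc_iterations` synthetic datasets are built by perturbing the fitted
#' curve with Gaussian noise whose SD equals the residual RMS of the primary
#' fit, each is refit, and the SD of the refitted \eqn{T_\alpha} values is
#' reported as `mc_error`.
#'
#' Non-convergence or a non-positive fitted time constant never raises an
#' error; the result is flagged `converged = FALSE`.
#'
#' @param curve a [decay_curve()] with at least 4 delay points.
#' @param mc_iterations number of Monte Carlo refits (default 500).
#' @param seed optional RNG seed for the Monte Carlo stage.
#' @return object of class `exp_fit`: list with `residue_id`, `experiment`,
#'   `t_relax` (s), `i0`, `mc_error` (s), `rms`, `converged`.
#' @export
fit_exponential <- function(curve, mc_iterations = 500, seed = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  t <- curve$delays
  y <- curve$intensities
  if (length(t) < 4L)
    stop("fit_exponential: at least 4 delay points are required")
  if (length(unique(y)) == 1L)
    stop("fit_exponential: intensities are constant; nothing to fit")
  failed <- structure(list(residue_id = curve$residue_id,
                           experiment = curve$experiment,
                           t_relax = NA_real_, i0 = NA_real_,
                           mc_error = NA_real_, rms = NA_real_,
                           converged = FALSE), class = "exp_fit")
  fit1 <- function(yy) {
    # log-linear start (guard non-positive intensities)
    pos <- yy > 0
    start <- if (sum(pos) >= 2L) {
      cf <- stats::coef(stats::lm(log(yy[pos]) ~ t[pos]))
      list(i0 = exp(cf[[1]]), t_relax = if (cf[[2]] < 0) -1 / cf[[2]] else max(t))
    } else list(i0 = max(yy), t_relax = stats::median(t))
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ i0 * exp(-t / t_relax), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    stats::coef(fit)
  }
  est <- fit1(y)
  if (is.null(est) || !is.finite(est[["t_relax"]]) || est[["t_relax"]] <= 0)
    return(failed)
  yhat <- est[["i0"]] * exp(-t / est[["t_relax"]])
  rms <- sqrt(mean((y - yhat)^2))
  mc_error <- 0
  if (mc_iterations > 0 && rms > 0) {
    if (!is.null(seed)) set.seed(seed)
    tmc <- vapply(seq_len(mc_iterations), function(i) {
      e <- fit1(yhat + stats::rnorm(length(t), sd = rms))
      if (is.null(e)) NA_real_ else e[["t_relax"]]
    }, 0)
    tmc <- tmc[is.finite(tmc) & tmc > 0]
    mc_error <- if (length(tmc) >= 2L) stats::sd(tmc) else NA_real_
  }
  structure(list(residue_id = curve$residue_id, experiment = curve$experiment,
                 t_relax = est[["t_relax"]], i0 = est[["i0"]],
                 mc_error = mc_error, rms = rms, converged = TRUE),
            class = "exp_fit")
}

#' Steady-state heteronuclear NOE from saturated/unsaturated pairs
#'
#' hnNOE = I_sat / I_eq per replicate; the reported value is the mean over
#' replicates and the error is the sample SD across replicates (the
#' convention for duplicate measurements). With a single replicate the SD is
#' undefined and the error is reported as 0 with a warning.
#'
#' @param pairs list of [noe_pair()] objects for one residue, or a
#'   data.frame with columns `residue`, `replicate`, `i_sat`, `i_eq`
#'   (several residues allowed).
#' @return data.frame with columns `residue`, `noe`, `noe_err`, `n_rep`.
#' @export
compute_hnnoe <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      stopifnot(inherits(p, "noe_pair"))
      data.frame(residue = p$residue_id, replicate = p$replicate_id,
                 i_sat = p$i_sat, i_eq = p$i_eq, stringsAsFactors = FALSE)
    }))
  }
  if (any(pairs$i_eq == 0))
    stop("compute_hnnoe: i_eq must be nonzero")
  ratios <- pairs$i_sat / pairs$i_eq
  groups <- split(ratios, pairs$residue)
  if (any(vapply(groups, length, 0L) < 2L))
    warning("single NOE replicate for some residue(s); error reported as 0")
  out <- data.frame(
    residue = names(groups),
    noe = vapply(groups, mean, 0),
    noe_err = vapply(groups, function(r) if (length(r) >= 2L) stats::sd(r) else 0, 0),
    n_rep = vapply(groups, length, 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a per-residue relaxation record table
#'
#' Combines T1 and T2 exponential fits and hnNOE values into the rate table
#' consumed by [reduced_spectral_density()]: R1 = 1/T1, R2 = 1/T2, with
#' errors propagated as \eqn{\sigma_R = \sigma_T / T^2}.
#'
#' @param t1_fits,t2_fits lists of `exp_fit` objects (from
#'   [fit_exponential()]) for the T1 and T2 experiments.
#' @param noe data.frame from [compute_hnnoe()].
#' @param field_mhz spectrometer 1H frequency the data were recorded at.
#' @return data.frame of class `relaxation_records` with columns `residue`,
#'   `r1`, `r1_err`, `r2`, `r2_err`, `noe`, `noe_err` and attribute
#'   `field_mhz`. Residues lacking a converged fit in either experiment are
#'   dropped with a warning.
#' @export
relaxation_records <- function(t1_fits, t2_fits, noe, field_mhz = 600.13) {
  tab <- function(fits, what) {
    keep <- Filter(function(f) isTRUE(f$converged), fits)
    if (length(keep) < length(fits))
      warning(length(fits) - length(keep), " non-converged ", what,
              " fit(s) dropped")
    data.frame(residue = vapply(keep, `[[`, "", "residue_id"),
               t_relax = vapply(keep, `[[`, 0, "t_relax"),
               err = vapply(keep, `[[`, 0, "mc_error"),
               stringsAsFactors = FALSE)
  }
  t1 <- tab(t1_fits, "T1")
  t2 <- tab(t2_fits, "T2")
  m <- merge(merge(t1, t2, by = "residue", suffixes = c("_1", "_2")),
             noe[, c("residue", "noe", "noe_err")], by = "residue")
  out <- data.frame(
    residue = m$residue,
    r1 = 1 / m$t_relax_1, r1_err = m$err_1 / m$t_relax_1^2,
    r2 = 1 / m$t_relax_2, r2_err = m$err_2 / m$t_relax_2^2,
    noe = m$noe, noe_err = m$noe_err, stringsAsFactors = FALSE)
  out <- out[order(suppressWarnings(as.numeric(out$residue)), out$residue), ]
  rownames(out) <- NULL
  structure(out, class = c("relaxation_records", "data.frame"),
            field_mhz = field_mhz)
}

# closed-form reduced mapping on rates; J in seconds
reduced_map <- function(r1, r2, noe, constants) {
  d2 <- constants$d2; c2 <- constants$c2
  gr <- constants$gamma_n / constants$gamma_h
  sigma <- r1 * (noe - 1) * gr
  jh <- 4 * sigma / (5 * d2)
  jn <- (r1 - 7 * d2 / 4 * jh) / (3 * d2 / 4 + c2)
  j0 <- (r2 - 13 * d2 / 8 * jh - (3 * d2 / 8 + c2 / 2) * jn) /
    (d2 / 2 + 2 * c2 / 3)
  list(j0 = j0, j_wn = jn, j_wh = jh)
}

#' Reduced spectral density mapping
#'
#' Converts per-residue (R1, R2, NOE) at one field into the spectral density
#' sampled at three frequencies, under the standard lumping of the
#' high-frequency terms \eqn{J(\omega_H\pm\omega_N) \approx J(\omega_H)
#' \approx J(0.87\omega_H)}:
#' \deqn{\sigma = R_1 (NOE - 1) \gamma_N/\gamma_H}
#' \deqn{J(0.87\omega_H) = 4\sigma / (5 d^2)}
#' \deqn{J(\omega_N) = [R_1 - (7d^2/4) J(0.87\omega_H)] / (3d^2/4 + c^2)}
#' \deqn{J(0) = [R_2 - (13d^2/8) J(0.87\omega_H) - (3d^2/8 + c^2/2)
#'   J(\omega_N)] / (d^2/2 + 2c^2/3)}
#' Errors are obtained by first-order propagation of the rate and NOE errors
#' through these closed forms (R1, R2 and NOE treated as independent).
#'
#' Noise can push mapped values negative; such values are flagged invalid
#' (per-value `valid_*` columns), never clamped, and are excluded from the
#' summaries computed downstream - clamping would bias the group SDs that
#' are the headline readout of the J(0) profiles.
#'
#' @param records a `relaxation_records` data.frame (or any data.frame with
#'   columns `residue`, `r1`, `r1_err`, `r2`, `r2_err`, `noe`, `noe_err`).
#' @param constants a [spin_constants()] object; fixed for the whole table.
#' @return data.frame of class `spectral_densities`: per residue `j0`,
#'   `j0_err`, `j_wn`, `j_wn_err`, `j_wh`, `j_wh_err` (all ns) and logical
#'   `valid_j0`, `valid_j_wn`, `valid_j_wh`.
#' @export
reduced_spectral_density <- function(records, constants = spin_constants()) {
  need <- c("residue", "r1", "r1_err", "r2", "r2_err", "noe", "noe_err")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$r1 == 0))
    stop("reduced_spectral_density: zero R1 encountered")
  d2 <- constants$d2; c2 <- constants$c2
  gr <- constants$gamma_n / constants$gamma_h
  An <- 3 * d2 / 4 + c2          # J(wN) denominator
  A0 <- d2 / 2 + 2 * c2 / 3      # J(0) denominator
  B <- 13 * d2 / 8
  C <- 3 * d2 / 8 + c2 / 2
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r1 <- records$r1[i]; r2 <- records$r2[i]; noe <- records$noe[i]
    jj <- reduced_map(r1, r2, noe, constants)
    # partial derivatives of (jh, jn, j0) wrt (r1, r2, noe)
    djh_dr1 <- 4 * (noe - 1) * gr / (5 * d2)
    djh_dnoe <- 4 * r1 * gr / (5 * d2)
    djn_dr1 <- (1 - 7 * d2 / 4 * djh_dr1) / An
    djn_dnoe <- -(7 * d2 / 4) * djh_dnoe / An
    dj0_dr1 <- (-B * djh_dr1 - C * djn_dr1) / A0
    dj0_dr2 <- 1 / A0
    dj0_dnoe <- (-B * djh_dnoe - C * djn_dnoe) / A0
    v <- c(records$r1_err[i], records$r2_err[i], records$noe_err[i])^2
    jh_err <- sqrt(djh_dr1^2 * v[1] + djh_dnoe^2 * v[3])
    jn_err <- sqrt(djn_dr1^2 * v[1] + djn_dnoe^2 * v[3])
    j0_err <- sqrt(dj0_dr1^2 * v[1] + dj0_dr2^2 * v[2] + dj0_dnoe^2 * v[3])
    data.frame(residue = records$residue[i],
               j0 = jj$j0 * 1e9, j0_err = j0_err * 1e9,
               j_wn = jj$j_wn * 1e9, j_wn_err = jn_err * 1e9,
               j_wh = jj$j_wh * 1e9, j_wh_err = jh_err * 1e9,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$valid_j0 <- is.finite(out$j0) & out$j0 >= 0
  out$valid_j_wn <- is.finite(out$j_wn) & out$j_wn >= 0
  out$valid_j_wh <- is.finite(out$j_wh) & out$j_wh >= 0
  structure(out, class = c("spectral_densities", "data.frame"),
            field_mhz = constants$field_mhz)
}

#' Isotropic rotational correlation time from trimmed R2/R1
#'
#' Estimates the overall tumbling time of a rigid isotropic rotor from the
#' R2/R1 ratio: the most extreme ratios (exchange-broadened or highly mobile
#' residues) are trimmed symmetrically, and the rigid-rotor ratio equation
#' (forward relaxation equations with S^2 = 1, tau_e = 0, Rex = 0) is solved
#' for tau_c by bracketed root finding on (0.1, 100] ns.
#'
#' @param records a `relaxation_records` data.frame.
#' @param trim_fraction total fraction of ratios to trim (half per tail);
#'   in `[0, 1)`. At least 5 residues must survive trimming.
#' @param constants a [spin_constants()] object.
#' @return tau_c in ns.
#' @export
estimate_tauc_isotropic <- function(records, trim_fraction = 0.2,
                                    constants = spin_constants()) {
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("validation error: trim_fraction must be in [0, 1)")
  if (!all(c("r1", "r2") %in% names(records)))
    stop("records must carry r1 and r2 columns (see relaxation_records)")
  ratio <- records$r2 / records$r1
  n_keep <- length(ratio) - 2 * floor(length(ratio) * trim_fraction / 2)
  if (n_keep < 5L)
    stop("validation error: fewer than 5 residues remain after trimming")
  target <- mean(ratio, trim = trim_fraction / 2)
  f <- function(tau_ns) {
    r <- forward_rates(function(w) model_free_j(w, 1, tau_ns), constants)
    r$r2 / r$r1 - target
  }
  lo <- 0.1; hi <- 100
  if (f(lo) * f(hi) > 0)
    stop("no rigid-rotor tau_c in (0.1, 100] ns reproduces the trimmed R2/R1 ratio")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' J(0) ratio profile between modified and unmodified forms
#'
#' The per-residue ratio of J(0) in the modified (e.g. ubiquitylated) form
#' to the unmodified form, with relative errors combined in quadrature, plus
#' the group mean and SD of the ratio over valid shared residues, and each
#' table's own J(0) mean +/- SD summary. Ratios are computed only where both
#' inputs are valid (finite, non-negative).
#'
#' @param modified,unmodified `spectral_densities` tables from
#'   [reduced_spectral_density()].
#' @return object of class `jratio_profile`: list with `profile` (data.frame
#'   residue, ratio, ratio_err), `mean`, `sd`, `n`, and `summary_modified` /
#'   `summary_unmodified` (each mean, sd, n of J(0) in ns).
#' @export
jratio_profile <- function(modified, unmodified) {
  a <- modified[modified$valid_j0, c("residue", "j0", "j0_err")]
  b <- unmodified[unmodified$valid_j0, c("residue", "j0", "j0_err")]
  m <- merge(a, b, by = "residue", suffixes = c("_mod", "_unmod"))
  if (!nrow(m))
    stop("validation error: no shared valid residues between the two tables")
  if (nrow(m) < 5L)
    stop("validation error: fewer than 5 shared valid residues")
  ratio <- m$j0_mod / m$j0_unmod
  rel <- sqrt((m$j0_err_mod / m$j0_mod)^2 + (m$j0_err_unmod / m$j0_unmod)^2)
  profile <- data.frame(residue = m$residue, ratio = ratio,
                        ratio_err = abs(ratio) * rel,
                        stringsAsFactors = FALSE)
  ord <- order(suppressWarnings(as.numeric(profile$residue)), profile$residue)
  profile <- profile[ord, ]
  rownames(profile) <- NULL
  summarize <- function(tab) {
    v <- tab$j0[tab$valid_j0]
    list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  structure(list(profile = profile, mean = mean(ratio), sd = stats::sd(ratio),
                 n = nrow(profile),
                 summary_modified = summarize(modified),
                 summary_unmodified = summarize(unmodified)),
            class = "jratio_profile")
}

#' @export
print.jratio_profile <- function(x, ...) {
  cat(sprintf("J(0) ratio profile over %d residues: mean %.2f, SD %.2f\n",
              x$n, x$mean, x$sd))
  cat(sprintf("  modified   J(0) = %.1f +/- %.1f ns (n=%d)\n",
              x$summary_modified$mean, x$summary_modified$sd,
              x$summary_modified$n))
  cat(sprintf("  unmodified J(0) = %.1f +/- %.1f ns (n=%d)\n",
              x$summary_unmodified$mean, x$summary_unmodified$sd,
              x$summary_unmodified$n))
  invisible(x)
}

#' Chemical shift perturbation between two peak lists
#'
#' Weighted 1H/15N displacement per shared residue:
#' \eqn{CSP = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}} with the
#' conventional nitrogen weight w = 0.14. Residues present in only one list
#' are excluded (with a message).
#'
#' @param list_a,list_b [peak_list()] objects.
#' @param nitrogen_weight scalar weight for the 15N dimension.
#' @return data.frame with columns `residue`, `csp` (ppm).
#' @export
compute_csp <- function(list_a, list_b, nitrogen_weight = 0.14) {
  m <- merge(as.data.frame(list_a), as.data.frame(list_b),
             by = "residue_id", suffixes = c("_a", "_b"))
  if (!nrow(m))
    stop("validation error: no shared residues between the peak lists")
  dropped <- length(union(list_a$residue_id, list_b$residue_id)) - nrow(m)
  if (dropped > 0)
    message(dropped, " residue(s) present in only one list excluded from CSP")
  out <- data.frame(
    residue = m$residue_id,
    csp = sqrt((m$h_ppm_a - m$h_ppm_b)^2 +
                 (nitrogen_weight * (m$n_ppm_a - m$n_ppm_b))^2),
    stringsAsFactors = FALSE)
  ord <- order(suppressWarnings(as.numeric(out$residue)), out$residue)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
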