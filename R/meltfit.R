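#' Barycentric mean emission wavelength
#'
#' The intensity-weighted mean wavelength of a fluorescence emission
#' spectrum, \eqn{\langle\lambda\rangle = \sum_i \lambda_i F(\lambda_i) /
#' \sum_i F(\lambda_i)}. Tryptophan emission red-shifts on solvent exposure,
#' so this scalar tracks unfolding far more robustly than the peak maximum.
#'
#' @param x an [emission_spectrum()], or a numeric wavelength vector when
#'   `intensities` is given.
#' @param intensities intensities matching `x` when `x` is a plain vector.
#' @return barycentric mean wavelength in nm; always within the wavelength
#'   range of the spectrum.
#' @examples
#' barycentric_mean(c(320, 360), c(1, 3))  # 350
#' @export
barycentric_mean <- function(x, intensities = NULL) {
  if (inherits(x, "emission_spectrum")) {
    lambda <- x$wavelengths
    f <- x$intensities
  } else {
    lambda <- as.numeric(x)
    f <- as.numeric(intensities)
  }
  tot <- sum(f)
  if (!is.finite(tot) || tot <= 0)
    stop("barycentric_mean: total intensity must be positive")
  sum(lambda * f) / tot
}

#' Build melting curves from a set of emission spectra
#'
#' Reduces each spectrum to its barycentric mean and assembles, per
#' replicate, the curve of mean emission wavelength versus condition
#' (temperature or denaturant concentration), sorted by condition.
#'
#' @param spectra a `melt_series` data.frame (as returned by
#'   [read_dataset()] or [simulate_melt_series()]) or a list of
#'   [emission_spectrum()] objects.
#' @return data.frame of class `melt_curve` with columns `replicate`,
#'   `condition`, `bc_mean` and attribute `condition_kind`.
#' @export
build_melt_curve <- function(spectra) {
  if (inherits(spectra, "melt_series")) spectra <- split_spectra(spectra)
  if (!length(spectra)) stop("build_melt_curve: no spectra supplied")
  df <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(replicate = s$replicate_id, condition = s$condition_value,
               bc_mean = barycentric_mean(s), kind = s$condition_kind,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df[c("replicate", "condition")]))
    stop("build_melt_curve: duplicate (replicate, condition) pairs")
  counts <- table(df$replicate)
  if (any(counts < 3L))
    stop("build_melt_curve: each replicate needs at least 3 distinct conditions")
  kind <- unique(df$kind)
  if (length(kind) != 1L)
    stop("build_melt_curve: mixed condition kinds in one series")
  df <- df[order(df$replicate, df$condition), c("replicate", "condition", "bc_mean")]
  rownames(df) <- NULL
  structure(df, class = c("melt_curve", "data.frame"), condition_kind = kind)
}

#' Fit the Boltzmann sigmoid to a melting curve
#'
#' Fits
#' \deqn{\lambda(T) = \lambda_N + \frac{\lambda_D - \lambda_N}
#'   {1 + \exp\{(T_{half} - T)/rate\}}}
#' by Levenberg-Marquardt least squares, where \eqn{\lambda_N} and
#' \eqn{\lambda_D} are the emission wavelengths of the native and fully
#' denatured states, \eqn{T_{half}} is the transition midpoint and `rate`
#' sets the slope. The same model serves chemical denaturation with
#' concentration in place of temperature. Standard errors come from the
#' local curvature (the estimated covariance of the least-squares fit).
#'
#' Starting values are derived from the data unless overridden: the baselines
#' from the barycentric means at the 10% lowest and highest conditions, the
#' midpoint from the steepest-slope condition, and rate = 2 (condition
#' units). When the optimizer fails, or the fitted midpoint falls outside
#' the data range, the result is returned with `converged = FALSE` rather
#' than raising an error.
#'
#' @param curve a single-replicate `melt_curve` (or a data.frame with
#'   `condition` and `bc_mean`); at least 5 points.
#' @param init optional named list overriding starting values
#'   (`lambda_n`, `lambda_d`, `t_half`, `rate`).
#' @return object of class `melt_fit`: list with `lambda_n`, `lambda_d`,
#'   `t_half`, `rate`, `se` (named vector), `converged`, `rms`, `n`,
#'   `replicate_id`, `condition_kind`.
#' @export
fit_sigmoid <- function(curve, init = NULL) {
  kind <- attr(curve, "condition_kind") %||% "thermal"
  rep_id <- if (!is.null(curve$replicate)) unique(curve$replicate) else "r1"
  if (length(rep_id) > 1L)
    stop("fit_sigmoid: fit one replicate at a time (see build_melt_curve)")
  x <- curve$condition
  y <- curve$bc_mean
  if (length(x) < 5L)
    stop("fit_sigmoid: at least 5 points are required")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  k <- max(1L, ceiling(0.1 * length(x)))
  slope <- diff(y) / diff(x)
  start <- list(
    lambda_n = mean(y[seq_len(k)]),
    lambda_d = mean(y[seq(length(y) - k + 1L, length(y))]),
    t_half = x[which.max(abs(slope))],
    rate = 2
  )
  if (!is.null(init)) start[names(init)] <- init

  failed <- function() {
    structure(list(lambda_n = NA_real_, lambda_d = NA_real_,
                   t_half = NA_real_, rate = NA_real_,
                   se = c(lambda_n = NA_real_, lambda_d = NA_real_,
                          t_half = NA_real_, rate = NA_real_),
                   converged = FALSE, rms = NA_real_, n = length(x),
                   replicate_id = rep_id, condition_kind = kind),
              class = "melt_fit")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lambda_n + (lambda_d - lambda_n) / (1 + exp((t_half - x) / rate)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  est <- stats::coef(fit)
  if (!is.finite(est[["t_half"]]) ||
      est[["t_half"]] < min(x) || est[["t_half"]] > max(x))
    return(failed())
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 4), names(est))
  })
  structure(list(
    lambda_n = est[["lambda_n"]], lambda_d = est[["lambda_d"]],
    t_half = est[["t_half"]], rate = est[["rate"]],
    se = se[c("lambda_n", "lambda_d", "t_half", "rate")],
    converged = TRUE,
    rms = sqrt(mean(stats::resid(fit)^2)),
    n = length(x), replicate_id = rep_id, condition_kind = kind),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  lab <- if (x$condition_kind == "thermal") "T_half/K" else "c_half/M"
  if (!x$converged) {
    cat("melt_fit: not converged (", x$n, "points )\n")
  } else {
    cat(sprintf(
      "melt_fit [%s]: %s = %.2f +/- %.2f, rate = %.2f, lambda_N = %.2f, lambda_D = %.2f nm\n",
      x$replicate_id, lab, x$t_half, x$se[["t_half"]], x$rate,
      x$lambda_n, x$lambda_d))
  }
  invisible(x)
}

#' Fit every replicate of a melt series
#'
#' Convenience wrapper: [build_melt_curve()] then [fit_sigmoid()] per
#' replicate.
#'
#' @param spectra a `melt_series` or list of spectra.
#' @param init optional starting-value overrides passed to [fit_sigmoid()].
#' @return list of `melt_fit` objects, one per replicate.
#' @export
fit_melt_series <- function(spectra, init = NULL) {
  curve <- build_melt_curve(spectra)
  lapply(split(curve, curve$replicate), function(d) {
    d2 <- structure(d, class = c("melt_curve", "data.frame"),
                    condition_kind = attr(curve, "condition_kind"))
    fit_sigmoid(d2, init = init)
  })
}

#' Aggregate replicate midpoint fits
#'
#' Mean, SEM (sample SD / sqrt(n)) and n of the fitted midpoints over
#' converged replicate fits, the summary reported per construct (mean of
#' three independent experiments, error bars = SEM).
#'
#' @param fits list of `melt_fit` objects (or a numeric vector of midpoints).
#' @return list with `mean`, `sem`, `n`, `values`.
#' @export
aggregate_replicates <- function(fits) {
  if (is.numeric(fits)) {
    vals <- fits
  } else {
    conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
    if (any(!conv))
      warning(sum(!conv), " non-converged fit(s) excluded from aggregation")
    vals <- vapply(fits[conv], function(f) f$t_half, 0)
  }
  if (length(vals) < 2L)
    stop("aggregate_replicates: at least 2 converged fits are required")
  list(mean = mean(vals), sem = stats::sd(vals) / sqrt(length(vals)),
       n = length(vals), values = unname(vals))
}

#' Compare transition midpoints between two constructs
#'
#' Two-sample Student's t test on replicate midpoints: two-tailed, pooled
#' variance by default (Welch's unequal-variance form behind `welch = TRUE`).
#' Reports the difference Delta = mean(b) - mean(a) alongside group means,
#' SEMs and the test.
#'
#' Degenerate inputs follow fixed conventions: zero variance in both groups
#' with equal means gives p = 1; zero variance with different means gives a
#' p at the smallest positive double, with a warning.
#'
#' @param group_a,group_b numeric vectors of replicate midpoints (each
#'   n >= 2), or lists of `melt_fit` objects.
#' @param welch use Welch's t test instead of the pooled-variance form.
#' @return object of class `transition_comparison`: list with `delta`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`, `t_statistic`, `df`, `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @export
compare_transitions <- function(group_a, group_b, welch = FALSE) {
  pull <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(Filter(function(f) isTRUE(f$converged), g),
           function(f) f$t_half, 0)
  }
  a <- pull(group_a); b <- pull(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_transitions: each group needs n >= 2")
  delta <- mean(b) - mean(a)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    } else {
      warning("zero variance in both groups with different means; p reported at the double floor")
      tt <- list(statistic = sign(delta) * Inf,
                 parameter = length(a) + length(b) - 2,
                 p.value = .Machine$double.xmin)
    }
  } else {
    ht <- stats::t.test(b, a, var.equal = !welch,
                        alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(
    delta = delta, mean_a = mean(a), mean_b = mean(b),
    sem_a = sem(a), sem_b = sem(b),
    t_statistic = tt$statistic, df = tt$parameter, p_value = tt$p.value,
    n_a = length(a), n_b = length(b),
    method = if (welch) "welch" else "pooled"),
    class = "transition_comparison")
}

#' @export
print.transition_comparison <- function(x, ...) {
  cat(sprintf(
    "transition comparison (%s t test): delta = %.2f, t = %.3g (df %.3g), p = %.3g\n",
    x$method, x$delta, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  group a: %.2f +/- %.2f (n=%d); group b: %.2f +/- %.2f (n=%d)\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  invisible(x)
}

#' @export
as.data.frame.melt_fit <- function(x, ...) {
  data.frame(replicate = x$replicate_id, lambda_n = x$lambda_n,
             lambda_d = x$lambda_d, t_half = x$t_half, rate = x$rate,
             t_half_se = unname(x$se[["t_half"]]), converged = x$converged,
             rms = x$rms, stringsAsFactors = FALSE)
}
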