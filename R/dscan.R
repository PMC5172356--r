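#' Linear two-window baseline correction of a DSC trace
#'
#' Subtracts the straight line through the mean heat capacity of a
#' transition-free pre-transition window and a post-transition window. The
#' defaults take the first and last 10% of the temperature grid. After
#' subtraction the trace averages to ~0 inside both windows. If a detected
#' peak's support overlaps either window a warning is raised (the windows
#' were asserted transition-free).
#'
#' @param trace a [dsc_trace()].
#' @param pre_window,post_window numeric length-2 temperature ranges (K)
#'   inside the trace range, or `NULL` for the 10% defaults.
#' @return a baseline-subtracted [dsc_trace()] with attribute `baseline`
#'   (intercept, slope).
#' @export
correct_baseline <- function(trace, pre_window = NULL, post_window = NULL) {
  stopifnot(inherits(trace, "dsc_trace"))
  tt <- trace$temperatures
  cp <- trace$heat_capacity
  rng <- range(tt)
  if (is.null(pre_window))
    pre_window <- c(rng[1], rng[1] + 0.1 * diff(rng))
  if (is.null(post_window))
    post_window <- c(rng[2] - 0.1 * diff(rng), rng[2])
  for (w in list(pre_window, post_window)) {
    if (length(w) != 2L || w[1] >= w[2] || w[1] < rng[1] || w[2] > rng[2])
      stop("validation error: baseline window outside trace range")
  }
  in_pre <- tt >= pre_window[1] & tt <= pre_window[2]
  in_post <- tt >= post_window[1] & tt <= post_window[2]
  if (!any(in_pre) || !any(in_post))
    stop("validation error: baseline window contains no points")
  x1 <- mean(tt[in_pre]); y1 <- mean(cp[in_pre])
  x2 <- mean(tt[in_post]); y2 <- mean(cp[in_post])
  slope <- (y2 - y1) / (x2 - x1)
  intercept <- y1 - slope * x1
  corrected <- cp - (intercept + slope * tt)
  out <- dsc_trace(tt, corrected, scan_label = trace$scan_label,
                   scan_rate = trace$scan_rate)
  attr(out, "baseline") <- c(intercept = intercept, slope = slope)
  # warn if a clear corrected peak's support reaches into a window (the
  # windows were asserted transition-free). Round-off residue and bare noise
  # are not treated as features.
  m <- max(corrected)
  noise_est <- stats::mad(diff(corrected)) / sqrt(2)
  feature <- m > max(10 * noise_est, 1e-8 * max(diff(range(cp)), 1))
  if (feature) {
    pk <- find_transition_peaks(out, min_prominence = 0.25 * m)
    overlaps <- function(lo, hi, w) lo <= w[2] && hi >= w[1]
    for (i in seq_len(nrow(pk))) {
      if (overlaps(pk$support_lo[i], pk$support_hi[i], pre_window) ||
          overlaps(pk$support_lo[i], pk$support_hi[i], post_window)) {
        warning("baseline window overlaps the detected peak support")
        break
      }
    }
  }
  out
}

#' Detect transition peaks in a baseline-corrected DSC trace
#'
#' Local maxima of the heat capacity exceeding a prominence threshold,
#' sorted by temperature. The transition temperature is defined as the grid
#' temperature of the peak maximum (no interpolation). The peak area is the
#' trapezoidal integral over the contiguous support where the corrected heat
#' capacity exceeds 5% of the peak height.
#'
#' @param trace a baseline-corrected [dsc_trace()].
#' @param min_prominence minimum peak prominence, same units as the heat
#'   capacity (kJ/K/mol).
#' @return data.frame with one row per peak: `t_m` (K), `height`, `area`
#'   (kJ/mol), `prominence`, `support_lo`, `support_hi`. Zero rows when no
#'   peak passes the threshold.
#' @export
find_transition_peaks <- function(trace, min_prominence) {
  stopifnot(inherits(trace, "dsc_trace"))
  if (missing(min_prominence) || !is.finite(min_prominence) || min_prominence < 0)
    stop("min_prominence must be a non-negative number")
  tt <- trace$temperatures
  y <- trace$heat_capacity
  n <- length(y)
  # strict local maxima (plateaus take the first point)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  empty <- data.frame(t_m = numeric(0), height = numeric(0),
                      area = numeric(0), prominence = numeric(0),
                      support_lo = numeric(0), support_hi = numeric(0))
  if (!length(is_max)) return(empty)
  rows <- lapply(is_max, function(i) {
    h <- y[i]
    # prominence: drop to the highest of the two key cols. On each side,
    # find the minimum between the peak and the nearest higher point (or
    # the trace end); prominence = height - max(left min, right min).
    left <- if (any(y[seq_len(i - 1)] > h)) {
      j <- max(which(y[seq_len(i - 1)] > h))
      min(y[j:i])
    } else min(y[1:i])
    right <- if (i < n && any(y[(i + 1):n] > h)) {
      j <- i + min(which(y[(i + 1):n] > h))
      min(y[i:j])
    } else min(y[i:n])
    prom <- h - max(left, right)
    # support: contiguous region around the peak with y > 5% of height
    thr <- 0.05 * h
    lo <- i; while (lo > 1L && y[lo - 1L] > thr) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1L] > thr) hi <- hi + 1L
    area <- if (hi > lo) pracma::trapz(tt[lo:hi], y[lo:hi]) else 0
    data.frame(t_m = tt[i], height = h, area = area, prominence = prom,
               support_lo = tt[lo], support_hi = tt[hi])
  })
  out <- do.call(rbind, rows)
  out <- out[out$prominence >= min_prominence & out$height > 0, , drop = FALSE]
  out <- out[order(out$t_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Folding reversibility from first-heat and reheat scans
#'
#' Matches transition peaks between a first heating and a reheating of the
#' same sample (nearest midpoint within `matching_tolerance`) and reports,
#' per first-heat peak, the reversibility index = reheat area / first-heat
#' area. A first-heat peak with no reheat partner gets index 0 - the
#' signature of irreversible unfolding, where the endotherm is absent on
#' reheating.
#'
#' @param first,reheat baseline-corrected [dsc_trace()] objects with
#'   overlapping temperature ranges.
#' @param matching_tolerance maximum |t_m| difference for a match, K
#'   (default 3).
#' @param min_prominence prominence threshold passed to
#'   [find_transition_peaks()]; default 5% of the first-heat maximum.
#' @return object of class `reversibility_report`: data.frame with one row
#'   per first-heat peak (`t_m_first`, `area_first`, `t_m_reheat`,
#'   `area_reheat`, `reversibility_index`).
#' @export
reversibility_index <- function(first, reheat, matching_tolerance = 3,
                                min_prominence = NULL) {
  stopifnot(inherits(first, "dsc_trace"), inherits(reheat, "dsc_trace"))
  if (max(first$temperatures) < min(reheat$temperatures) ||
      max(reheat$temperatures) < min(first$temperatures))
    stop("validation error: traces have no overlapping temperature range")
  if (is.null(min_prominence))
    min_prominence <- 0.05 * max(first$heat_capacity)
  pk1 <- find_transition_peaks(first, min_prominence)
  if (!nrow(pk1))
    stop("validation error: no peaks detected in the first heat")
  pk2 <- find_transition_peaks(reheat, min_prominence)
  rows <- lapply(seq_len(nrow(pk1)), function(i) {
    out <- data.frame(t_m_first = pk1$t_m[i], area_first = pk1$area[i],
                      t_m_reheat = NA_real_, area_reheat = NA_real_,
                      reversibility_index = 0)
    if (nrow(pk2)) {
      dist <- abs(pk2$t_m - pk1$t_m[i])
      j <- which.min(dist)
      if (dist[j] <= matching_tolerance) {
        out$t_m_reheat <- pk2$t_m[j]
        out$area_reheat <- pk2$area[j]
        out$reversibility_index <- pk2$area[j] / pk1$area[i]
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  if (any(out$reversibility_index == 0))
    warning(sum(out$reversibility_index == 0),
            " first-heat peak(s) unmatched in the reheat (index 0)")
  structure(out, class = c("reversibility_report", "data.frame"))
}
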