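test_that("barycentric mean reproduces closed-form weighted means", {
  # two-point closed form: (320*1 + 360*3) / 4 = 350
  expect_equal(barycentric_mean(c(320, 360), c(1, 3)), 350)
  # symmetric triangular band centered at 350 on a symmetric grid
  lam <- seq(340, 360, by = 1)
  tri <- 10 - abs(lam - 350)
  expect_equal(barycentric_mean(lam, tri), 350)
  # affine intensity scaling leaves it unchanged
  expect_equal(barycentric_mean(lam, 7.3 * tri), 350)
  # result always inside the wavelength range
  s <- emission_spectrum(lam, tri, 300)
  bc <- barycentric_mean(s)
  expect_true(bc >= min(lam) && bc <= max(lam))
})

test_that("truncation shifts the barycentric mean as quadrature predicts", {
  # Gaussian band at 330 nm, sigma 15, truncated to the 310-400 nm window:
  # the window clips more blue than red tail, pulling the mean above 330
  lam <- seq(310, 400, by = 0.05)
  f <- exp(-(lam - 330)^2 / (2 * 15^2))
  bc <- barycentric_mean(lam, f)
  oracle <- truncated_gaussian_centroid(330, 15, 310, 400)
  expect_gt(bc, 330)
  expect_equal(bc, oracle, tolerance = 0.01 / oracle)
})

test_that("non-positive total intensity is a computation error", {
  expect_error(barycentric_mean(c(320, 330, 340), c(0, 0, 0)), "positive")
  expect_error(barycentric_mean(c(320, 330, 340), c(1, -2, 0.5)), "positive")
})

test_that("melt curves are one barycentric mean per condition, sorted", {
  spectra <- list(
    emission_spectrum(310:312, c(1, 2, 1), 350, replicate_id = "a"),
    emission_spectrum(310:312, c(1, 2, 1), 300, replicate_id = "a"),
    emission_spectrum(310:312, c(1, 2, 1), 325, replicate_id = "a"),
    emission_spectrum(310:312, c(1, 2, 1), 300, replicate_id = "b"),
    emission_spectrum(310:312, c(1, 2, 1), 325, replicate_id = "b"),
    emission_spectrum(310:312, c(1, 2, 1), 350, replicate_id = "b"))
  curve <- build_melt_curve(spectra)
  expect_equal(nrow(curve), 6L)
  expect_equal(unique(curve$replicate), c("a", "b"))
  for (r in c("a", "b"))
    expect_equal(curve$condition[curve$replicate == r], c(300, 325, 350))
  # duplicate (replicate, condition) pairs are rejected
  expect_error(build_melt_curve(c(spectra, spectra[1])), "duplicate")
})

test_that("noiseless sigmoid curves invert to the generating parameters", {
  grid <- seq(300, 360, by = 2)
  cases <- list(c(340, 355, 332.1, 2.0), c(335, 352, 316.5, 1.2),
                c(338, 354, 328.8, 3.5))
  for (cs in cases) {
    y <- cs[1] + (cs[2] - cs[1]) / (1 + exp((cs[3] - grid) / cs[4]))
    curve <- structure(
      data.frame(replicate = "r1", condition = grid, bc_mean = y),
      class = c("melt_curve", "data.frame"), condition_kind = "thermal")
    fit <- fit_sigmoid(curve)
    expect_true(fit$converged)
    expect_equal(fit$lambda_n, cs[1], tolerance = 1e-6)
    expect_equal(fit$lambda_d, cs[2], tolerance = 1e-6)
    expect_equal(fit$t_half, cs[3], tolerance = 1e-6)
    expect_equal(fit$rate, cs[4], tolerance = 1e-6)
    expect_lt(fit$rms, 1e-8)
  }
})

test_that("fitting is invariant to affine intensity rescaling upstream", {
  p <- melt_sim_params(324, seed = 31)
  series <- simulate_melt_series(p)
  scaled <- series
  scaled$intensity <- scaled$intensity * 3.7
  f1 <- fit_melt_series(series)
  f2 <- fit_melt_series(scaled)
  expect_equal(vapply(f1, `[[`, 0, "t_half"), vapply(f2, `[[`, 0, "t_half"),
               tolerance = 1e-9)
})

test_that("degenerate curves set the convergence flag instead of erroring", {
  grid <- seq(300, 360, by = 2)
  flat <- structure(
    data.frame(replicate = "r1", condition = grid, bc_mean = rep(345, length(grid))),
    class = c("melt_curve", "data.frame"), condition_kind = "thermal")
  fit <- fit_sigmoid(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$t_half))
  # fewer than 5 points is a hard validation error
  short <- structure(
    data.frame(replicate = "r1", condition = grid[1:4], bc_mean = c(1, 2, 3, 4)),
    class = c("melt_curve", "data.frame"), condition_kind = "thermal")
  expect_error(fit_sigmoid(short), "5 points")
})

test_that("replicate aggregation gives mean, SEM = SD/sqrt(n), and n", {
  agg <- aggregate_replicates(c(332.0, 332.1, 332.2))
  expect_equal(agg$mean, 332.1)
  expect_equal(agg$sem, sd(c(332.0, 332.1, 332.2)) / sqrt(3))
  expect_equal(agg$sem, 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(agg$n, 3L)
  # identical replicates have SEM 0
  expect_equal(aggregate_replicates(c(330, 330, 330))$sem, 0)
  # a non-converged fit is excluded with a warning
  ok <- structure(list(t_half = 330, converged = TRUE), class = "melt_fit")
  bad <- structure(list(t_half = NA_real_, converged = FALSE), class = "melt_fit")
  expect_warning(agg2 <- aggregate_replicates(list(ok, ok, bad)), "non-converged")
  expect_equal(agg2$n, 2L)
  expect_error(aggregate_replicates(c(330)), "at least 2")
})

test_that("transition comparison matches the textbook pooled t test", {
  a <- c(332.0, 332.1, 332.2)
  b <- c(316.3, 316.5, 316.7)
  cmp <- compare_transitions(a, b)
  oracle <- pooled_t_oracle(a, b)
  expect_equal(cmp$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(cmp$df, oracle$df)
  expect_equal(cmp$delta, mean(b) - mean(a), tolerance = 1e-12)
  # swapping labels negates delta and preserves p exactly
  rev <- compare_transitions(b, a)
  expect_equal(rev$delta, -cmp$delta)
  expect_equal(rev$p_value, cmp$p_value)
})

test_that("comparison conventions cover degenerate variance cases", {
  expect_equal(compare_transitions(c(330, 330), c(330, 330))$p_value, 1)
  expect_warning(cmp <- compare_transitions(c(330, 330), c(331, 331)), "floor")
  expect_lte(cmp$p_value, .Machine$double.xmin)
  expect_gt(cmp$p_value, 0)
  expect_error(compare_transitions(c(330), c(331, 332)), "n >= 2")
})

test_that("chemical denaturation reuses the same fit with a known c_half", {
  p <- melt_sim_params(3.2, rate_true = 0.25,
                       condition_grid = seq(0, 7, by = 0.25),
                       condition_kind = "chemical", noise_sd = 0,
                       n_replicates = 1)
  fit <- fit_melt_series(simulate_melt_series(p))[[1]]
  expect_identical(fit$condition_kind, "chemical")
  expect_equal(fit$t_half, 3.2, tolerance = 1e-6)
})

test_that("midpoint recovery is unbiased and its errors are calibrated", {
  # 100 three-replicate experiments at default noise: mean bias of the
  # fitted midpoint < 0.1 K, and ~95% of per-fit +/-2SE intervals cover
  set.seed(501)
  truth <- 326
  n_exp <- 100
  errs <- numeric(n_exp)
  covered <- logical(0)
  for (i in seq_len(n_exp)) {
    p <- melt_sim_params(truth, seed = 100000 + i)
    fits <- fit_melt_series(simulate_melt_series(p))
    th <- vapply(fits, `[[`, 0, "t_half")
    se <- vapply(fits, function(f) f$se[["t_half"]], 0)
    errs[i] <- mean(th) - truth
    covered <- c(covered, abs(th - truth) <= 2 * se)
  }
  expect_lt(abs(mean(errs)), 0.1)
  cov <- mean(covered)
  expect_gte(cov, 0.88)
  expect_lte(cov, 0.99)
})
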