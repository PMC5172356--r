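t1_grid <- c(10, 20, 40, 180, 300, 500, 1000) / 1000
t2_grid <- c(10, 30, 50, 70, 90, 110, 150) / 1000

test_that("noiseless exponential decays invert exactly", {
  y <- 100 * exp(-t1_grid / 0.5)
  fit <- fit_exponential(decay_curve(1, t1_grid, y, "T1"), mc_iterations = 50,
                         seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$t_relax, 0.5, tolerance = 1e-7)
  expect_equal(fit$i0, 100, tolerance = 1e-7)
  expect_equal(fit$mc_error, 0)  # zero residual -> zero Monte Carlo spread
  expect_error(
    fit_exponential(decay_curve(1, t1_grid, rep(5, 7), "T1")),
    "constant")
  expect_error(fit_exponential(decay_curve(1, c(0.01, 0.1, 0.5),
                                           c(3, 2, 1), "T1")),
               "4 delay")
})

test_that("hnNOE is the replicate-mean ratio with SD errors", {
  pairs <- list(noe_pair(7, i_sat = 80, i_eq = 100, replicate_id = "e1"),
                noe_pair(7, i_sat = 80, i_eq = 100, replicate_id = "e2"))
  out <- compute_hnnoe(pairs)
  expect_equal(out$noe, 0.8)
  expect_equal(out$noe_err, 0)
  # ratios 0.76, 0.80 -> mean 0.78, error = sample SD ~ 0.0283
  df <- data.frame(residue = "7", replicate = c("e1", "e2"),
                   i_sat = c(76, 80), i_eq = c(100, 100))
  out2 <- compute_hnnoe(df)
  expect_equal(out2$noe, 0.78)
  expect_equal(out2$noe_err, sd(c(0.76, 0.80)))
  expect_equal(out2$noe_err, 0.0282842712474619, tolerance = 1e-10)
  # single replicate: error 0 with a warning
  expect_warning(out3 <- compute_hnnoe(df[1, ]), "single")
  expect_equal(out3$noe_err, 0)
  expect_error(noe_pair(7, 1, 0), "nonzero")
})

test_that("forward equations have the expected structure", {
  sc <- spin_constants()
  # J nonzero only at zero frequency: no longitudinal pathways
  j0_only <- function(w) ifelse(w == 0, 4.2e-9, 0)
  r <- forward_rates(j0_only, sc)
  expect_equal(r$r1, 0)
  expect_equal(r$noe, 1)  # guarded 0/0 -> no enhancement
  expect_gt(r$r2, 0)
  # Rex adds to R2 only, exactly
  j <- function(w) model_free_j(w, 0.85, 8, tau_e = 30)
  base <- forward_rates(j, sc, rex = 0)
  plus <- forward_rates(j, sc, rex = 3.7)
  expect_equal(plus$r2 - base$r2, 3.7, tolerance = 1e-12)
  expect_equal(plus$r1, base$r1)
  expect_equal(plus$noe, base$noe)
  expect_error(forward_rates(function(w) -1e-9, sc), "non-negative")
})

test_that("reduced mapping inverts the lumped forward equations to 10 digits", {
  sc <- spin_constants()
  # the J(0) value echoes the unmodified-protein summary statistic
  triples <- list(c(4.2, 0.30, 0.010), c(11.4, 0.25, 0.005),
                  c(2.0, 0.4, 0.02))
  set.seed(42)
  for (k in 1:20)
    triples[[length(triples) + 1]] <- c(runif(1, 0.5, 15), runif(1, 0.05, 0.5),
                                        runif(1, 0.001, 0.05))
  for (tr in triples) {
    fr <- forward_rates_reduced(tr[1], tr[2], tr[3], sc)
    rec <- data.frame(residue = "1", r1 = fr$r1, r1_err = 0, r2 = fr$r2,
                      r2_err = 0, noe = fr$noe, noe_err = 0)
    jj <- reduced_spectral_density(rec, sc)
    expect_equal(jj$j0, tr[1], tolerance = 1e-10)
    expect_equal(jj$j_wn, tr[2], tolerance = 1e-10)
    expect_equal(jj$j_wh, tr[3], tolerance = 1e-10)
    expect_true(all(jj$valid_j0, jj$valid_j_wn, jj$valid_j_wh))
  }
})

test_that("rigid-rotor J(0) is recovered within the lumping approximation", {
  sc <- spin_constants()
  for (tm in c(2, 5, 10, 15, 20)) {
    # model-free closed form: J(0) = (2/5) tau_m
    expect_equal(model_free_j(0, 1, tm) * 1e9, 0.4 * tm, tolerance = 1e-12)
    r <- forward_rates(function(w) model_free_j(w, 1, tm), sc)
    rec <- data.frame(residue = "1", r1 = r$r1, r1_err = 0, r2 = r$r2,
                      r2_err = 0, noe = r$noe, noe_err = 0)
    jj <- reduced_spectral_density(rec, sc)
    expect_lt(abs(jj$j0 - 0.4 * tm) / (0.4 * tm), 0.05)
  }
})

test_that("NOE = 1 maps to exactly zero high-frequency density", {
  sc <- spin_constants()
  rec <- data.frame(residue = "1", r1 = 1.5, r1_err = 0.02, r2 = 10,
                    r2_err = 0.1, noe = 1, noe_err = 0.01)
  jj <- reduced_spectral_density(rec, sc)
  expect_equal(jj$j_wh, 0)
})

test_that("mapped J(0) increases strictly with R2 at fixed R1 and NOE", {
  sc <- spin_constants()
  r2s <- seq(5, 25, by = 2.5)
  j0 <- vapply(r2s, function(r2) {
    rec <- data.frame(residue = "1", r1 = 1.4, r1_err = 0, r2 = r2,
                      r2_err = 0, noe = 0.8, noe_err = 0)
    reduced_spectral_density(rec, sc)$j0
  }, 0)
  expect_true(all(diff(j0) > 0))
})

test_that("negative mapped values are flagged, not clamped", {
  sc <- spin_constants()
  # an unphysically low R2 drives J(0) negative
  rec <- data.frame(residue = "1", r1 = 2.5, r1_err = 0, r2 = 0.3,
                    r2_err = 0, noe = 0.6, noe_err = 0)
  jj <- reduced_spectral_density(rec, sc)
  expect_lt(jj$j0, 0)
  expect_false(jj$valid_j0)
  expect_error(reduced_spectral_density(
    data.frame(residue = "1", r1 = 0, r1_err = 0, r2 = 5, r2_err = 0,
               noe = 0.8, noe_err = 0), sc), "zero R1")
})

test_that("analytic error propagation agrees with a Monte Carlo oracle", {
  sc <- spin_constants()
  r <- forward_rates(function(w) model_free_j(w, 0.85, 8, tau_e = 30), sc)
  errs <- c(r1 = 0.03 * r$r1, r2 = 0.03 * r$r2, noe = 0.04)
  rec <- data.frame(residue = "1", r1 = r$r1, r1_err = errs[["r1"]],
                    r2 = r$r2, r2_err = errs[["r2"]], noe = r$noe,
                    noe_err = errs[["noe"]])
  jj <- reduced_spectral_density(rec, sc)
  # oracle: resample rates from their stated errors, map each draw, take SDs
  set.seed(314)
  n <- 4000
  draws <- vapply(seq_len(n), function(i) {
    rec_i <- data.frame(residue = "1",
                        r1 = rnorm(1, r$r1, errs[["r1"]]), r1_err = 0,
                        r2 = rnorm(1, r$r2, errs[["r2"]]), r2_err = 0,
                        noe = rnorm(1, r$noe, errs[["noe"]]), noe_err = 0)
    jm <- reduced_spectral_density(rec_i, sc)
    c(jm$j0, jm$j_wn, jm$j_wh)
  }, numeric(3))
  mc_sd <- apply(draws, 1, sd)
  analytic <- c(jj$j0_err, jj$j_wn_err, jj$j_wh_err)
  expect_true(all(abs(analytic - mc_sd) / mc_sd < 0.15))
})

test_that("isotropic tau_c is recovered from trimmed R2/R1", {
  sc <- spin_constants()
  # 12 rigid residues, no noise
  mf <- model_free_params(1:12, s2 = 1, tau_m = 8)
  sim <- simulate_relaxation_dataset(
    relax_sim_params(mf, noise_fraction = 0, seed = 21))
  rec <- data.frame(residue = sim$truth$residue, r1 = sim$truth$r1,
                    r1_err = 0, r2 = sim$truth$r2, r2_err = 0,
                    noe = sim$truth$noe, noe_err = 0)
  tau <- estimate_tauc_isotropic(rec, trim_fraction = 0)
  expect_equal(tau, 8, tolerance = 5e-4)
  # 20% of residues exchange-broadened: trimming keeps the estimate honest
  mf2 <- model_free_params(1:20, s2 = 1, tau_m = 8,
                           rex = c(rep(0, 16), rep(5, 4)))
  sim2 <- simulate_relaxation_dataset(
    relax_sim_params(mf2, noise_fraction = 0, seed = 22))
  rec2 <- data.frame(residue = sim2$truth$residue, r1 = sim2$truth$r1,
                     r1_err = 0, r2 = sim2$truth$r2, r2_err = 0,
                     noe = sim2$truth$noe, noe_err = 0)
  tau2 <- estimate_tauc_isotropic(rec2, trim_fraction = 0.3)
  expect_lt(abs(tau2 - 8) / 8, 0.05)
  expect_error(estimate_tauc_isotropic(rec2, trim_fraction = 1),
               "trim_fraction")
  expect_error(estimate_tauc_isotropic(rec2[1:4, ], trim_fraction = 0),
               "5 residues")
})

test_that("J(0) ratio profiles summarize modified vs unmodified tables", {
  sc <- spin_constants()
  tab <- function(tm, n = 8) {
    r <- forward_rates(function(w) model_free_j(w, 1, tm), sc)
    rec <- data.frame(residue = as.character(1:n), r1 = r$r1,
                      r1_err = 0.01, r2 = r$r2, r2_err = 0.05, noe = r$noe,
                      noe_err = 0.01)
    reduced_spectral_density(rec, sc)
  }
  t4 <- tab(4); t8 <- tab(8)
  # identical tables: all ratios 1, SD 0
  same <- jratio_profile(t4, t4)
  expect_equal(same$profile$ratio, rep(1, 8))
  expect_equal(same$sd, 0)
  # doubled table: all ratios 2
  doubled <- t4
  doubled$j0 <- 2 * t4$j0
  expect_equal(jratio_profile(doubled, t4)$profile$ratio, rep(2, 8))
  # 8 ns vs 4 ns rigid rotors: mean ratio equals the mapped-J0 quotient,
  # which in turn tracks the model-free closed form at the lumping accuracy
  prof <- jratio_profile(t8, t4)
  expect_equal(prof$mean, t8$j0[1] / t4$j0[1], tolerance = 1e-10)
  closed <- (model_free_j(0, 1, 8) / model_free_j(0, 1, 4))
  expect_equal(prof$mean, closed, tolerance = 0.1 * closed)
  expect_equal(prof$summary_unmodified$mean, t4$j0[1], tolerance = 1e-10)
  # disjoint residue sets are rejected
  t4b <- t4
  t4b$residue <- as.character(101:108)
  expect_error(jratio_profile(t8, t4b), "shared")
})

test_that("exchange broadening inflates mapped J(0) against Rex-free twins", {
  sc <- spin_constants()
  mf <- model_free_params(1:10, s2 = 0.88, tau_m = 8,
                          rex = c(rep(0, 5), rep(4, 5)))
  sim <- simulate_relaxation_dataset(
    relax_sim_params(mf, noise_fraction = 0, seed = 33))
  rec <- data.frame(residue = sim$truth$residue, r1 = sim$truth$r1,
                    r1_err = 0, r2 = sim$truth$r2, r2_err = 0,
                    noe = sim$truth$noe, noe_err = 0)
  jj <- reduced_spectral_density(rec, sc)
  free <- jj$j0[1:5]; loaded <- jj$j0[6:10]
  expect_true(all(loaded > free))
})

test_that("chemical shift perturbation follows the weighted closed form", {
  a <- peak_list(c(5, 6, 7), h_ppm = c(8.0, 8.2, 7.9),
                 n_ppm = c(120, 118, 125))
  expect_equal(compute_csp(a, a)$csp, rep(0, 3))
  b <- peak_list(c(5, 6, 7), h_ppm = c(8.02, 8.2, 7.9),
                 n_ppm = c(120.10, 118, 125))
  csp <- compute_csp(a, b)
  expect_equal(csp$csp[1], sqrt(0.02^2 + (0.14 * 0.10)^2), tolerance = 1e-12)
  expect_equal(csp$csp[1], 0.0244, tolerance = 1e-3)
  # unmatched residues are excluded with a message
  c_list <- peak_list(c(6, 7, 99), h_ppm = c(8.2, 7.9, 9.1),
                      n_ppm = c(118, 125, 130))
  expect_message(out <- compute_csp(a, c_list), "excluded")
  expect_equal(out$residue, c("6", "7"))
  expect_error(compute_csp(a, peak_list(50, 8, 120)), "shared")
})

test_that("relaxation records assemble rates with propagated errors", {
  mf <- model_free_params(1:4, s2 = 0.85, tau_m = 8)
  out <- sim_relaxation_records(mf, seed = 55, noise_fraction = 0.02,
                                mc_iterations = 40)
  rec <- out$records
  expect_equal(nrow(rec), 4L)
  expect_true(all(rec$r1 > 0 & rec$r2 > 0))
  expect_true(all(rec$r1_err >= 0 & rec$r2_err >= 0 & rec$noe_err >= 0))
  # rates land near the generating truth at 2% noise
  expect_equal(rec$r1, out$sim$truth$r1, tolerance = 0.1)
  expect_equal(rec$r2, out$sim$truth$r2, tolerance = 0.1)
})
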