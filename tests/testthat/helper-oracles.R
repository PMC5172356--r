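# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# textbook pooled-variance two-sample t test (two-tailed)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# continuous barycentric mean of a truncated Gaussian band by quadrature
truncated_gaussian_centroid <- function(mu, sigma, lo, hi) {
  f <- function(x) exp(-(x - mu)^2 / (2 * sigma^2))
  num <- integrate(function(x) x * f(x), lo, hi, rel.tol = 1e-12)$value
  den <- integrate(f, lo, hi, rel.tol = 1e-12)$value
  num / den
}

# discrete centroid of a pure emission band on the simulator's grid
grid_band_centroid <- function(center, width, grid = seq(310, 400, by = 1)) {
  b <- exp(-(grid - center)^2 / (2 * width^2))
  sum(grid * b) / sum(b)
}

# run the full relaxation pipeline (simulate -> fit -> records)
sim_relaxation_records <- function(mf, seed = 1, noise_fraction = 0.02,
                                   mc_iterations = 60, field_mhz = 600.13) {
  sim <- simulate_relaxation_dataset(relax_sim_params(
    mf, field_mhz = field_mhz, noise_fraction = noise_fraction, seed = seed))
  t1 <- lapply(seq_along(sim$t1_curves), function(i)
    fit_exponential(sim$t1_curves[[i]], mc_iterations = mc_iterations,
                    seed = seed + 7000 + i))
  t2 <- lapply(seq_along(sim$t2_curves), function(i)
    fit_exponential(sim$t2_curves[[i]], mc_iterations = mc_iterations,
                    seed = seed + 8000 + i))
  noe <- suppressWarnings(compute_hnnoe(sim$noe))
  list(records = relaxation_records(t1, t2, noe, field_mhz = field_mhz),
       sim = sim)
}
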