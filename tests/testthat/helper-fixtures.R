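# Reference rate set: fast bimolecular step (K_bi = 5000 M^-1), branch
# constants chosen so keq_ze = 4 and k1Z/k1E = 2.
example_rates <- function() {
  rate_constants(k1 = 10, k_m1 = 0.002, k1Z = 0.02, k_m1Z = 0.002,
                 k1E = 0.01, k_m1E = 0.004)
}

# Direct log-uniform draws over the simulation-study ranges (bimolecular
# Keq 1000-10000 M^-1, unimolecular Keq 1-20), without the timescale
# calibration of sample_rate_constants; used by the oracle/property suites.
draw_raw_rates <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    K_bi <- exp(runif(1, log(1000), log(10000)))
    KZ <- exp(runif(1, log(1), log(20)))
    KE <- exp(runif(1, log(1), log(20)))
    k1Z <- exp(runif(1, log(1e-3), log(1e-1)))
    k1E <- exp(runif(1, log(1e-3), log(1e-1)))
    k_m1 <- exp(runif(1, log(1e-3), log(1e-1)))
    rate_constants(k1 = K_bi * k_m1, k_m1 = k_m1,
                   k1Z = k1Z, k_m1Z = k1Z / KZ,
                   k1E = k1E, k_m1E = k1E / KE)
  })
}

# Log-spaced grid from t0 through t_end hitting both ratio limits.
limits_grid <- function(rates, a0 = 1e-3) {
  t0 <- 1e-3 / max(rates$k1Z, rates$k_m1Z, rates$k1E, rates$k_m1E)
  t_end <- 500 / min(rates$k1Z, rates$k_m1Z, rates$k1E, rates$k_m1E,
                     rates$k_m1, rates$k1 * a0)
  c(0, exp(seq(log(t0), log(t_end), length.out = 80)))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
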