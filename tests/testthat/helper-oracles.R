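# Independent oracles and small fixtures shared across tests.

# Uniform phase grid covering `cycles` whole cycles in n samples.
uniform_phase_grid <- function(n, cycles = 1L) {
  2 * pi * cycles * (seq_len(n) - 1L) / n
}

# Explicit per-sample loop implementation of debiased PAC (the oracle the
# vectorized implementation is checked against).
dpac_loop <- function(phi, amp) {
  n <- length(phi)
  pc <- 0 + 0i
  for (t in seq_len(n)) pc <- pc + exp(1i * phi[t])
  pc <- pc / n
  s <- 0 + 0i
  for (t in seq_len(n)) s <- s + amp[t] * (exp(1i * phi[t]) - pc)
  Mod(s / n)
}

# Exhaustive pair-counting Mann-Whitney U (wins for a, ties counted half).
u_pair_count <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Brute-force Benjamini-Yekutieli step-up adjustment.
by_step_up <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m * cm / seq(i, m)) * ps[seq(i, m)]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Cheap preprocessed null epochs for unit tests (generated at the analysis
# rate so no decimation step is needed).
quick_null_series <- function(seed, n_epochs = 4L, phase_bias = 0,
                              pac_depth = 0) {
  cfg <- sim_config(sampling_rate = 128, n_epochs = n_epochs,
                    pac_depth = pac_depth, phase_bias = phase_bias,
                    noise_sd = 0.5, seed = seed)
  preprocess_epochs(generate_aac_epochs(cfg))
}
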