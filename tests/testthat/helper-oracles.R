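# Naive per-cell GKL reference, independent of the vectorised engine.
naive_gkl <- function(v) {
  L <- length(v)
  wrap <- function(j) v[((j - 1) %% L) + 1]
  out <- integer(L)
  for (i in seq_len(L)) {
    trio <- if (v[i] == 0) {
      c(v[i], wrap(i - 1), wrap(i - 3))
    } else {
      c(v[i], wrap(i + 1), wrap(i + 3))
    }
    out[i] <- as.integer(sum(trio) >= 2)
  }
  out
}

# Reference health dynamics: a plain per-agent loop built on the exported
# pure helpers (mix_health / support_update), used as an independent route
# against the vectorised cohort engine. Assumes p_noise = 1 (every unlocked
# embryo hit each step) and a theta low enough that no embryo ever takes the
# random rule, so the engine consumes RNG only for the initial states and the
# per-step exposure draws, which this loop mirrors.
reference_health_trajectory <- function(config, seed) {
  set.seed(seed)
  n <- config$n
  grid <- cohort_grid(n, config$topology)
  for (i in seq_len(n)) eca_init(config$eca) # consume the state draws
  h <- rep(1, n)
  ever <- logical(n)
  b <- rep(0, n)
  b_on <- logical(n)
  traj <- matrix(NA_real_, config$eca$steps, n)
  for (t in seq_len(config$eca$steps)) {
    h_prev <- h
    runif(n) # exposure draws (all hit at p_noise = 1)
    h <- pmax(0, h - config$n_dec)
    ever <- rep(TRUE, n)
    stress <- h
    for (i in seq_len(n)) {
      part_nb <- grid$nb[[i]][ever[grid$nb[[i]]]]
      part_nn <- grid$nn[[i]][ever[grid$nn[[i]]]]
      h[i] <- mix_health(h[i], h_prev[part_nb], h_prev[part_nn],
                         config$w_self, config$w_nb, config$w_nn)
    }
    h_mixed <- h
    for (i in seq_len(n)) {
      snb <- grid$nb[[i]][b_on[grid$nb[[i]]]]
      snn <- grid$nn[[i]][b_on[grid$nn[[i]]]]
      h[i] <- support_update(h_mixed[i],
                             self_signal = if (b_on[i]) b[i] else NULL,
                             nb_signal = b[snb], nn_signal = b[snn],
                             w_self = config$w_self, w_nb = config$w_nb,
                             w_nn = config$w_nn)
    }
    b <- stress
    b_on <- ever
    traj[t, ] <- h
  }
  traj
}
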