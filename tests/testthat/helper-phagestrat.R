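# Shared fixtures: everything is generated in code at test time.

ref_params <- function(...) phage_params(...)

# short-horizon spec for cheap integration tests
quick_spec <- function(strategy, N0 = 2, t_end = 2000, ...) {
  p <- phage_params(N0 = N0, ...)
  simulation_spec(strategy, p, initial_state = phage_state(N = N0),
                  t_end = t_end)
}

# build a phage_trajectory by hand (for classification tests that need
# exactly controlled component levels)
synthetic_trajectory <- function(levels, t_end = 100, n = 101,
                                 transient_fraction = 0) {
  tt <- seq(0, t_end, length.out = n)
  df <- data.frame(time_h = tt)
  for (v in c("B1", "B2", "I1", "I2", "P1", "P2", "N"))
    df[[v]] <- rep_len(levels[[v]], n)
  spec <- simulation_spec("lytic", phage_params(), t_end = t_end,
                          transient_fraction = transient_fraction)
  structure(df, spec = spec, class = c("phage_trajectory", "data.frame"))
}

# closed-form single-species chemostat equilibrium (independent oracle)
chemostat_equilibrium <- function(p, y = p$y1) {
  Nstar <- 1 / (y - 1)
  list(N = Nstar, B = p$D * (p$N0 - Nstar) / p$x)
}
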