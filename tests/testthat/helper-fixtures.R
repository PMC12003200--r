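# shared fixture builders (everything generated in code; no stored data)

# a small valid localization table with optional NA photometrics
make_loc_table <- function(n = 30, n_traces = 3, seed = 1,
                           channel = "scaffold", with_na = FALSE) {
  set.seed(seed)
  trace <- rep(seq_len(n_traces), length.out = n)
  ord <- order(trace)
  trace <- trace[ord]
  t <- as.vector(unlist(tapply(seq_len(n), trace, function(i)
    cumsum(runif(length(i), 0.001, 0.003)), simplify = FALSE)))
  efo <- runif(n, 25, 60)
  cfr <- runif(n, 0.2, 0.8)
  df <- localizations(trace_id = trace, t = t,
                      x = rnorm(n, 0, 100), y = rnorm(n, 0, 100),
                      z = rnorm(n, 0, 50),
                      efo = efo, efc = cfr * efo, cfr = cfr,
                      dcr = runif(n), channel = channel)
  if (with_na) {
    df$dcr[seq(1, n, by = 3)] <- NA
    df$efc[seq(2, n, by = 5)] <- NA
  }
  df
}

# pore-frame track with a prescribed z path (deterministic)
make_pore_track <- function(z, r = 23, theta_deg = 40, t0 = 0, dt = 0.002,
                            track_id = 1L) {
  n <- length(z)
  th <- theta_deg * pi / 180
  seg <- data.frame(trace_id = track_id, t = t0 + (seq_len(n) - 1) * dt,
                    x = r * cos(th) + 0 * z, y = r * sin(th) + 0 * z, z = z,
                    efo = 30, efc = 15, cfr = 0.5, dcr = 0.5,
                    channel = "cargo",
                    xp = r * cos(th) + 0 * z, yp = r * sin(th) + 0 * z,
                    zp = z)
  attr(seg, "track_id") <- track_id
  attr(seg, "pore_id") <- 1L
  attr(seg, "double_dye_flag") <- FALSE
  seg
}

# standard three-species "red model" conditions used in recovery tests
red_model_species <- function() {
  list(species_spec(weight = 0.07, D = 0, sigma_x = 4.1),
       species_spec(weight = 0.56, D = 0, sigma_x = 8.2),
       species_spec(weight = 0.37, D = 0.055, sigma_x = 8.2))
}

cargo_timesteps <- function() {
  timestep_model("geometric_retry", base_ms = 0.55, retry_p = 0.75)
}
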