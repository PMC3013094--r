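# shared fixtures: standard fresh-water tunnel and a noiseless truth
std_tunnel <- function(volume = 1.8) {
  tunnel_spec(volume = volume, temperature = 28, salinity = 0,
              barometric_pressure = 101.325)
}

noiseless_truth <- function(seed = 1L, ...) {
  synthetic_truth(seed = seed, trace_noise_sd = 0, ct_noise_sd = 0, ...)
}

# build an oxygen trace declining linearly in concentration units
linear_trace <- function(slope_umol_l_h, spec, duration = 1200, by = 2,
                         start_pct = 100, noise_sd = 0, fish_id = "f1") {
  sat <- o2_saturation(spec$temperature, spec$salinity,
                       spec$barometric_pressure)
  t_s <- seq(0, duration, by = by)
  conc <- sat * start_pct / 100 + slope_umol_l_h * t_s / 3600
  pct <- conc / sat * 100
  if (noise_sd > 0) pct <- pct + rnorm(length(pct), 0, noise_sd)
  oxygen_trace(t_s, pct, phase = "closed", fish_id = fish_id)
}
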