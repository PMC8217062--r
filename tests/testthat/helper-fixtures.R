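# Shared fixtures: experiment-like configurations and a random-case
# generator for property tests.  All randomness is seeded locally so the
# suite is reproducible.

set_a <- function(flow_ml_min = 0, tin_c = NULL, t0_c = NULL)
  preset_config("setA", flow_ml_min = flow_ml_min, tin_c = tin_c,
                t0_c = t0_c)

set_b <- function(flow_ml_min = 0, tin_c = NULL, t0_c = NULL)
  preset_config("setB", flow_ml_min = flow_ml_min, tin_c = tin_c,
                t0_c = t0_c)

std_burst <- function(power_w = 40) laser_schedule(20, 80, power_w)

# constant-temperature trace (time grid in seconds)
const_trace <- function(temp_c, duration_s, dt = 1) {
  tt <- seq(0, duration_s, by = dt)
  temperature_trace(tt, rep(temp_c, length(tt)), label = "const")
}

# random non-degenerate configuration with a relaxation time >= ~2 s so a
# fixed-step oracle at dt = 0.01 s stays well-resolved
random_config <- function() {
  v <- runif(1, 4, 100)          # mL
  q <- runif(1, 0, 40)           # mL/min
  b <- runif(1, 0.3, 3)          # W/°C
  system_config(volume_ml = v, t0_c = runif(1, 20, 38),
                beta_w_per_c = b, flow_ml_min = q,
                tin_c = runif(1, 15, 38))
}

random_schedule <- function(t_max = 180) {
  n <- sample(1:3, 1)
  bounds <- sort(runif(2 * n, 1, t_max))
  laser_schedule(bounds[seq(1, 2 * n, 2)], bounds[seq(2, 2 * n, 2)],
                 runif(n, 0, 60))
}
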