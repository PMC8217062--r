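# Synthetic thermocouple traces: the analytic model sampled on the
# experimental grid plus seeded i.i.d. Gaussian measurement noise.  The
# default grid mirrors the validation experiments: two laser powers
# (10, 40 W) x three flow rates (0, 20, 40 mL/min) x five runs, sampled at
# 0.1 s with 20 s pre-laser irrigation, 60 s firing and 20 s decay.

#' Generate one synthetic thermocouple run
#'
#' Samples the analytic model on a regular grid and adds independent
#' Gaussian measurement noise.  With `noise_sigma = 0` the model curve is
#' reproduced exactly; with a `seed` the trace is bit-reproducible and the
#' caller's RNG state is left untouched.
#'
#' @inheritParams simulate_trace
#' @param noise_sigma Measurement noise standard deviation, °C
#'   (default 0.2 °C, a plausible T-type thermocouple precision).
#' @param sample_dt Sampling interval, s (default 0.1 s).
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param t_end End of the recording, s (default 20 s past last laser-off).
#' @param label Trace label.
#' @return A [temperature_trace()].
#' @export
#' @examples
#' cfg <- preset_config("setB", flow_ml_min = 20)
#' tr <- generate_run(cfg, laser_schedule(20, 80, 40), seed = 1)
generate_run <- function(cfg, schedule, noise_sigma = 0.2, sample_dt = 0.1,
                         seed = NULL, t_end = max(schedule$off) + 20,
                         label = "synthetic") {
  stopifnot(is.numeric(noise_sigma), length(noise_sigma) == 1L,
            noise_sigma >= 0, is.numeric(sample_dt), sample_dt > 0)
  times <- seq(0, t_end, by = sample_dt)
  temps <- temperature_at(cfg, schedule, times)
  if (noise_sigma > 0) {
    eps <- if (is.null(seed)) rnorm(length(times), 0, noise_sigma)
           else withr::with_seed(as.integer(seed),
                                 rnorm(length(times), 0, noise_sigma))
    temps <- temps + eps
  }
  temperature_trace(times, temps, label = label)
}

#' Specify a synthetic experiment grid
#'
#' The defaults reproduce the validation study design: laser settings of
#' 1 J x 40 Hz (40 W) and 0.5 J x 20 Hz (10 W), flow rates of 0, 20 and
#' 40 mL/min, five runs per cell, recorded at 0.1 s intervals with the
#' 20 s / 60 s / 20 s pre-fire/fire/decay timing.
#'
#' @param preset `"setA"` or `"setB"` vessel/bath conditions.
#' @param powers_w Laser powers, W.
#' @param flows_ml_min Irrigation flow rates, mL/min.
#' @param runs_per_cell Replicate runs per (power, flow) cell; `>= 1`.
#' @param noise_sigma Measurement noise SD, °C.
#' @param sample_dt Sampling interval, s.
#' @param seed Integer master seed; per-run sub-seeds are derived from it.
#' @return An object of class `experiment_grid` (a list of the settings).
#' @export
experiment_grid <- function(preset = c("setA", "setB"),
                            powers_w = c(10, 40),
                            flows_ml_min = c(0, 20, 40),
                            runs_per_cell = 5, noise_sigma = 0.2,
                            sample_dt = 0.1, seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(runs_per_cell >= 1, sample_dt > 0, noise_sigma >= 0,
            length(powers_w) >= 1, length(flows_ml_min) >= 1)
  structure(list(preset = preset, powers_w = powers_w,
                 flows_ml_min = flows_ml_min,
                 runs_per_cell = as.integer(runs_per_cell),
                 noise_sigma = noise_sigma, sample_dt = sample_dt,
                 seed = as.integer(seed)),
            class = "experiment_grid")
}

# deterministic per-run sub-seed, kept inside 32-bit integer range
run_seed <- function(master, cell, run) {
  as.integer((as.numeric(master) %% 1000003 + 7919 * cell + 104729 * run) %%
               2147483647)
}

#' Generate a full synthetic experiment grid
#'
#' One trace per (power, flow, run) combination, each with its own sub-seed
#' derived from the master seed so any subset can be regenerated
#' reproducibly.  The manifest maps trace names to their settings.
#'
#' @param spec An [experiment_grid()] specification.
#' @param beta_true Wall-loss coefficient used for generation, W/°C
#'   (default: the preset's fitted value).
#' @param t1_s,tf_s Laser-on time and firing time, s.
#' @return A list with `traces` (named list of [temperature_trace()]) and
#'   `manifest` (data frame: `name`, `power_w`, `flow_ml_min`, `run`,
#'   `seed`, `preset`, `beta_true`).
#' @export
#' @examples
#' grid <- generate_grid(experiment_grid("setB", runs_per_cell = 1,
#'                                       sample_dt = 0.5))
#' grid$manifest
generate_grid <- function(spec, beta_true = NULL, t1_s = 20, tf_s = 60) {
  if (!inherits(spec, "experiment_grid"))
    stop("'spec' must be an experiment_grid", call. = FALSE)
  base <- preset_config(spec$preset)
  if (is.null(beta_true)) beta_true <- base$beta
  cells <- expand.grid(power_w = spec$powers_w,
                       flow_ml_min = spec$flows_ml_min,
                       KEEP.OUT.ATTRS = FALSE)
  traces <- list()
  manifest <- list()
  for (ci in seq_len(nrow(cells))) {
    cfg <- preset_config(spec$preset, flow_ml_min = cells$flow_ml_min[ci])
    cfg <- set_beta(cfg, beta_true)
    sched <- single_burst(cells$power_w[ci], tf_s = tf_s, t1_s = t1_s)
    for (run in seq_len(spec$runs_per_cell)) {
      sd_i <- run_seed(spec$seed, ci, run)
      nm <- sprintf("%s_W%g_Q%g_run%d", spec$preset, cells$power_w[ci],
                    cells$flow_ml_min[ci], run)
      traces[[nm]] <- generate_run(cfg, sched,
                                   noise_sigma = spec$noise_sigma,
                                   sample_dt = spec$sample_dt,
                                   seed = sd_i, label = nm)
      manifest[[length(manifest) + 1L]] <-
        data.frame(name = nm, power_w = cells$power_w[ci],
                   flow_ml_min = cells$flow_ml_min[ci], run = run,
                   seed = sd_i, preset = spec$preset,
                   beta_true = beta_true)
    }
  }
  list(traces = traces, manifest = do.call(rbind, manifest))
}
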