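# Domain types: fluid properties, system configuration, laser schedule,
# temperature trace.  Clinical units (mL, mL/min, °C, W, s) at the interface;
# strictly SI (m^3, m^3/s, W) internally.  The model is linear with an offset,
# so temperatures stay in °C throughout.

ML_TO_M3 <- 1e-6
ML_MIN_TO_M3_S <- 1e-6 / 60

#' Thermal properties of the irrigation fluid
#'
#' Defaults are water at 25 °C: conductivity 0.606 W/(m K), density
#' 1000 kg/m^3, specific heat 4180 J/(kg K).  Conductivity is carried for
#' configuration fidelity but does not enter the lumped solution (wall loss
#' is parameterised directly by the coefficient `beta` of [system_config()]).
#'
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param rho Density, kg m^-3.
#' @param c Specific heat capacity, J kg^-1 K^-1.
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' fluid_properties()         # water
fluid_properties <- function(k = 6.06e-1, rho = 1.00e3, c = 4.18e3) {
  for (nm in c("k", "rho", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("fluid property '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(list(k = k, rho = rho, c = c), class = "fluid_properties")
}

#' System configuration for the lumped thermal model
#'
#' Describes the fluid-filled vessel: its volume, the bath/initial
#' temperature, the wall heat-loss coefficient beta = h*s (heat-transfer
#' coefficient times exchange area, fitted per vessel), and the irrigation
#' inflow.  Arguments are in clinical units and converted to SI on ingestion.
#'
#' @param volume_ml Vessel volume, mL.
#' @param t0_c Bath and initial fluid temperature, °C.
#' @param beta_w_per_c Wall heat-loss coefficient, W/°C.  May be `NA` when
#'   the configuration is used as a template for [fit_beta()].
#' @param flow_ml_min Irrigation flow rate, mL/min.
#' @param tin_c Irrigation fluid temperature, °C (defaults to `t0_c`).
#' @param fluid A [fluid_properties()] object.
#' @return An object of class `system_config` with SI fields `V` (m^3),
#'   `Q` (m^3/s), plus `T0`, `Tin` (°C), `beta` (W/°C) and `fluid`.
#' @seealso [preset_config()] for the Set A / Set B experimental presets.
#' @export
#' @examples
#' cfg <- system_config(volume_ml = 38.3, t0_c = 22, beta_w_per_c = 1.36)
#' cfg
system_config <- function(volume_ml, t0_c, beta_w_per_c,
                          flow_ml_min = 0, tin_c = t0_c,
                          fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  num1 <- function(x, nm, allow_na = FALSE) {
    if (allow_na && length(x) == 1L && is.na(x)) return(NA_real_)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  volume_ml <- num1(volume_ml, "volume_ml")
  flow_ml_min <- num1(flow_ml_min, "flow_ml_min")
  beta <- num1(beta_w_per_c, "beta_w_per_c", allow_na = TRUE)
  t0_c <- num1(t0_c, "t0_c")
  tin_c <- num1(tin_c, "tin_c")
  if (volume_ml <= 0) stop("vessel volume must be positive", call. = FALSE)
  if (flow_ml_min < 0) stop("flow rate must be non-negative", call. = FALSE)
  if (!is.na(beta) && beta < 0)
    stop("beta must be non-negative", call. = FALSE)
  structure(
    list(V = volume_ml * ML_TO_M3, T0 = t0_c, beta = beta,
         Q = flow_ml_min * ML_MIN_TO_M3_S, Tin = tin_c, fluid = fluid),
    class = "system_config")
}

#' @export
print.system_config <- function(x, ...) {
  cat("Lumped thermal system configuration\n")
  cat(sprintf("  volume      : %.4g mL\n", x$V / ML_TO_M3))
  cat(sprintf("  irrigation  : Q = %.4g mL/min at Tin = %.4g °C\n",
              x$Q / ML_MIN_TO_M3_S, x$Tin))
  cat(sprintf("  bath/initial: T0 = %.4g °C\n", x$T0))
  cat(sprintf("  wall loss   : beta = %s W/°C\n",
              if (is.na(x$beta)) "NA (to be fitted)"
              else sprintf("%.4g", x$beta)))
  invisible(x)
}

# replace beta (used by the fitter)
set_beta <- function(cfg, beta) {
  cfg$beta <- beta
  cfg
}

#' Experimental preset configurations
#'
#' Two in-vitro validation settings.  Set A: 5.89 mL test tube in a 37 °C
#' water bath, irrigated at 23 °C, fitted wall-loss coefficient
#' beta = 1.15 W/°C.  Set B: 38.3 mL cylindrical vessel at room temperature
#' (22 °C bath and irrigation), beta = 1.36 W/°C.  Best-fit values near 1.14
#' have also been reported for Set A; the preset carries 1.15.
#'
#' @param preset `"setA"` or `"setB"` (case-insensitive).
#' @param flow_ml_min Irrigation flow rate to install, mL/min.
#' @param tin_c Optional override of the irrigation temperature, °C.
#' @param t0_c Optional override of the bath/initial temperature, °C.
#' @return A [system_config()].
#' @export
#' @examples
#' preset_config("setA", flow_ml_min = 20)
preset_config <- function(preset = c("setA", "setB"), flow_ml_min = 0,
                          tin_c = NULL, t0_c = NULL) {
  preset <- match.arg(tolower(preset[1L]), c("seta", "setb"))
  base <- switch(preset,
    seta = list(volume_ml = 5.89, t0_c = 37, tin_c = 23,
                beta_w_per_c = 1.15),
    setb = list(volume_ml = 38.3, t0_c = 22, tin_c = 22,
                beta_w_per_c = 1.36))
  if (!is.null(t0_c)) base$t0_c <- t0_c
  if (!is.null(tin_c)) base$tin_c <- tin_c
  system_config(volume_ml = base$volume_ml, t0_c = base$t0_c,
                beta_w_per_c = base$beta_w_per_c,
                flow_ml_min = flow_ml_min, tin_c = base$tin_c)
}

#' Laser on/off schedule
#'
#' An ordered set of non-overlapping laser firing intervals with their
#' powers.  The single-burst case (laser on at `t1`, off at `t2 = t1 + tf`)
#' is the one-interval schedule; arbitrary operator duty cycles are longer
#' lists.
#'
#' @param on_s,off_s Numeric vectors of on/off times, s; `0 <= on < off`,
#'   intervals sorted and non-overlapping.
#' @param power_w Laser power per interval, W (recycled if scalar).
#' @return An object of class `laser_schedule`: a data frame with columns
#'   `on`, `off`, `W`.
#' @export
#' @examples
#' laser_schedule(20, 80, 40)                    # one 60 s burst at 40 W
#' laser_schedule(c(0, 30), c(10, 50), c(40, 10))
laser_schedule <- function(on_s, off_s, power_w) {
  if (length(on_s) != length(off_s))
    stop("'on_s' and 'off_s' must have equal length", call. = FALSE)
  if (length(on_s) == 0L) stop("schedule must have >= 1 interval",
                               call. = FALSE)
  power_w <- rep_len(as.numeric(power_w), length(on_s))
  if (any(!is.finite(on_s)) || any(!is.finite(off_s)) ||
      any(!is.finite(power_w)))
    stop("schedule entries must be finite", call. = FALSE)
  if (any(on_s < 0) || any(off_s <= on_s))
    stop("intervals must satisfy 0 <= on < off", call. = FALSE)
  if (is.unsorted(on_s, strictly = TRUE))
    stop("intervals must be sorted by onset", call. = FALSE)
  if (length(on_s) > 1L && any(on_s[-1L] < off_s[-length(off_s)]))
    stop("intervals must not overlap", call. = FALSE)
  if (any(power_w < 0)) stop("laser power must be >= 0", call. = FALSE)
  structure(data.frame(on = as.numeric(on_s), off = as.numeric(off_s),
                       W = power_w),
            class = c("laser_schedule", "data.frame"))
}

#' Single laser burst
#'
#' Convenience wrapper for the standard experiment timing: laser switched on
#' at `t1` and fired for `tf` seconds.
#'
#' @param power_w Laser power, W.
#' @param tf_s Firing time, s.
#' @param t1_s Laser-on time, s (default 20 s of pre-laser irrigation).
#' @return A [laser_schedule()] with one interval.
#' @export
single_burst <- function(power_w, tf_s = 60, t1_s = 20) {
  laser_schedule(t1_s, t1_s + tf_s, power_w)
}

#' Temperature trace
#'
#' A sampled (time, temperature) series, either from the model or from a
#' thermocouple recording.
#'
#' @param times Sample times, s; strictly increasing, length >= 2.
#' @param temps Temperatures, °C; same length as `times`.
#' @param label Free-text probe identifier (default `"model"`).
#' @return An object of class `temperature_trace`: a data frame with columns
#'   `time_s`, `temp_c` and attribute `label`.
#' @export
temperature_trace <- function(times, temps, label = "model") {
  times <- as.numeric(times); temps <- as.numeric(temps)
  if (length(times) != length(temps))
    stop("'times' and 'temps' must have equal length", call. = FALSE)
  if (length(times) < 2L) stop("a trace needs >= 2 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(temps)))
    stop("trace values must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("trace times must be strictly increasing", call. = FALSE)
  structure(data.frame(time_s = times, temp_c = temps),
            label = as.character(label)[1L],
            class = c("temperature_trace", "data.frame"))
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "Temperature trace '%s': %d samples, t = [%.4g, %.4g] s, T = [%.4g, %.4g] °C\n",
    attr(x, "label"), nrow(x), x$time_s[1L], x$time_s[nrow(x)],
    min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

#' Plot a temperature trace
#'
#' Base-graphics convenience plot of temperature against time.
#'
#' @param x A [temperature_trace()].
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.temperature_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$temp_c, type = "l",
                 xlab = "time (s)", ylab = "temperature (°C)",
                 main = attr(x, "label"), ...)
  invisible(x)
}
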