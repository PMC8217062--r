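# Piecewise-analytic solution of the lumped energy balance
#
#   rho*c*V dT/dt = W(t) + rho*c*Q*(Tin - T) - beta*(T - T0)
#
# Within a constant-power phase T relaxes exponentially toward the phase
# steady state Tstar with time constant tau = rho*c*V/(rho*c*Q + beta).
# When Q = 0 and beta = 0 the balance degenerates to linear heating at rate
# W/(rho*c*V) with no steady state.

# phase-local constants for power W (W): either exponential relaxation
# (Tstar, tau) or the degenerate linear branch (slope, °C/s)
phase_params <- function(cfg, W) {
  rc <- cfg$fluid$rho * cfg$fluid$c
  denom <- rc * cfg$Q + cfg$beta
  if (denom > 0) {
    list(type = "exp",
         Tstar = (W + rc * cfg$Q * cfg$Tin + cfg$beta * cfg$T0) / denom,
         tau = rc * cfg$V / denom, slope = NA_real_)
  } else {
    list(type = "linear", Tstar = NA_real_, tau = NA_real_,
         slope = W / (rc * cfg$V))
  }
}

check_cfg <- function(cfg) {
  if (!inherits(cfg, "system_config"))
    stop("'cfg' must be a system_config", call. = FALSE)
  if (is.na(cfg$beta))
    stop("configuration has no beta; supply one or use fit_beta()",
         call. = FALSE)
  invisible(cfg)
}

#' Phase steady state and time constant
#'
#' For a constant laser power the balance of laser heating against advective
#' (irrigation) and wall losses gives an equilibrium temperature
#' \eqn{T^\star = (W + \rho c Q T_{\mathrm{in}} + \beta T_0)/(\rho c Q + \beta)}
#' approached exponentially with time constant
#' \eqn{\tau = \rho c V/(\rho c Q + \beta)}.  \eqn{T^\star} is independent of
#' the vessel volume; \eqn{\tau} is proportional to it.
#'
#' @param cfg A [system_config()].
#' @param power_w Laser power, W.
#' @return A list with elements `Tstar` (°C) and `tau` (s).
#' @section Degenerate case:
#' With `Q = 0` and `beta = 0` all heat stays in the vessel: temperature
#' grows without bound (linearly in time) and no steady state exists; an
#' error is signalled.  [temperature_at()] still handles this regime.
#' @export
#' @examples
#' heat_load(preset_config("setA"), 40)   # Tstar = 37 + 40/1.15, tau ~ 21.4 s
heat_load <- function(cfg, power_w) {
  check_cfg(cfg)
  stopifnot(is.numeric(power_w), length(power_w) == 1L, power_w >= 0)
  pp <- phase_params(cfg, power_w)
  if (pp$type == "linear")
    stop("unbounded heating: Q = 0 and beta = 0 admit no steady state",
         call. = FALSE)
  list(Tstar = pp$Tstar, tau = pp$tau)
}

# Build the full phase decomposition for a schedule: rows are maximal
# constant-power intervals starting at t = 0 (pre-laser W = 0 included);
# the last row extends to Inf.  Tstart is propagated through the analytic
# solution so evaluation within any phase is O(1).
phase_table <- function(cfg, schedule, T_init = cfg$T0) {
  check_cfg(cfg)
  if (!inherits(schedule, "laser_schedule"))
    stop("'schedule' must be a laser_schedule", call. = FALSE)
  bounds <- unique(c(0, t(schedule[, c("on", "off")])))
  powers <- numeric(length(bounds))
  for (i in seq_len(nrow(schedule)))
    powers[bounds >= schedule$on[i] & bounds < schedule$off[i]] <-
      schedule$W[i]
  n <- length(bounds)
  tab <- data.frame(t0 = bounds, t1 = c(bounds[-1L], Inf), W = powers,
                    type = NA_character_, Tstar = NA_real_, tau = NA_real_,
                    slope = NA_real_, Tstart = NA_real_)
  Tcur <- T_init
  for (i in seq_len(n)) {
    pp <- phase_params(cfg, tab$W[i])
    tab$type[i] <- pp$type
    tab$Tstar[i] <- pp$Tstar; tab$tau[i] <- pp$tau; tab$slope[i] <- pp$slope
    tab$Tstart[i] <- Tcur
    if (is.finite(tab$t1[i])) {
      dt <- tab$t1[i] - tab$t0[i]
      Tcur <- if (pp$type == "exp")
        pp$Tstar + (Tcur - pp$Tstar) * exp(-dt / pp$tau)
      else Tcur + pp$slope * dt
    }
  }
  tab
}

# vectorised evaluation of the piecewise solution on a phase table
eval_phases <- function(tab, t) {
  idx <- findInterval(t, tab$t0)   # t >= 0 guaranteed by callers
  dt <- t - tab$t0[idx]
  ifelse(tab$type[idx] == "exp",
         tab$Tstar[idx] + (tab$Tstart[idx] - tab$Tstar[idx]) *
           exp(-dt / tab$tau[idx]),
         tab$Tstart[idx] + tab$slope[idx] * dt)
}

#' Temperature at given times under a laser schedule
#'
#' Evaluates the piecewise-exponential analytic solution: within each
#' constant-power phase (pre-laser, each on-interval, each off-gap)
#' \eqn{T(t) = T^\star + (T_{\mathrm{phase\,start}} - T^\star)
#' e^{-(t - t_{\mathrm{phase\,start}})/\tau}}, continuous across phase
#' boundaries, with \eqn{T(0) = } `T_init`.  Degenerate phases
#' (`Q = 0`, `beta = 0`) heat linearly at `W/(rho c V)`.
#'
#' @param cfg A [system_config()].
#' @param schedule A [laser_schedule()].
#' @param t Times, s; vectorised, all `>= 0`.
#' @param T_init Initial temperature at `t = 0`, °C (default `cfg$T0`).
#' @return Temperatures, °C, one per element of `t`.
#' @export
#' @examples
#' cfg <- preset_config("setB")
#' temperature_at(cfg, laser_schedule(20, 80, 40), c(0, 20, 80, 100))
temperature_at <- function(cfg, schedule, t, T_init = cfg$T0) {
  if (length(t) == 0L) stop("'t' must be non-empty", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0", call. = FALSE)
  tab <- phase_table(cfg, schedule, T_init)
  eval_phases(tab, t)
}

#' Sample the analytic model on a time grid
#'
#' Vectorised sampling of [temperature_at()].  The default grid emulates the
#' validation experiments: 0.1 s spacing from 0 to 20 s past the last
#' laser-off time (20 s pre-laser + firing + 20 s decay for the standard
#' single burst).
#'
#' @inheritParams temperature_at
#' @param times Strictly increasing sample times, s.
#' @param label Trace label.
#' @return A [temperature_trace()].
#' @export
#' @examples
#' tr <- simulate_trace(preset_config("setA"), single_burst(40))
#' tr
simulate_trace <- function(cfg, schedule,
                           times = seq(0, max(schedule$off) + 20, by = 0.1),
                           T_init = cfg$T0, label = "model") {
  if (length(times) == 0L) stop("empty time grid", call. = FALSE)
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing with >= 2 points",
         call. = FALSE)
  temperature_trace(times, temperature_at(cfg, schedule, times, T_init),
                    label = label)
}

#' Numeric ODE verification twin
#'
#' Integrates the governing balance numerically (classical fixed-step
#' Runge-Kutta 4 via \pkg{deSolve}, restarted at every power switch so the
#' discontinuity never falls inside a step) and samples the result on a
#' grid.  This is a verification oracle for [simulate_trace()] — it shares
#' no code with the analytic solution — and is intended for tests.
#'
#' @inheritParams simulate_trace
#' @param dt Integration step, s; must be small relative to the relaxation
#'   time constant.
#' @return A [temperature_trace()] labelled `"ode"`.
#' @export
ode_trace <- function(cfg, schedule,
                      times = seq(0, max(schedule$off) + 20, by = 0.1),
                      dt = 1e-3, T_init = cfg$T0) {
  check_cfg(cfg)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (times[1L] < 0) stop("'t' must be >= 0", call. = FALSE)
  rc <- cfg$fluid$rho * cfg$fluid$c
  deriv <- function(t, y, parms) {
    list((parms$W + rc * cfg$Q * (cfg$Tin - y) -
            cfg$beta * (y - cfg$T0)) / (rc * cfg$V))
  }
  bounds <- unique(c(0, t(schedule[, c("on", "off")])))
  powers <- numeric(length(bounds))
  for (i in seq_len(nrow(schedule)))
    powers[bounds >= schedule$on[i] & bounds < schedule$off[i]] <-
      schedule$W[i]
  seg_end <- c(bounds[-1L], max(times))
  out_t <- numeric(0); out_T <- numeric(0)
  Tcur <- T_init
  for (i in seq_along(bounds)) {
    a <- bounds[i]; b <- seg_end[i]
    if (b <= a) next
    want <- times[times >= a & times <= b]
    grid <- sort(unique(c(seq(a, b, by = dt), b, want)))
    sol <- deSolve::ode(y = c(T = Tcur), times = grid, func = deriv,
                        parms = list(W = powers[i]), method = "rk4")
    keep <- sol[, "time"] %in% want
    out_t <- c(out_t, sol[keep, "time"])
    out_T <- c(out_T, sol[keep, "T"])
    Tcur <- unname(sol[nrow(sol), "T"])
    if (b >= max(times)) break
  }
  o <- !duplicated(out_t)
  temperature_trace(out_t[o], out_T[o], label = "ode")
}

#' Temperature change after a firing interval
#'
#' \eqn{\Delta T(t_f) = T(t_1 + t_f) - T_0} at the end of a single
#' on-interval of length `t_f` starting from the bath temperature `T0`
#' (`t1_s = 0`, no pre-laser phase, by default).  May be negative when cold
#' irrigation dominates the laser heat input.
#'
#' @inheritParams heat_load
#' @param tf_s Firing time, s; `> 0`.
#' @param t1_s Laser-on time, s; a positive value inserts a pre-laser
#'   irrigation phase from 0 to `t1_s`.
#' @return Temperature change, °C.
#' @export
#' @examples
#' delta_T_after_firing(preset_config("setA", flow_ml_min = 20), 40, 60)
delta_T_after_firing <- function(cfg, power_w, tf_s = 60, t1_s = 0) {
  stopifnot(is.numeric(tf_s), length(tf_s) == 1L, tf_s > 0)
  sched <- single_burst(power_w, tf_s = tf_s, t1_s = t1_s)
  temperature_at(cfg, sched, t1_s + tf_s) - cfg$T0
}
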