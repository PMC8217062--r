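# t43 (CEM43) thermal dose: equivalent minutes at a constant 43 °C,
#
#   t43 = integral of R^(43 - T(t)) dt,   R = 0    for T <= 37 °C
#                                             0.25 for 37 < T < 43 °C
#                                             0.5  for T >= 43 °C
#
# Sustained t43 >= 120 min is the conventional tissue-damage threshold.
# The integrand is continuous at 43 °C (both branches give 1) and has a
# small jump at 37 °C (0 vs 0.25^6); quadrature is split at both crossings.

T_LOWER <- 37   # no-dose branch boundary, °C
T_REF <- 43     # reference temperature, °C

#' Thermal-dose base factor R
#'
#' The piecewise base of the t43 dose integrand: 0 at or below 37 °C,
#' 0.25 strictly between 37 and 43 °C, 0.5 at or above 43 °C.
#'
#' @param temp_c Temperature, °C; vectorised.
#' @return The dimensionless factor, same length as `temp_c`.
#' @export
#' @examples
#' r_factor(c(36, 37, 40, 43, 50))
r_factor <- function(temp_c) {
  if (any(!is.finite(temp_c))) stop("temperature must be finite",
                                    call. = FALSE)
  ifelse(temp_c <= T_LOWER, 0, ifelse(temp_c < T_REF, 0.25, 0.5))
}

# dose integrand in equivalent minutes per second of exposure
dose_rate <- function(temp_c) r_factor(temp_c)^(T_REF - temp_c) / 60

dose_result <- function(t43, horizon, truncated) {
  structure(list(t43 = t43, horizon = horizon, truncated = truncated),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("t43 = %.6g min over [%.6g s horizon]%s\n", x$t43, x$horizon,
              if (x$truncated) " (truncated: lower bound)" else ""))
  invisible(x)
}

# times within [a, b] at which an exponential-relaxation phase crosses
# temperature `level` (at most one crossing per phase: T is monotone)
phase_crossing <- function(row, level, a, b) {
  if (row$type == "exp") {
    num <- level - row$Tstar; den <- row$Tstart - row$Tstar
    if (den == 0 || num / den <= 0 || num / den > 1) return(numeric(0))
    t <- row$t0 - row$tau * log(num / den)
  } else {
    if (row$slope == 0) return(numeric(0))
    t <- row$t0 + (level - row$Tstart) / row$slope
  }
  t[t > a & t < b]
}

# integrate dose_rate(T(t)) dt over [a, b] within one phase, splitting at
# the 37/43 °C crossings so each quadrature piece is smooth
integrate_phase_dose <- function(row, a, b, rel_tol = 1e-8) {
  cuts <- sort(unique(c(a, b,
                        phase_crossing(row, T_LOWER, a, b),
                        phase_crossing(row, T_REF, a, b))))
  tab1 <- as.data.frame(row)
  total <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k]; hi <- cuts[k + 1L]
    mid_T <- eval_phases(tab1, (lo + hi) / 2)
    if (mid_T <= T_LOWER) next  # exact zero on the no-dose branch
    total <- total + stats::integrate(
      function(t) dose_rate(eval_phases(tab1, t)),
      lo, hi, rel.tol = rel_tol, abs.tol = 0)$value
  }
  total
}

#' Thermal dose of an analytic model curve
#'
#' Integrates the t43 dose of the piecewise-exponential temperature solution
#' by adaptive quadrature per constant-power phase (relative tolerance
#' `1e-8`), splitting each phase at its 37 °C and 43 °C crossings.
#'
#' Integration runs from `t_start` (default: first laser-on time) over the
#' firing phases and the post-laser decay.  The decay tail is truncated
#' exactly where the temperature first drops to 37 °C (the dose rate is
#' identically zero beyond); when the post-laser steady state itself exceeds
#' 37 °C the integral does not converge and is cut at `horizon` (default:
#' ten off-phase time constants past the last off time) with
#' `truncated = TRUE`, marking the reported value as a lower bound.
#'
#' @inheritParams temperature_at
#' @param t_start Integration start, s (default first laser-on time).
#' @param horizon Maximum integration end, s; `NULL` for the default rule.
#' @return A `dose_result`: list with `t43` (equivalent minutes at 43 °C),
#'   `horizon` (s) and `truncated` (logical).
#' @export
#' @examples
#' cfg <- preset_config("setA", flow_ml_min = 20, tin_c = 28)
#' t43_of_model(cfg, single_burst(40, tf_s = 120, t1_s = 0))
t43_of_model <- function(cfg, schedule, t_start = NULL, horizon = NULL,
                         T_init = cfg$T0) {
  tab <- phase_table(cfg, schedule, T_init)
  if (is.null(t_start)) t_start <- min(schedule$on)
  last_off <- max(schedule$off)
  # end of integration: 37 °C crossing of the final decay when it exists
  fin <- tab[nrow(tab), , drop = FALSE]
  default_horizon <- if (fin$type == "exp")
    last_off + 10 * fin$tau else last_off + 86400
  if (is.null(horizon)) horizon <- default_horizon
  if (horizon <= t_start)
    stop("'horizon' must exceed 't_start'", call. = FALSE)
  t_end <- horizon
  if (fin$type == "exp" && fin$Tstar < fin$Tstart) {
    if (fin$Tstart <= T_LOWER) {
      t_end <- min(t_end, fin$t0)        # decay starts at/below 37
    } else {
      cross <- phase_crossing(fin, T_LOWER, fin$t0, Inf)
      if (length(cross)) t_end <- min(t_end, cross)  # tail reaches 37
    }
  } else if (fin$type == "linear" && fin$Tstart <= T_LOWER) {
    t_end <- min(t_end, fin$t0)          # degenerate: constant at/below 37
  }
  # horizon cut while the dose rate is still positive => lower bound only
  truncated <- eval_phases(tab, t_end) > T_LOWER + 1e-9
  total <- 0
  for (i in seq_len(nrow(tab))) {
    a <- max(t_start, tab$t0[i]); b <- min(t_end, tab$t1[i])
    if (b > a)
      total <- total + integrate_phase_dose(tab[i, , drop = FALSE], a, b)
  }
  dose_result(total, t_end, truncated)
}

#' Thermal dose of a sampled temperature trace
#'
#' Composite-trapezoid t43 integration of the dose rate evaluated at the
#' trace samples, over `[t_start, horizon]`.  Contributions are exactly zero
#' where the trace is at or below 37 °C.
#'
#' @param trace A [temperature_trace()].
#' @param t_start Integration start, s (default: first sample).
#' @param horizon Integration end, s (default: last sample).  The trace must
#'   span the full window.
#' @return A `dose_result`; `truncated` is `TRUE` when the trace is still
#'   above 37 °C at the horizon, in which case `t43` is a lower bound.
#' @export
#' @examples
#' tr <- temperature_trace(seq(0, 600, 1), rep(45, 601))
#' t43_of_trace(tr)   # 0.5^-2 * 10 min = 40 equivalent minutes
t43_of_trace <- function(trace, t_start = NULL, horizon = NULL) {
  if (!inherits(trace, "temperature_trace"))
    stop("'trace' must be a temperature_trace", call. = FALSE)
  if (is.null(t_start)) t_start <- trace$time_s[1L]
  if (is.null(horizon)) horizon <- trace$time_s[nrow(trace)]
  if (horizon <= t_start)
    stop("'horizon' must exceed 't_start'", call. = FALSE)
  if (t_start < trace$time_s[1L] || horizon > trace$time_s[nrow(trace)])
    stop("trace does not span [t_start, horizon]", call. = FALSE)
  keep <- trace$time_s >= t_start & trace$time_s <= horizon
  tt <- trace$time_s[keep]; yy <- trace$temp_c[keep]
  if (length(tt) < 2L)
    stop("fewer than 2 samples inside the integration window",
         call. = FALSE)
  g <- dose_rate(yy)
  t43 <- sum(diff(tt) * (g[-1L] + g[-length(g)]) / 2)
  dose_result(t43, horizon, truncated = yy[length(yy)] > T_LOWER)
}
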