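# Safe-firing-time solver and parameter-scan tables.
#
# t43 is non-decreasing in the firing time t_f, so the largest t_f with
# t43 <= threshold is found by bracketed bisection.  When the on-phase
# steady state T* never exceeds 37 °C the dose is identically zero and the
# safe firing time is unbounded.

DOSE_THRESHOLD_MIN <- 120   # conventional tissue-damage threshold
TF_CAP_S <- 86400           # 24 h bracket cap: beyond this, effectively safe

safe_time_result <- function(tf_safe, regime, dose_at_tf, capped = FALSE) {
  structure(list(tf_safe = tf_safe, regime = regime,
                 dose_at_tf = dose_at_tf, capped = capped),
            class = "safe_time_result")
}

#' @export
print.safe_time_result <- function(x, ...) {
  tf <- if (is.infinite(x$tf_safe)) "Inf"
        else sprintf("%.3f s (%.4g min)", x$tf_safe, x$tf_safe / 60)
  cat(sprintf("Safe firing time: %s [regime: %s, dose at tf = %.4g min%s]\n",
              tf, x$regime, x$dose_at_tf,
              if (x$capped) ", bracket cap reached" else ""))
  invisible(x)
}

#' Longest safe laser firing time
#'
#' Solves for the largest single-burst firing time `t_f` such that the t43
#' thermal dose of the resulting temperature curve — firing from the bath
#' temperature at `t = 0` plus the post-laser decay, per the [t43_of_model()]
#' policy — stays at or below `threshold_min` equivalent minutes.
#'
#' The on-phase steady state classifies the regime: `T* <= 37 °C` means the
#' dose is identically zero and `tf_safe = Inf` (`"no-dose"`); `37 < T* <
#' 43 °C` accrues dose at below 1 min/min (`"sub-43"`); `T* >= 43 °C` accrues
#' super-linearly (`"supra-43"`).  In the two dosed regimes the monotone map
#' `t_f -> t43` is bracketed by geometric growth and bisected to `tol_s`.
#' If the dose still has not reached the threshold at a 24 h firing time the
#' result is reported as infinite with `capped = TRUE` (effectively safe,
#' rather than exactly dose-free).
#'
#' @inheritParams heat_load
#' @param threshold_min Dose threshold, equivalent minutes at 43 °C; `> 0`.
#' @param tol_s Bisection tolerance on the firing time, s.
#' @param horizon Optional dose-integration horizon override, s, passed to
#'   [t43_of_model()].
#' @return A `safe_time_result`: `tf_safe` (s, possibly `Inf`), `regime`
#'   (`"no-dose"`, `"sub-43"` or `"supra-43"`), `dose_at_tf` (min) and
#'   `capped`.
#' @export
#' @examples
#' # cold, fast irrigation: plateau below body temperature, no dose at all
#' safe_firing_time(preset_config("setA", flow_ml_min = 35, tin_c = 18), 40)
safe_firing_time <- function(cfg, power_w, threshold_min = DOSE_THRESHOLD_MIN,
                             tol_s = 1e-3, horizon = NULL) {
  check_cfg(cfg)
  stopifnot(is.numeric(power_w), length(power_w) == 1L, power_w > 0)
  if (!is.numeric(threshold_min) || length(threshold_min) != 1L ||
      threshold_min <= 0)
    stop("'threshold_min' must be a positive number", call. = FALSE)

  pp <- phase_params(cfg, power_w)
  if (pp$type == "exp") {
    if (pp$Tstar <= T_LOWER)
      return(safe_time_result(Inf, "no-dose", 0))
    regime <- if (pp$Tstar < T_REF) "sub-43" else "supra-43"
  } else {
    regime <- "supra-43"   # unbounded linear heating always reaches 43 °C
  }

  dose_at <- function(tf) {
    t43_of_model(cfg, laser_schedule(0, tf, power_w), t_start = 0,
                 horizon = horizon)
  }

  # geometric bracket growth; monotonicity checked as we go
  lo <- 0; lo_dose <- 0
  hi <- 60
  repeat {
    d <- dose_at(hi)
    if (d$t43 < lo_dose - 1e-9)
      stop("dose is not monotone in firing time; bracket invalid",
           call. = FALSE)
    if (d$t43 > threshold_min) break
    if (hi >= TF_CAP_S) {
      if (d$truncated)
        warning("dose integral truncated below threshold at the 24 h cap; ",
                "safe time reported as infinite but the dose bound is not ",
                "converged", call. = FALSE)
      return(safe_time_result(Inf, regime, d$t43, capped = TRUE))
    }
    lo <- hi; lo_dose <- d$t43
    hi <- min(hi * 2, TF_CAP_S)
  }

  while (hi - lo > tol_s) {
    mid <- (lo + hi) / 2
    if (dose_at(mid)$t43 <= threshold_min) lo <- mid else hi <- mid
  }
  safe_time_result(lo, regime,
                   if (lo > 0) dose_at(lo)$t43 else 0)
}

#' Temperature-change scan over a two-parameter grid
#'
#' Evaluates [delta_T_after_firing()] over a grid spanned by exactly two of
#' flow rate, laser power and vessel volume (the third plus all remaining
#' settings come from `cfg`/`power_w`), returning a long-format table.
#' Negative entries mark conditions where cold irrigation outweighs laser
#' heating.
#'
#' @inheritParams delta_T_after_firing
#' @param flows_ml_min,powers_w,volumes_ml Grid axes; supply exactly two.
#' @return A data frame with one column per varied axis (`flow_ml_min`,
#'   `power_w`, `volume_ml`) and `delta_T_c`.
#' @export
#' @examples
#' cfg <- preset_config("setA", tin_c = 23)
#' scan_delta_T(cfg, power_w = 20, flows_ml_min = c(0, 20, 40),
#'              volumes_ml = c(10, 30, 50))
scan_delta_T <- function(cfg, power_w = NULL, tf_s = 60,
                         flows_ml_min = NULL, powers_w = NULL,
                         volumes_ml = NULL, t1_s = 0) {
  axes <- list(flow_ml_min = flows_ml_min, power_w = powers_w,
               volume_ml = volumes_ml)
  axes <- axes[!vapply(axes, is.null, logical(1))]
  if (length(axes) != 2L)
    stop("supply exactly two of flows_ml_min, powers_w, volumes_ml",
         call. = FALSE)
  if (any(vapply(axes, length, integer(1)) == 0L))
    stop("grid axes must be non-empty", call. = FALSE)
  if (is.null(powers_w) && is.null(power_w))
    stop("'power_w' is required when powers_w is not a grid axis",
         call. = FALSE)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid$delta_T_c <- vapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    if (!is.null(grid$volume_ml)) ci$V <- grid$volume_ml[i] * ML_TO_M3
    if (!is.null(grid$flow_ml_min))
      ci$Q <- grid$flow_ml_min[i] * ML_MIN_TO_M3_S
    w <- if (!is.null(grid$power_w)) grid$power_w[i] else power_w
    delta_T_after_firing(ci, w, tf_s = tf_s, t1_s = t1_s)
  }, numeric(1))
  grid
}

#' Safe-firing-time scan over irrigation temperature and flow rate
#'
#' Evaluates [safe_firing_time()] on a `Tin x Q` grid and reports the safe
#' firing time in minutes (with `Inf` as the no-dose sentinel) together with
#' the dose regime per cell.  The attribute `"contours"` carries, per
#' irrigation temperature, the closed-form flow rates at which the on-phase
#' steady state crosses 37 °C and 43 °C — the regime boundaries, independent
#' of vessel volume.
#'
#' @inheritParams safe_firing_time
#' @param tins_c Irrigation temperatures, °C.
#' @param flows_ml_min Flow rates, mL/min.
#' @return A data frame with columns `tin_c`, `flow_ml_min`, `tf_safe_min`,
#'   `regime`, `capped`; attribute `"contours"` is a data frame
#'   `(tin_c, q37_ml_min, q43_ml_min)` (`NA` when a boundary does not exist
#'   at that temperature).
#' @export
scan_safe_time <- function(cfg, power_w, tins_c, flows_ml_min,
                           threshold_min = DOSE_THRESHOLD_MIN, tol_s = 1e-3) {
  if (length(tins_c) == 0L || length(flows_ml_min) == 0L)
    stop("grid axes must be non-empty", call. = FALSE)
  grid <- expand.grid(tin_c = tins_c, flow_ml_min = flows_ml_min,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    ci$Tin <- grid$tin_c[i]
    ci$Q <- grid$flow_ml_min[i] * ML_MIN_TO_M3_S
    safe_firing_time(ci, power_w, threshold_min = threshold_min,
                     tol_s = tol_s)
  })
  grid$tf_safe_min <- vapply(res, function(r) r$tf_safe / 60, numeric(1))
  grid$regime <- vapply(res, function(r) r$regime, character(1))
  grid$capped <- vapply(res, function(r) r$capped, logical(1))
  attr(grid, "contours") <- steady_state_contours(cfg, power_w, tins_c)
  grid
}

# flow rate at which the on-phase steady state equals `level` (°C), per Tin:
#   rho*c*Q*(level - Tin) = W + beta*(T0 - level)
steady_state_contours <- function(cfg, power_w, tins_c) {
  rc <- cfg$fluid$rho * cfg$fluid$c
  q_at <- function(level) {
    rhs <- power_w + cfg$beta * (cfg$T0 - level)
    q <- ifelse(tins_c < level & rhs > 0, rhs / (rc * (level - tins_c)), NA)
    q / ML_MIN_TO_M3_S
  }
  data.frame(tin_c = tins_c, q37_ml_min = q_at(T_LOWER),
             q43_ml_min = q_at(T_REF))
}
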