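# Least-squares estimation of the wall heat-loss coefficient beta from
# thermocouple traces.  beta is the only free parameter (all other system
# settings are measured), so the fit is a one-dimensional bounded
# minimisation of the pooled residual sum of squares.

BETA_BOUNDS <- c(1e-3, 1e2)   # W/°C search interval

fit_result <- function(beta_hat, rss, n_points, stderr_beta, window,
                       bound_hit = FALSE) {
  structure(list(beta_hat = beta_hat, rss = rss, n_points = n_points,
                 stderr_beta = stderr_beta, window = window,
                 bound_hit = bound_hit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "beta_hat = %.6g W/°C (stderr %.3g), rss = %.4g °C^2 over %d points, window [%.4g, %.4g] s%s\n",
    x$beta_hat, x$stderr_beta, x$rss, x$n_points,
    x$window[1L], x$window[2L],
    if (x$bound_hit) " [warning: estimate at search bound]" else ""))
  invisible(x)
}

#' Estimate the wall heat-loss coefficient from temperature traces
#'
#' Fits `beta` by minimising the summed squared residuals between the
#' analytic model temperature and one or more (pooled, equally weighted)
#' thermocouple traces over a fit window.  The canonical design is the
#' no-irrigation case (`Q = 0`) with the laser at full power, where the
#' exponential rise is governed by `beta` alone; the default window is the
#' rise phase, from laser-on to laser-off.
#'
#' Before minimisation the objective is scanned on a logarithmic grid over
#' the search interval `[1e-3, 1e2]` W/°C to confirm unimodality and a
#' non-degenerate dependence on `beta`; flat objectives (no observable
#' temperature dynamics) raise a non-identifiability error.  The reported
#' standard error comes from the curvature of the residual sum of squares
#' at the minimum.
#'
#' @param traces A [temperature_trace()] or a list of them; all must
#'   overlap the fit window.
#' @param cfg A [system_config()]; its `beta` may be `NA` (it is ignored).
#' @param schedule A [laser_schedule()]; the default window is
#'   `[min(on), max(off)]`.
#' @param window Length-2 numeric fit window `(t_start, t_end)`, s; set the
#'   end beyond laser-off to include the decay phase.
#' @param bounds Search interval for `beta`, W/°C.
#' @param tol Minimisation tolerance on `beta`.
#' @return A `fit_result`: `beta_hat` (W/°C), `rss` (°C^2), `n_points`,
#'   `stderr_beta`, `window`, `bound_hit`.
#' @export
#' @examples
#' cfg <- preset_config("setB")
#' sched <- laser_schedule(20, 80, 40)
#' tr <- simulate_trace(cfg, sched)        # noise-free, beta = 1.36
#' fit_beta(tr, cfg, sched)
fit_beta <- function(traces, cfg, schedule, window = NULL,
                     bounds = BETA_BOUNDS, tol = 1e-6) {
  if (inherits(traces, "temperature_trace")) traces <- list(traces)
  if (!length(traces) ||
      !all(vapply(traces, inherits, logical(1), "temperature_trace")))
    stop("'traces' must be temperature_trace objects", call. = FALSE)
  if (!inherits(cfg, "system_config"))
    stop("'cfg' must be a system_config", call. = FALSE)
  if (is.null(window)) window <- c(min(schedule$on), max(schedule$off))
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("'window' must be (t_start, t_end) with t_end > t_start",
         call. = FALSE)

  tt <- numeric(0); yy <- numeric(0)
  for (tr in traces) {
    keep <- tr$time_s >= window[1L] & tr$time_s <= window[2L]
    tt <- c(tt, tr$time_s[keep]); yy <- c(yy, tr$temp_c[keep])
  }
  if (length(tt) < 3L)
    stop("fewer than 3 trace points overlap the fit window", call. = FALSE)

  rss_of <- function(beta) {
    m <- temperature_at(set_beta(cfg, beta), schedule, tt)
    sum((yy - m)^2)
  }

  # unimodality / identifiability screen on a log grid
  grid <- exp(seq(log(bounds[1L]), log(bounds[2L]), length.out = 41L))
  obj <- vapply(grid, rss_of, numeric(1))
  spread <- max(obj) - min(obj)
  if (spread <= 1e-12 * (1 + min(obj)))
    stop("beta is not identifiable from these traces: the objective does ",
         "not depend on beta (no observable temperature dynamics in the ",
         "fit window)", call. = FALSE)
  d <- diff(obj)
  sign_changes <- sum(diff(sign(d[d != 0])) != 0)
  if (sign_changes > 1L)
    warning("objective is not unimodal on the coarse scan; reporting the ",
            "best local minimum near the grid optimum", call. = FALSE)
  i <- which.min(obj)
  lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
  opt <- stats::optimize(rss_of, c(lo, hi), tol = tol)
  beta_hat <- opt$minimum; rss <- opt$objective

  bound_hit <- beta_hat <= bounds[1L] * 1.05 || beta_hat >= bounds[2L] * 0.95
  if (bound_hit)
    warning("fitted beta is at the search bound; estimate is unreliable",
            call. = FALSE)

  # curvature-based standard error: var(beta) ~ 2*sigma^2 / d2RSS/dbeta2
  h <- max(1e-5, 1e-4 * beta_hat)
  curv <- (rss_of(beta_hat + h) - 2 * rss + rss_of(beta_hat - h)) / h^2
  sigma2 <- rss / max(1L, length(tt) - 1L)
  stderr_beta <- if (curv > 0) sqrt(2 * sigma2 / curv) else NA_real_

  fit_result(beta_hat, rss, length(tt), stderr_beta, window, bound_hit)
}

#' Model curve at the fitted parameter
#'
#' Convenience helper: the analytic trace implied by a [fit_beta()] result,
#' for overlaying on the data it was fitted to.
#'
#' @param fit A `fit_result`.
#' @inheritParams simulate_trace
#' @return A [temperature_trace()] labelled `"fitted"`.
#' @export
fitted_trace <- function(fit, cfg, schedule,
                         times = seq(0, max(schedule$off) + 20, by = 0.1)) {
  simulate_trace(set_beta(cfg, fit$beta_hat), schedule, times,
                 label = "fitted")
}
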