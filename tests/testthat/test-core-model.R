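# Analytic lumped-model solution: steady states, time constants, piecewise
# propagation, degenerate branches, and agreement with the numeric ODE twin.

test_that("heat_load reproduces the energy-balance steady state", {
  # no source, no gradient: stays at the bath temperature
  cfg <- system_config(38.3, t0_c = 25, beta_w_per_c = 1, flow_ml_min = 10,
                       tin_c = 25)
  expect_equal(heat_load(cfg, 0)$Tstar, 25)

  # closed vessel at full power: rise W/beta, time constant rho*c*V/beta
  hl <- heat_load(set_a(), 40)
  expect_equal(hl$Tstar, 37 + 40 / 1.15, tolerance = 1e-12)
  expect_equal(hl$tau, 1000 * 4180 * 5.89e-6 / 1.15, tolerance = 1e-12)

  # independent oracle: long-time plateau and 63.2% rise time of the ODE
  sched <- laser_schedule(0, 200, 40)
  ode <- ode_trace(set_a(), sched, times = seq(0, 200, 0.05), dt = 5e-3)
  expect_equal(ode$temp_c[nrow(ode)], hl$Tstar, tolerance = 1e-3)
  rise <- ode$time_s[which(ode$temp_c >= 37 + (hl$Tstar - 37) *
                             (1 - exp(-1)))[1L]]
  expect_equal(rise, hl$tau, tolerance = 0.01)
})

test_that("cold fast irrigation plateaus below body temperature", {
  # flux-balance root as independent oracle: W = rho*c*Q*(T - Tin) + beta*(T - T0)
  cfg <- set_a(flow_ml_min = 35, tin_c = 18)
  rc <- 1000 * 4180
  oracle <- uniroot(function(T) 40 - rc * (35e-6 / 60) * (T - 18) -
                      1.15 * (T - 37), c(0, 100), tol = 1e-10)$root
  ts <- heat_load(cfg, 40)$Tstar
  expect_equal(ts, oracle, tolerance = 1e-9)
  expect_lt(ts, 37)
})

test_that("steady state is volume-independent and tau is proportional to V", {
  vols <- c(5.89, 38.3, 100)
  hls <- lapply(vols, function(v) {
    cfg <- system_config(v, 37, 1.15, flow_ml_min = 20, tin_c = 23)
    heat_load(cfg, 40)
  })
  tstars <- vapply(hls, `[[`, numeric(1), "Tstar")
  expect_equal(max(tstars) - min(tstars), 0)
  taus <- vapply(hls, `[[`, numeric(1), "tau")
  expect_equal(taus / vols, rep(taus[1L] / vols[1L], 3), tolerance = 1e-12)
  cfg2 <- system_config(2 * 38.3, 37, 1.15, flow_ml_min = 20, tin_c = 23)
  expect_equal(heat_load(cfg2, 40)$tau / taus[2L] * (38.3 / 5.89),
               2 * 38.3 / 5.89, tolerance = 1e-12)
})

test_that("degenerate closed adiabatic vessel heats linearly, no steady state", {
  cfg <- system_config(38.3, 22, beta_w_per_c = 0, flow_ml_min = 0)
  expect_error(heat_load(cfg, 40), "unbounded")
  sched <- laser_schedule(0, 60, 40)
  dT <- temperature_at(cfg, sched, 60) - 22
  expect_equal(dT, 40 * 60 / (1000 * 4180 * 38.3e-6), tolerance = 1e-12)
  expect_equal(dT, 14.9912, tolerance = 1e-4)
})

test_that("temperature_at propagates a single burst piecewise", {
  cfg <- set_b()
  sched <- laser_schedule(20, 80, 40)
  expect_equal(temperature_at(cfg, sched, 0), 22)        # initial condition
  # no gradient before firing (T0 = Tin), so flat pre-laser phase
  expect_equal(temperature_at(cfg, sched, 20), 22)
  # end-of-firing closed form, against the frozen ODE-verified value
  hl <- heat_load(cfg, 40)
  expect_equal(temperature_at(cfg, sched, 80),
               22 + (hl$Tstar - 22) * (1 - exp(-60 / hl$tau)),
               tolerance = 1e-12)
  expect_equal(temperature_at(cfg, sched, 80), 33.7448, tolerance = 1e-4)
  expect_error(temperature_at(cfg, sched, -1), ">= 0")
})

test_that("analytic solution matches the ODE oracle on experiment-like cases", {
  cfg <- set_b(flow_ml_min = 20)
  sched <- std_burst(40)
  tt <- seq(0, 100, 0.1)
  a <- simulate_trace(cfg, sched, times = tt)
  o <- ode_trace(cfg, sched, times = tt, dt = 1e-3)
  expect_lt(max(abs(a$temp_c - o$temp_c)), 1e-3)

  cfgA <- set_a(flow_ml_min = 14.5)
  a2 <- simulate_trace(cfgA, sched, times = tt)
  o2 <- ode_trace(cfgA, sched, times = tt, dt = 1e-3)
  expect_lt(max(abs(a2$temp_c - o2$temp_c)), 1e-3)
})

test_that("ODE oracle self-checks: constant case and step-halving convergence", {
  cfg <- system_config(38.3, 25, 1.2, flow_ml_min = 10, tin_c = 25)
  o <- ode_trace(cfg, laser_schedule(10, 20, 0), times = seq(0, 30, 1))
  expect_equal(o$temp_c, rep(25, 31))

  cfg2 <- set_a(flow_ml_min = 20)
  sched <- laser_schedule(5, 40, 40)
  tt <- seq(0, 60, 1)
  a <- simulate_trace(cfg2, sched, times = tt)
  err <- vapply(c(0.4, 0.2, 0.1), function(dt)
    max(abs(ode_trace(cfg2, sched, times = tt, dt = dt)$temp_c -
              a$temp_c)), numeric(1))
  # classical RK4: halving the step cuts the error by about 2^4
  expect_gt(err[1L] / err[2L], 8)
  expect_gt(err[2L] / err[3L], 8)
})

test_that("trace is continuous, bounded and phase-monotone", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      cfg <- random_config()
      sched <- random_schedule()
      eps <- 1e-9
      switches <- sort(unique(c(sched$on, sched$off)))
      left <- temperature_at(cfg, sched, pmax(switches - eps, 0))
      right <- temperature_at(cfg, sched, switches + eps)
      expect_lt(max(abs(left - right)), 1e-6)

      # single-interval boundedness: T stays within the envelope spanned by
      # the initial temperature and the on/off steady states
      s1 <- laser_schedule(sched$on[1L], sched$off[1L], sched$W[1L])
      ts_on <- heat_load(cfg, s1$W[1L])$Tstar
      ts_off <- heat_load(cfg, 0)$Tstar
      tt <- seq(0, sched$off[1L] + 100, length.out = 200)
      temps <- temperature_at(cfg, s1, tt)
      lo <- min(cfg$T0, ts_on, ts_off) - 1e-9
      hi <- max(cfg$T0, ts_on, ts_off) + 1e-9
      expect_true(all(temps >= lo & temps <= hi))

      # within each phase the trajectory is monotone toward that phase's T*
      tab <- lithotherm:::phase_table(cfg, sched)
      for (i in seq_len(nrow(tab))) {
        b <- min(tab$t1[i], tab$t0[i] + 50)
        if (b <= tab$t0[i]) next
        tp <- seq(tab$t0[i], b, length.out = 20)
        y <- temperature_at(cfg, sched, tp)
        expect_true(all(diff(y) >= -1e-9) || all(diff(y) <= 1e-9))
      }
    }
  })
})

test_that("delta_T_after_firing matches its definition and sign structure", {
  cfg <- set_a(flow_ml_min = 20, tin_c = 37)
  expect_equal(delta_T_after_firing(cfg, 0), 0)
  expect_gt(delta_T_after_firing(cfg, 10), 0)

  # cold irrigation case checked against the ODE oracle
  cfg2 <- system_config(30, 37, 1.15, flow_ml_min = 20, tin_c = 23)
  sched <- laser_schedule(0, 60, 20)
  o <- ode_trace(cfg2, sched, times = c(0, 60), dt = 1e-3)
  expect_equal(delta_T_after_firing(cfg2, 20, 60),
               o$temp_c[2L] - 37, tolerance = 1e-6)
})

test_that("delta_T after fixed firing time is monotone in W, Q and V", {
  base <- function(q, v) system_config(v, 37, 1.15, flow_ml_min = q,
                                       tin_c = 37)
  dT_w <- vapply(c(5, 10, 20, 40, 80), function(w)
    delta_T_after_firing(base(20, 30), w), numeric(1))
  expect_true(all(diff(dT_w) > 0))
  dT_q <- vapply(c(0, 5, 10, 20, 40), function(q)
    delta_T_after_firing(base(q, 30), 20), numeric(1))
  expect_true(all(diff(dT_q) < 0))
  dT_v <- vapply(c(5, 15, 30, 60, 100), function(v)
    delta_T_after_firing(base(20, v), 20), numeric(1))
  expect_true(all(diff(dT_v) < 0))
})

test_that("duty-cycle schedules accumulate heat across bursts", {
  cfg <- set_b(flow_ml_min = 10)
  pulsed <- laser_schedule(c(10, 40, 70), c(30, 60, 90), 40)
  tt <- seq(0, 120, 0.5)
  a <- simulate_trace(cfg, pulsed, times = tt)
  o <- ode_trace(cfg, pulsed, times = tt, dt = 5e-3)
  expect_lt(max(abs(a$temp_c - o$temp_c)), 1e-3)
  # each successive burst starts warmer than the previous one
  starts <- temperature_at(cfg, pulsed, pulsed$on)
  expect_true(all(diff(starts) > 0))
})

test_that("constructors validate their invariants", {
  expect_error(system_config(-1, 37, 1), "positive")
  expect_error(system_config(10, 37, -0.5), "non-negative")
  expect_error(laser_schedule(10, 5, 40), "on < off")
  expect_error(laser_schedule(c(0, 5), c(10, 20), 40), "overlap")
  expect_error(temperature_trace(c(0, 0), c(1, 2)), "increasing")
  expect_error(fluid_properties(k = -1), "positive")
  expect_error(simulate_trace(set_a(), std_burst(), times = numeric(0)),
               "empty")
})
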