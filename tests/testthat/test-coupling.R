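test_that("exchange interpolation is linear, exact on shared grids, and refuses extrapolation", {
  t_src <- seq(0, 1, by = 0.1)
  y <- 3 * t_src - 1                      # linear ramp: interpolation exact
  expect_equal(interpolate_exchange(t_src, y, c(0.05, 0.37, 0.99)),
               3 * c(0.05, 0.37, 0.99) - 1)
  expect_equal(interpolate_exchange(t_src, y, t_src), y)
  # round trip between rationally related grids reproduces source values
  y2 <- sin(2 * pi * t_src)
  t_fine <- seq(0, 1, by = 0.025)
  back <- interpolate_exchange(t_fine, interpolate_exchange(t_src, y2, t_fine),
                               t_src)
  expect_equal(back, y2)
  expect_error(interpolate_exchange(t_src, y, 1.2), "extrapolation")
})

test_that("zero contractility never opens the valve and ejects nothing", {
  cfg <- coarse_coupled_config(T0 = 0)
  sim <- init_sa(cfg)
  cyc <- run_phase_machine(cfg$lv, sim, cfg$coupling)
  expect_true(is.na(cyc$events$t_open))
  expect_equal(cyc$SV, 0)
  expect_equal(cyc$t_ej, 0)
  expect_equal(nrow(cyc$interface), 0L)
  expect_false("ejection" %in% cyc$lv$phase)
})

test_that("a coupled cycle honours the interface and volume bookkeeping", {
  cfg <- coarse_coupled_config(T0 = 30)
  sim <- init_sa(cfg)
  sa_reset_volumes(sim)
  cyc <- run_phase_machine(cfg$lv, sim, cfg$coupling)
  expect_gt(cyc$SV, 5)
  # ejection begins only after the cavity pressure crosses the root pressure
  expect_true(cyc$events$t_open > 0)
  pre <- cyc$lv$t < cyc$events$t_open
  expect_true(all(cyc$lv$V[pre] == cyc$EDV))
  # stroke volume equals the time-integrated interface flow (trapezoid)
  q <- cyc$interface$Q_minus
  vol <- cyc$dt * (sum(q) - q[length(q)] / 2)   # starts from q_prev = 0
  expect_lt(abs(vol - cyc$SV) / cyc$SV, 0.005)
  # both models report the same interface state at every exchange instant
  expect_lt(max(abs(cyc$interface$P_minus - cyc$interface$P_plus)), 1e-3)
  expect_equal(cyc$interface$Q_minus, cyc$interface$Q_plus)
  # the arterial inlet received exactly the ejected volume
  d <- sa_diagnostics(sim)
  expect_lt(abs(d$in_volume - cyc$SV) / cyc$SV, 0.01)
  # end-diastolic state is restored for the next cycle at the fixed EDP
  expect_equal(cyc$lv$V[nrow(cyc$lv)], cyc$EDV, tolerance = 1e-6)
  expect_equal(cyc$lv$P_lv[nrow(cyc$lv)], cfg$lv$edp, tolerance = 0.05)
  # phases appear in canonical order
  expect_equal(rle(cyc$lv$phase)$values, c("ivc", "ejection", "ivr", "filling"))
})

test_that("tightening the exchange tolerance leaves the interface series unchanged", {
  cfg <- coarse_coupled_config(T0 = 30)
  run_with <- function(tol) {
    cfg$coupling$exchange_tolerance <- tol
    sim <- init_sa(cfg)
    run_phase_machine(cfg$lv, sim, cfg$coupling)$interface$Q_minus
  }
  q1 <- run_with(1e-7)
  q2 <- run_with(1e-9)
  expect_equal(length(q1), length(q2))
  expect_lt(max(abs(q1 - q2)) / max(q1), 1e-3)
})

test_that("cycles converge to a periodic solution; degenerate threshold warns", {
  cfg <- coarse_coupled_config(T0 = 30)
  sim <- init_sa(cfg)
  per <- run_until_periodic(cfg$lv, sim, cfg$coupling)
  expect_true(per$converged)
  expect_lt(per$metrics[length(per$metrics)], cfg$coupling$convergence_threshold)
  # an impossible threshold exercises the warning path
  cfg$coupling$convergence_threshold <- 0
  cfg$coupling$max_cycles <- 2
  sim2 <- init_sa(cfg)
  expect_warning(res <- run_until_periodic(cfg$lv, sim2, cfg$coupling),
                 "convergence")
  expect_false(res$converged)
})

test_that("calibration recovers known passive-scale and contractility targets", {
  # generate synthetic targets from the model itself, then start calibration
  # from deliberately wrong parameters
  cfg <- coarse_coupled_config(T0 = 28, n = 512)
  hop_true <- cfg$lv$hop; hop_true$passive_scale <- 0.45
  lv_true <- reduced_lv(cfg$lv$geom, hop_true,
                        activation_params(T0 = 28), edp = 8)
  cfg_true <- cfg; cfg_true$lv <- lv_true
  sim <- init_sa(cfg_true)
  cyc <- NULL
  for (i in 1:2) cyc <- run_phase_machine(lv_true, sim, cfg_true$coupling)
  targets <- list(EDV = lv_true$EDV, SV = cyc$SV, t_ej = cyc$t_ej)

  cfg_start <- cfg
  hop0 <- cfg$lv$hop; hop0$passive_scale <- 1.9
  cfg_start$lv <- reduced_lv(cfg$lv$geom, hop0,
                             activation_params(T0 = 45), edp = 8)
  cal <- calibrate_baseline(targets, cfg_start, tol = 0.02)
  expect_true(cal$converged)
  expect_lt(abs(cal$lv$hop$passive_scale - 0.45) / 0.45, 0.02)
  expect_lt(abs(cal$lv$actp$T0 - 28) / 28, 0.05)
  expect_lt(abs(cal$lv$EDV - targets$EDV) / targets$EDV, 1e-6)

  # fixed point: calibrating an already-calibrated model changes nothing
  cal2 <- calibrate_baseline(targets, cal$config, tol = 0.02)
  expect_equal(cal2$lv$actp$T0, cal$lv$actp$T0)
})
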