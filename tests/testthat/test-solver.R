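test_that("the uniform rest state is an exact fixed point", {
  net <- make_test_network("single_vessel")
  sim <- sa_sim(net, fast_settings(), small_tree())
  for (i in 1:40) sa_step(sim, 0)
  ser <- sa_series(sim)
  expect_equal(max(abs(ser$Q)), 0)
  expect_equal(max(abs(ser$P - cgs_to_mmHg(net$tube_law$P0))), 0)
  snap <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  expect_equal(snap$A, pi * snap$r0^2)
})

test_that("a small pulse propagates at the analytic wave speed", {
  p <- tube_law_params()
  seg <- tibble::tibble(id = 1L, name = "v", length_cm = 60, r_top_cm = 0.5,
                        r_bottom_cm = 0.5, daughter_1 = NA_integer_,
                        daughter_2 = NA_integer_, bed_root_radius_cm = 0.5)
  net <- arterial_network(seg, p)
  ss <- solver_settings(n_per_period = 4096)
  sim <- sa_sim(net, ss, small_tree())
  snap <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  A0 <- pi * 0.5^2
  lvsa:::sa_set_state_(sim$ptr, 0L,
                       A0 * (1 + 0.005 * exp(-((snap$x - 15) / 2)^2)),
                       rep(0, length(snap$x)))
  nst <- 100
  for (i in seq_len(nst)) sa_step(sim, 0, interior_only = TRUE)
  s2 <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  x_peak <- snap$x[which.max(s2$A - A0)]
  c_meas <- (x_peak - 15) / (nst * ss$dt)
  expect_lt(abs(c_meas - wave_speed(A0, 0.5, p)) / wave_speed(A0, 0.5, p), 0.02)
})

test_that("interior-only stepping leaves boundary nodes untouched", {
  net <- make_test_network("single_vessel")
  sim <- sa_sim(net, fast_settings(), small_tree())
  snap <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  A <- snap$A * (1 + 0.004 * sin(seq(0, pi, length.out = length(snap$A))))
  lvsa:::sa_set_state_(sim$ptr, 0L, A, rep(3, length(snap$A)))
  sa_step(sim, 0, interior_only = TRUE)
  s2 <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  m <- length(A)
  expect_equal(s2$A[c(1, m)], A[c(1, m)])
  expect_equal(s2$Q[c(1, m)], c(3, 3))
  expect_false(isTRUE(all.equal(s2$A[2:(m - 1)], A[2:(m - 1)])))
})

test_that("the inlet admits exactly the prescribed volume", {
  net <- make_test_network("single_vessel")
  ss <- fast_settings()
  sim <- sa_sim(net, ss, small_tree())
  qf <- make_inflow(SV = 30, Q_peak = 250, t_ej = 0.25, period = 0.9)
  tt <- ss$dt * seq_len(ss$n_per_period)
  sa_run_steps(sim, qf$fun(tt))
  d <- sa_diagnostics(sim)
  expect_lt(abs(d$in_volume - 30) / 30, 0.005)
})

test_that("a step inflow change stays causal (no instantaneous distal response)", {
  p <- tube_law_params()
  seg <- tibble::tibble(id = 1L, name = "v", length_cm = 40, r_top_cm = 0.5,
                        r_bottom_cm = 0.5, daughter_1 = NA_integer_,
                        daughter_2 = NA_integer_, bed_root_radius_cm = 0.5)
  net <- arterial_network(seg, p)
  ss <- fast_settings(2048)
  sim <- sa_sim(net, ss, small_tree())
  c0 <- wave_speed(pi * 0.25, 0.5, p)
  nst <- 30
  sa_run_steps(sim, rep(50, nst))   # step change at t = 0
  s2 <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  reach <- c0 * nst * ss$dt
  beyond <- s2$x > reach * 1.5
  expect_true(any(beyond))
  expect_lt(max(abs(s2$Q[beyond])), 1e-8 * 50)
  expect_gt(s2$Q[1], 49)
})

test_that("junctions split symmetrically and conserve flow exactly", {
  net <- make_test_network("symmetric_bifurcation")
  ss <- fast_settings()
  sim <- sa_sim(net, ss, small_tree())
  qf <- function(t) 120 * sin(pi * pmin(t, 0.3) / 0.3)^2 * (t < 0.3)
  sa_run_steps(sim, qf(ss$dt * seq_len(2048)))
  ser <- sa_series(sim)
  expect_equal(ser$Q[, "daughter_a"], ser$Q[, "daughter_b"])
  # boundary-node flow conservation across the junction
  par_end <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  d1 <- lvsa:::sa_snapshot_(sim$ptr, 1L)
  d2 <- lvsa:::sa_snapshot_(sim$ptr, 2L)
  np <- length(par_end$Q)
  expect_lt(abs(par_end$Q[np] - d1$Q[1] - d2$Q[1]),
            1e-10 * max(abs(par_end$Q[np]), 1))
  expect_lt(sa_diagnostics(sim)$max_junction_residual, 1e-10)
})

test_that("periodic inflow balances terminal outflow within 1%", {
  net <- make_test_network("symmetric_bifurcation")
  ss <- fast_settings()
  sim <- sa_sim(net, ss, small_tree())
  qf <- make_inflow(SV = 40, Q_peak = 300, t_ej = 0.25, period = 0.9)
  run_sa(net, qf, periods = 4, sim = sim)          # flush transients
  sa_reset_volumes(sim); sa_clear_series(sim)
  run_sa(net, qf, periods = 1, sim = sim)
  d <- sa_diagnostics(sim)
  expect_lt(abs(d$in_volume - sum(d$out_volume)) / d$in_volume, 0.01)
  run_sa(net, qf, periods = 1, sim = sim)
  expect_lt(100 * period_pressure_diff(sa_series(sim), ss$n_per_period), 1)
})

test_that("a steady inflow settles at the DC tree resistance", {
  law <- tube_law_params()
  net <- make_test_network("single_vessel", law)
  ss <- fast_settings()
  tr <- small_tree()
  sim <- sa_sim(net, ss, tr)
  qbar <- 15
  sa_run_steps(sim, rep(qbar, 4 * ss$n_per_period))
  snap <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  n <- length(snap$x)
  R_dc <- tree_dc_resistance(0.3, tr, mu = law$rho * law$nu)
  expect_lt(abs((snap$P[n] - law$P0) - R_dc * qbar) / (R_dc * qbar), 0.01)
})

test_that("refining dt and dx changes the solution by under 1%", {
  qf <- make_inflow(SV = 40, Q_peak = 300, t_ej = 0.25, period = 0.9)
  run_one <- function(n) {
    net <- make_test_network("single_vessel")
    ss <- solver_settings(n_per_period = n)
    sim <- sa_sim(net, ss, small_tree())
    run_sa(net, qf, periods = 3, sim = sim)
    ser <- sa_series(sim)
    ser$P[(nrow(ser$P) - n + 1):nrow(ser$P), 1]
  }
  p1 <- run_one(1024)
  p2 <- run_one(2048)
  expect_lt(max(abs(p2[seq(2, 2048, by = 2)] - p1)) / max(p1), 0.01)
})

test_that("the CFL guard aborts with a diagnostic", {
  net <- make_test_network("single_vessel")
  sim <- sa_sim(net, fast_settings(), small_tree())
  snap <- lvsa:::sa_snapshot_(sim$ptr, 0L)
  n <- length(snap$A)
  lvsa:::sa_set_state_(sim$ptr, 0L, snap$A, rep(1e5, n))  # absurd velocity
  expect_error(sa_step(sim, 0), "CFL")
})

test_that("solver state snapshots restore bit-for-bit", {
  net <- make_test_network("symmetric_bifurcation")
  ss <- fast_settings()
  sim <- sa_sim(net, ss, small_tree())
  qf <- make_inflow(SV = 40, Q_peak = 300, t_ej = 0.25, period = 0.9)
  run_sa(net, qf, periods = 1, sim = sim)
  st <- sa_state(sim)
  sa_run_steps(sim, rep(10, 200))
  a_after <- lvsa:::sa_snapshot_(sim$ptr, 0L)$A
  sa_restore(sim, st)
  sa_run_steps(sim, rep(10, 200))
  expect_identical(lvsa:::sa_snapshot_(sim$ptr, 0L)$A, a_after)
})
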