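# synthetic cycle_result builder for index tests
synth_cycle <- function(V, P, dt = 1e-3, interface = NULL, t_close = NA) {
  n <- length(V)
  structure(list(
    lv = tibble::tibble(t = dt * seq_len(n), V = V, P_lv = P,
                        activation = 0, phase = "ejection"),
    interface = interface %||% tibble::tibble(t = numeric(0),
                                              P_minus = numeric(0),
                                              Q_minus = numeric(0),
                                              P_plus = numeric(0),
                                              Q_plus = numeric(0)),
    events = list(t_open = dt, t_close = t_close, t_fill_start = NA),
    EDV = max(V), ESV = min(V), SV = max(V) - min(V),
    t_ej = if (is.na(t_close)) 0 else t_close - dt,
    sa = NULL, dt = dt), class = "cycle_result")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("case modifications act on exactly the intended parameters", {
  cfg <- coarse_coupled_config()
  expect_identical(apply_case(cfg, "baseline")$net$tube_law$k3,
                   cfg$net$tube_law$k3)
  c1 <- apply_case(cfg, "case1")
  expect_equal(c1$net$tube_law$k3, 2 * cfg$net$tube_law$k3)
  expect_equal(c1$bed_tube_law$k3, cfg$net$tube_law$k3)  # beds untouched
  c2 <- apply_case(cfg, "case2")
  expect_equal(c2$tree$xi, 2.4)
  c3 <- apply_case(cfg, "case3")
  expect_equal(c3$lv$hop$stiffness_scale, 2)
  expect_lt(c3$lv$EDV, cfg$lv$EDV)
  c4 <- apply_case(cfg, "case4")
  expect_equal(c4$lv$actp$T0, 1.33 * cfg$lv$actp$T0)
  expect_true(apply_case(cfg, "case1_iso")$iso)
  expect_error(apply_case(cfg, "case9"), "unknown")
})

test_that("stroke work equals the pressure-volume loop area", {
  # rectangular loop: P 10 -> 110 mmHg at V = 142, back at V = 70
  V <- c(142, 142, 70, 70)
  P <- c(10, 110, 110, 10)
  cyc <- synth_cycle(rep(V, each = 50), rep(P, each = 50), t_close = 0.05)
  idx <- lv_indices(cyc)
  expect_equal(idx$SW_cJ, 100 * 72 * 0.0133322, tolerance = 1e-10)
  expect_equal(idx$SW_cJ, 96.0, tolerance = 1e-3)
  # loop area is invariant to the cycle start point
  rot <- c(51:200, 1:50)
  cyc2 <- synth_cycle(rep(V, each = 50)[rot], rep(P, each = 50)[rot],
                      t_close = 0.05)
  expect_equal(lv_indices(cyc2)$SW_cJ, idx$SW_cJ)
})

test_that("a zero-contraction cycle yields null pump indices", {
  cyc <- synth_cycle(rep(140, 100), rep(8, 100))
  idx <- lv_indices(cyc)
  expect_equal(idx$SV_mL, 0)
  expect_equal(idx$SW_cJ, 0)
  expect_equal(idx$t_ej_ms, 0)
  expect_equal(idx$Qpeak_ao_mL_s, 0)
})

test_that("unconverged runs are refused unless overridden", {
  run <- structure(list(converged = FALSE, cycle = synth_cycle(rep(1, 4), rep(1, 4)),
                        case_id = "x", iso = FALSE), class = "lvsa_run")
  expect_error(lv_indices(run), "not converged")
  expect_s3_class(lv_indices(run, refuse_unconverged = FALSE), "tbl_df")
})

test_that("waveform indices read peaks, troughs, timings and backflow", {
  dt <- 0.01
  t <- dt * (1:200)
  base <- 100 + 20 * sin(2 * pi * (t - 0.3) / 2)
  k <- 17
  shifted <- c(base[1:k] * 0 + base[1], base[1:(200 - k)])
  q <- pmax(sin(pi * t / 1), 0)          # forward half-sine: no backflow
  series <- list(t = t, P = cbind(a = base, b = shifted),
                 Q = cbind(a = q, b = q - 0.3))
  wi <- waveform_indices(series)
  expect_equal(wi$t_peak_P_s[wi$probe == "b"] - wi$t_peak_P_s[wi$probe == "a"],
               k * dt)
  expect_equal(wi$Q_max_back_mL_s[wi$probe == "a"], 0)
  expect_equal(wi$Q_max_back_mL_s[wi$probe == "b"], 0.3)
  # constant series: peak equals trough, peak time ties to the first sample
  cs <- list(t = t, P = cbind(c = rep(5, 200)), Q = cbind(c = rep(1, 200)))
  wc <- waveform_indices(cs)
  expect_equal(wc$P_peak_mmHg, wc$P_trough_mmHg)
  expect_equal(wc$t_peak_P_s, dt)
})

test_that("elastances follow their definitions on synthetic loops", {
  mk <- function(Ves, Pes, SV) {
    n <- 100
    V <- seq(Ves + SV, Ves, length.out = n)
    P <- seq(Pes / 2, Pes, length.out = n)
    cyc <- synth_cycle(V, P, t_close = 0.1)
    cyc$events$t_close <- cyc$lv$t[n]
    cyc$SV <- SV
    cyc
  }
  # EA definition: Pes / SV
  runs <- list(baseline = mk(70, 100, 50),
               case1 = mk(75, 110, 45),
               case2 = mk(80, 120, 40))
  el <- elastances(runs)
  expect_equal(el$points$EA_mmHg_mL[el$points$run == "baseline"], 2)
  # exactly collinear end-systolic points with slope 2 give ES = 2
  expect_equal(el$ES_mmHg_mL, 2, tolerance = 1e-10)
  expect_equal(unname(el$EA_over_ES["baseline"]), 1, tolerance = 1e-10)
  # degenerate (identical) points are refused
  expect_error(elastances(list(a = mk(70, 100, 50), b = mk(70, 100, 50))),
               "degenerate")
})

test_that("percentage comparisons handle identity, doubling and zero baselines", {
  base <- tibble::tibble(SV_mL = 50, SW_cJ = 80, t_ej_ms = 0)
  same <- compare_to_baseline(list(baseline = base, x = base))
  expect_true(all(unlist(same[, c("SV_mL_pct", "SW_cJ_pct")]) == 0))
  doubled <- base; doubled$SV_mL <- 100
  cmp <- compare_to_baseline(list(baseline = base, x = doubled))
  expect_equal(cmp$SV_mL_pct, 100)
  expect_true(is.na(cmp$t_ej_ms_pct))   # zero baseline -> undefined, not NaN
  expect_error(compare_to_baseline(list(x = base)), "baseline")
})
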