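# Pathological scenarios and the clinical index battery.

CASE_IDS <- c("baseline", "case1", "case2", "case3", "case4",
              "case1_iso", "case2_iso")

#' Apply a pathological scenario to a configuration
#'
#' Scenario definitions (multipliers act on the calibrated baseline):
#' * `case1` -- arterial stiffening: `k3` doubled in the large arteries
#'   (vascular-bed wall law untouched);
#' * `case2` -- vascular-bed rarefaction: radius exponent 2.76 -> 2.4;
#' * `case3` -- stiffer myocardium: a-type Holzapfel-Ogden constants doubled;
#' * `case4` -- increased contractility: `T0` raised by 33%;
#' * `case1_iso`, `case2_iso` -- the same arterial changes driven by the
#'   prescribed baseline inflow instead of the coupled ventricle.
#'
#' @param config an [lvsa_config()] (typically the calibrated baseline).
#' @param case_id one of `"baseline"`, `"case1"`, `"case2"`, `"case3"`,
#'   `"case4"`, `"case1_iso"`, `"case2_iso"`.
#' @return The modified `lvsa_config`.
#' @export
apply_case <- function(config, case_id = "baseline") {
  if (!case_id %in% CASE_IDS) {
    stop("unknown case_id '", case_id, "'; expected one of: ",
         paste(CASE_IDS, collapse = ", "))
  }
  cfg <- config
  cfg$case_id <- case_id
  if (case_id %in% c("case1", "case1_iso")) {
    tl <- cfg$net$tube_law
    tl$k3 <- 2 * tl$k3
    cfg$net$tube_law <- tl     # bed_tube_law deliberately unchanged
  }
  if (case_id %in% c("case2", "case2_iso")) {
    # rarefaction acts on the resolved trees; each bed's lumped downstream
    # (sub-r_min) compartment keeps its aggregate resistance, so the per-leaf
    # impedance is rescaled by the change in leaf count
    term <- config$net$segments[!is.na(config$net$segments$bed_root_radius_cm), ]
    tree_new <- cfg$tree
    tree_new$xi <- 2.4
    override <- vapply(seq_len(nrow(term)), function(i) {
      r <- term$bed_root_radius_cm[i]
      cfg$tree$leaf_impedance *
        count_tree_leaves(r, tree_new) / count_tree_leaves(r, cfg$tree)
    }, numeric(1))
    cfg$bed_leaf_impedance <- stats::setNames(override, term$id)
    cfg$tree <- tree_new
    cfg$beds <- NULL      # bed impedances must be rebuilt for the new trees
  }
  if (case_id == "case3") {
    cfg$lv$hop$stiffness_scale <- 2 * cfg$lv$hop$stiffness_scale
    cfg$lv <- reduced_lv(cfg$lv$geom, cfg$lv$hop, cfg$lv$actp, cfg$lv$edp)
  }
  if (case_id == "case4") {
    cfg$lv$actp$T0 <- 1.33 * cfg$lv$actp$T0
    cfg$lv <- reduced_lv(cfg$lv$geom, cfg$lv$hop, cfg$lv$actp, cfg$lv$edp)
  }
  cfg$iso <- grepl("_iso$", case_id)
  cfg
}

#' Simulate one scenario to periodicity
#'
#' Coupled runs: initialise the arterial network with the prescribed inflow
#' for `init_periods`, then repeat coupled cycles until periodic
#' ([run_until_periodic()]).  Isolated-arterial runs (`iso`): keep driving
#' the network with the prescribed baseline inflow until the probe pressures
#' are periodic.
#'
#' @param config an [lvsa_config()], usually from [apply_case()].
#' @param verbose print progress.
#' @return Object of class `lvsa_run`: `case_id`, `iso`, `cycle` (coupled
#'   runs; `NULL` for iso), `sa` (probe series of the converged period),
#'   `converged`, `convergence_metric`, `diag`, `config`.
#' @export
simulate_case <- function(config, verbose = FALSE) {
  if (config$iso) {
    sim <- init_sa(config)
    run_sa(config$net, config$inflow, periods = 1, sim = sim)
    prev <- sa_series(sim)$P
    metric <- Inf
    converged <- FALSE
    n <- config$solver$n_per_period
    for (k in seq_len(config$coupling$max_cycles)) {
      sa_clear_series(sim)
      run_sa(config$net, config$inflow, periods = 1, sim = sim)
      cur <- sa_series(sim)$P
      metric <- max(abs(cur - prev)) / max(cur)
      prev <- cur
      if (metric < config$coupling$convergence_threshold) { converged <- TRUE; break }
    }
    ser <- sa_series(sim)
    res <- list(case_id = config$case_id, iso = TRUE, cycle = NULL, sa = ser,
                converged = converged, convergence_metric = metric,
                diag = sa_diagnostics(sim), config = config)
  } else {
    sim <- init_sa(config)
    sa_reset_volumes(sim)
    per <- run_until_periodic(config$lv, sim, config$coupling)
    res <- list(case_id = config$case_id, iso = FALSE, cycle = per$cycle,
                sa = per$cycle$sa, converged = per$converged,
                convergence_metric = utils::tail(per$metrics, 1),
                metrics = per$metrics, converged_cycle = per$converged_cycle,
                cycles = per$cycles,
                diag = sa_diagnostics(sim), config = config)
  }
  if (verbose) {
    message(sprintf("%s: converged = %s (metric %.3g)", config$case_id,
                    res$converged, res$convergence_metric))
  }
  structure(res, class = "lvsa_run")
}

#' @export
print.lvsa_run <- function(x, ...) {
  cat(sprintf("Scenario run '%s'%s: converged = %s (metric %.3g)\n",
              x$case_id, if (x$iso) " [isolated SA]" else "",
              x$converged, x$convergence_metric))
  if (!is.null(x$cycle)) print(x$cycle)
  invisible(x)
}

#' Ventricular pump-function indices of a converged cycle
#'
#' Peak active tension, peak aortic (outflow-tract) and cavity pressures,
#' peak interface flow, stroke volume, stroke work (pressure-volume loop
#' area, in cJ), ejection duration and ejection fraction.
#'
#' @param cycle a `cycle_result` from [run_phase_machine()] (or an
#'   `lvsa_run`), flagged as converged by the caller.
#' @param refuse_unconverged error when the run carries `converged = FALSE`.
#' @return One-row tibble of indices.
#' @export
lv_indices <- function(cycle, refuse_unconverged = TRUE) {
  if (inherits(cycle, "lvsa_run")) {
    if (refuse_unconverged && !isTRUE(cycle$converged)) {
      stop("run is not converged; pass refuse_unconverged = FALSE to override")
    }
    cycle <- cycle$cycle
  }
  if (is.null(cycle)) stop("no coupled cycle available (isolated run?)")
  sw_mmHg_mL <- abs(loop_area(cycle$lv$V, cycle$lv$P_lv))
  q_pk <- if (nrow(cycle$interface)) max(cycle$interface$Q_minus) else 0
  p_ao <- if (nrow(cycle$interface)) max(cycle$sa$inlet$P_mmHg) else NA_real_
  tibble::tibble(
    Tpeak_kPa = max(cycle$lv$activation),
    Ppeak_ao_mmHg = p_ao,
    Ppeak_LV_mmHg = max(cycle$lv$P_lv),
    Qpeak_ao_mL_s = q_pk,
    SV_mL = cycle$SV,
    SW_cJ = mmHg_mL_to_cJ(sw_mmHg_mL),
    t_ej_ms = 1e3 * cycle$t_ej,
    EF = cycle$SV / cycle$EDV)
}

# shoelace-type loop area, invariant to the cycle start point
loop_area <- function(V, P) {
  n <- length(V)
  j <- c(2:n, 1)
  sum((P + P[j]) / 2 * (V[j] - V))
}

#' Waveform indices at every probe
#'
#' Peak pressure, trough pressure, pressure peak time, peak flow, flow peak
#' time and maximum backflow over one converged period.  Peak times are
#' relative to the cycle start; ties resolve to the earliest sample.
#'
#' @param series a probe series list (`sa` element of a run: `t`, matrices
#'   `P`, `Q`).
#' @return Tibble with one row per probe.
#' @export
waveform_indices <- function(series) {
  t_rel <- series$t - series$t[1] + (series$t[2] - series$t[1])
  out <- lapply(colnames(series$P), function(nm) {
    Pv <- series$P[, nm]; Qv <- series$Q[, nm]
    tibble::tibble(
      probe = nm,
      t_peak_P_s = t_rel[which.max(Pv)],
      P_peak_mmHg = max(Pv),
      P_trough_mmHg = min(Pv),
      t_peak_Q_s = t_rel[which.max(Qv)],
      Q_peak_mL_s = max(Qv),
      Q_max_back_mL_s = max(0, -min(Qv)))
  })
  dplyr::bind_rows(out)
}

#' Ventricular-arterial elastances
#'
#' Effective arterial elastance `E_A = P_es / SV` per run, with the
#' end-systolic point taken at aortic-valve closure, and end-systolic
#' elastance `E_S` as the least-squares slope of the line through the
#' end-systolic (V, P) points of the supplied runs (afterload varies,
#' contractility does not: baseline plus the arterial-stiffening and
#' rarefaction scenarios).
#'
#' @param runs named list of converged coupled `lvsa_run`/`cycle_result`
#'   objects (at least baseline, case1, case2).
#' @return List: `points` (tibble of end-systolic V, P, SV, EA per run),
#'   `ES_mmHg_mL`, `EA_over_ES` (named vector).
#' @export
elastances <- function(runs) {
  pts <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    cyc <- if (inherits(r, "lvsa_run")) r$cycle else r
    es <- end_systolic_point(cyc)
    tibble::tibble(run = nm, V_es_mL = es$V, P_es_mmHg = es$P,
                   SV_mL = cyc$SV, EA_mmHg_mL = es$P / cyc$SV)
  })
  pts <- dplyr::bind_rows(pts)
  if (nrow(pts) < 2 || stats::sd(pts$V_es_mL) < 1e-9) {
    stop("end-systolic points are degenerate; need distinct afterload states")
  }
  fit <- stats::lm(P_es_mmHg ~ V_es_mL, data = pts)
  ES <- unname(stats::coef(fit)[2])
  list(points = pts, ES_mmHg_mL = ES,
       EA_over_ES = stats::setNames(pts$EA_mmHg_mL / ES, pts$run))
}

# (V, P) of the ventricle at aortic-valve closure
end_systolic_point <- function(cycle) {
  if (is.na(cycle$events$t_close)) stop("cycle has no ejection phase")
  k <- which.min(abs(cycle$lv$t - cycle$events$t_close))
  list(V = cycle$lv$V[k], P = cycle$lv$P_lv[k])
}

#' Percent changes of indices relative to baseline
#'
#' `(case - baseline) / baseline * 100` for every shared numeric column.
#' Indices whose baseline value is zero are reported as `NA` (undefined)
#' rather than propagating infinities.
#'
#' @param reports named list of one-row index tibbles ([lv_indices()]), one
#'   of them named `baseline`.
#' @param digits round the percentage table (default one decimal).
#' @return Tibble: one row per non-baseline case, percentage columns.
#' @export
compare_to_baseline <- function(reports, digits = 1) {
  if (!"baseline" %in% names(reports)) stop("reports must include 'baseline'")
  base <- reports$baseline
  num <- names(base)[vapply(base, is.numeric, logical(1))]
  rows <- lapply(setdiff(names(reports), "baseline"), function(nm) {
    r <- reports[[nm]]
    pct <- lapply(num, function(cn) {
      b <- base[[cn]]; v <- r[[cn]]
      if (!is.finite(b) || b == 0) NA_real_ else round((v - b) / b * 100, digits)
    })
    names(pct) <- paste0(num, "_pct")
    tibble::tibble(case = nm, !!!pct)
  })
  dplyr::bind_rows(rows)
}
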