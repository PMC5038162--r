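# R-side surface of the 1D network solver: discretisation, stepping, runs.

#' Solver settings for the 1D network scheme
#'
#' @param t_period cardiac period (s).
#' @param n_per_period number of time steps per period (power of two; the
#'   terminal convolution and the impedance spectra share this length).
#' @param cfl_limit hard Courant-number bound checked at every step.
#' @param cfl_target Courant number the spatial grids are sized for at the
#'   unstressed state (with a velocity/wave-speed safety margin).
#' @param junction_tolerance relative residual bound for the junction and
#'   terminal Newton solves.
#' @param max_junction_iters iteration cap for those solves.
#' @return An object of class `solver_settings`; `dt = t_period/n_per_period`.
#' @export
solver_settings <- function(t_period = 0.9, n_per_period = 8192,
                            cfl_limit = 1.0, cfl_target = 0.9,
                            junction_tolerance = 1e-11,
                            max_junction_iters = 60) {
  if (t_period <= 0) stop("t_period must be positive")
  if (n_per_period < 4 || bitwAnd(n_per_period, n_per_period - 1L) != 0) {
    stop("n_per_period must be a power of two")
  }
  if (cfl_limit <= 0 || cfl_limit > 1) stop("cfl_limit must be in (0, 1]")
  if (cfl_target <= 0 || cfl_target > cfl_limit) {
    stop("cfl_target must be in (0, cfl_limit]")
  }
  structure(list(t_period = t_period, n_per_period = as.integer(n_per_period),
                 dt = t_period / n_per_period, cfl_limit = cfl_limit,
                 cfl_target = cfl_target,
                 junction_tolerance = junction_tolerance,
                 max_junction_iters = as.integer(max_junction_iters)),
            class = "solver_settings")
}

# grid sizing: dx such that (1.2 c0 + 150 cm/s) dt / dx <= cfl_target, where
# c0 is the unstressed wave speed at the narrow end of the segment
segment_grid <- function(seg, tube_law, settings) {
  c0 <- wave_speed(pi * seg$r_bottom_cm^2, seg$r_bottom_cm, tube_law)
  dx_max <- (1.2 * c0 + 150) * settings$dt / settings$cfl_target
  n <- max(3L, as.integer(ceiling(seg$length_cm / dx_max)) + 1L)
  n
}

#' Build a stepping simulator for an arterial network
#'
#' Discretises every segment (grid sized from the unstressed wave speed so
#' the Courant number stays below `cfl_target` at the paper-scale time step),
#' attaches the structured-tree impedance of every terminal bed, and returns
#' a stateful simulator advanced by [sa_step()] / [sa_run_steps()].  The
#' state starts at rest: `A = A0`, `Q = 0`, zero convolution history.
#'
#' @param net an [arterial_network()].
#' @param settings a [solver_settings()].
#' @param tree a [tree_params()] describing the vascular beds.
#' @param bed_tube_law wall-law parameters for the small vessels inside the
#'   beds; defaults to the network's tube law.  Kept separate so large-artery
#'   stiffening scenarios leave the beds untouched.
#' @param beds optional precomputed list of [root_impedance()] spectra named
#'   by terminal segment id (recomputed otherwise).
#' @param leaf_impedance_override optional named vector (by terminal segment
#'   id) of per-bed leaf impedances replacing `tree$leaf_impedance`, used
#'   when the downstream compartment differs between beds.
#' @return An object of class `sa_sim` (holds an external pointer; copy via
#'   [sa_state()] / [sa_restore()], not by duplicating the object).
#' @export
sa_sim <- function(net, settings = solver_settings(), tree = tree_params(),
                   bed_tube_law = NULL, beds = NULL,
                   leaf_impedance_override = NULL) {
  if (is.null(bed_tube_law)) bed_tube_law <- net$tube_law
  seg <- net$segments
  id2idx <- stats::setNames(seq_len(nrow(seg)), seg$id)
  term <- terminal_ids(net)
  if (is.null(beds)) {
    beds <- lapply(stats::setNames(term, term), function(tid) {
      r <- seg$bed_root_radius_cm[seg$id == tid]
      p_bed <- tree
      if (!is.null(leaf_impedance_override) &&
          as.character(tid) %in% names(leaf_impedance_override)) {
        p_bed$leaf_impedance <- leaf_impedance_override[[as.character(tid)]]
      }
      root_impedance(r, p_bed, bed_tube_law,
                     t_period = settings$t_period,
                     n_freq = settings$n_per_period)
    })
  } else if (!all(as.character(term) %in% names(beds))) {
    stop("beds must contain an impedance spectrum for every terminal segment")
  }
  seg_list <- lapply(seq_len(nrow(seg)), function(i) {
    row <- seg[i, ]
    terminal <- is.na(row$daughter_1) && is.na(row$daughter_2)
    list(length = row$length_cm, r_top = row$r_top_cm,
         r_bottom = row$r_bottom_cm,
         n = segment_grid(row, net$tube_law, settings),
         d1 = if (is.na(row$daughter_1)) -1L else id2idx[[as.character(row$daughter_1)]] - 1L,
         d2 = if (is.na(row$daughter_2)) -1L else id2idx[[as.character(row$daughter_2)]] - 1L,
         terminal = terminal,
         zimp = if (terminal) beds[[as.character(row$id)]]$z_time else NULL)
  })
  par <- list(rho = net$tube_law$rho, nu = net$tube_law$nu,
              delta_star = net$tube_law$delta_star, P0 = net$tube_law$P0,
              k1 = net$tube_law$k1, k2 = net$tube_law$k2, k3 = net$tube_law$k3,
              dt = settings$dt, cfl_limit = settings$cfl_limit,
              junction_tolerance = settings$junction_tolerance,
              max_junction_iters = settings$max_junction_iters,
              root = id2idx[[as.character(net$root_id)]] - 1L)
  ptr <- sa_create_(seg_list, par, settings$n_per_period)
  structure(list(ptr = ptr, net = net, settings = settings, tree = tree,
                 beds = beds, bed_tube_law = bed_tube_law,
                 n_grid = vapply(seg_list, `[[`, integer(1), "n")),
            class = "sa_sim")
}

#' @export
print.sa_sim <- function(x, ...) {
  d <- sa_diag_(x$ptr)
  cat(sprintf("1D network simulator: %d segments, %d nodes, dt = %.3g ms, t = %.4f s (%d steps)\n",
              nrow(x$net$segments), sum(x$n_grid),
              1e3 * x$settings$dt, d$t, as.integer(d$step)))
  invisible(x)
}

#' Advance the simulator
#'
#' [sa_step()] advances one time step with inlet flow `q_in` (mL/s) applied
#' at the root; `interior_only = TRUE` advances the two-step Lax-Wendroff
#' interior update and leaves all boundary nodes untouched (used to test the
#' scheme in isolation).  [sa_run_steps()] advances one step per element of
#' `q_in`.
#'
#' @param sim an [sa_sim()] object.
#' @param q_in inlet volumetric flow (mL/s): scalar for [sa_step()], vector
#'   for [sa_run_steps()].
#' @param interior_only advance interior nodes only.
#' @return The simulator, invisibly (state is advanced in place).
#' @export
sa_step <- function(sim, q_in = 0, interior_only = FALSE) {
  sa_step_(sim$ptr, q_in, interior_only)
  invisible(sim)
}

#' @rdname sa_step
#' @export
sa_run_steps <- function(sim, q_in) {
  sa_run_(sim$ptr, q_in)
  invisible(sim)
}

#' Current root-inlet pressure of a simulator (CGS)
#' @param sim an [sa_sim()] object.
#' @return Pressure at the proximal node of the root segment, dyn cm^-2.
#' @export
sa_root_pressure <- function(sim) sa_root_pressure_(sim$ptr)

#' Hypothetical inlet pressure for a candidate inflow
#'
#' Evaluates the pressure the root inlet would take at the next time level if
#' the inflow were `q`, using the incoming characteristic of the current
#' state; the state is not advanced.  This is the arterial half of the
#' systolic pressure/flow exchange.
#'
#' @param sim an [sa_sim()] object.
#' @param q candidate inlet flow (mL/s).
#' @return Pressure in dyn cm^-2.
#' @export
sa_inlet_pressure <- function(sim, q) sa_inlet_pressure_(sim$ptr, q)

#' Snapshot / restore the solver state
#'
#' Captures (A, Q) on every segment plus the terminal convolution histories,
#' so a pre-initialised arterial tree can be reused across coupled runs
#' (e.g. during contractility calibration).
#'
#' @param sim an [sa_sim()] object.
#' @param state a state previously returned by [sa_state()].
#' @return [sa_state()] returns an opaque list; [sa_restore()] the simulator.
#' @export
sa_state <- function(sim) sa_state_get_(sim$ptr)

#' @rdname sa_state
#' @export
sa_restore <- function(sim, state) {
  sa_state_set_(sim$ptr, state)
  invisible(sim)
}

#' Recorded probe series of a simulator
#'
#' The solver records pressure, flow and area at the midpoint of every
#' segment (and at the root inlet) at every step.  Series accumulate until
#' [sa_clear_series()].
#'
#' @param sim an [sa_sim()] object.
#' @param decimate keep every `decimate`-th sample (endpoints preserved).
#' @return A list with `t` (s), matrices `P` (mmHg), `Q` (mL/s), `A` (cm^2)
#'   of dimension steps x segments (columns named by segment), and an
#'   `inlet` tibble with the root-inlet series.
#' @export
sa_series <- function(sim, decimate = 1L) {
  raw <- sa_series_(sim$ptr)
  idx <- seq_along(raw$t)
  if (decimate > 1L) {
    idx <- unique(c(seq(1L, length(idx), by = as.integer(decimate)), length(idx)))
  }
  nm <- sim$net$segments$name
  P <- raw$P[idx, , drop = FALSE] / MMHG_DYN
  Q <- raw$Q[idx, , drop = FALSE]
  A <- raw$A[idx, , drop = FALSE]
  colnames(P) <- colnames(Q) <- colnames(A) <- nm
  list(t = raw$t[idx], P = P, Q = Q, A = A,
       inlet = tibble::tibble(t = raw$t[idx],
                              P_mmHg = raw$inlet_P[idx] / MMHG_DYN,
                              Q_mL_s = raw$inlet_Q[idx],
                              A_cm2 = raw$inlet_A[idx]))
}

#' @rdname sa_series
#' @export
sa_clear_series <- function(sim) {
  sa_clear_series_(sim$ptr)
  invisible(sim)
}

#' Solver diagnostics
#'
#' @param sim an [sa_sim()] object.
#' @return List: current time and step, worst Courant number seen, worst
#'   junction residual of the last step, cumulative inlet volume and
#'   per-segment terminal outflow volumes (mL).
#' @export
sa_diagnostics <- function(sim) {
  d <- sa_diag_(sim$ptr)
  names(d$out_volume) <- sim$net$segments$name
  d
}

#' @rdname sa_diagnostics
#' @export
sa_reset_volumes <- function(sim) {
  sa_reset_volumes_(sim$ptr)
  invisible(sim)
}

#' Warm-start a simulator at its DC operating point
#'
#' Sets the state to the zero-frequency (Poiseuille) solution of the
#' network: uniform pressure `P_mmHg`, each vascular bed carrying its DC
#' flow `(P - P0)/R_dc`, each large artery carrying the sum of its
#' downstream bed flows, and the terminal convolution histories primed with
#' those steady flows.  The subsequent prescribed-inflow initialisation
#' periods then only need to converge the pulsatile component, which
#' travels on the fast wave time scale.
#'
#' @param sim an [sa_sim()] object.
#' @param P_mmHg operating pressure (mean arterial pressure).
#' @return The simulator, invisibly.
#' @export
sa_warm_start <- function(sim, P_mmHg = 100) {
  seg <- sim$net$segments
  law <- sim$net$tube_law
  P <- mmHg_to_cgs(P_mmHg)
  q_bed <- stats::setNames(rep(0, nrow(seg)), seg$id)
  for (tid in terminal_ids(sim$net)) {
    q_bed[[as.character(tid)]] <- (P - law$P0) / sim$beds[[as.character(tid)]]$R_dc
  }
  q_seg <- function(id) {
    row <- seg[seg$id == id, ]
    if (is.na(row$daughter_1)) return(q_bed[[as.character(id)]])
    q <- q_seg(row$daughter_1)
    if (!is.na(row$daughter_2)) q <- q + q_seg(row$daughter_2)
    q
  }
  st <- sa_state(sim)
  for (i in seq_len(nrow(seg))) {
    snap <- sa_snapshot_(sim$ptr, i - 1L)
    q <- q_seg(seg$id[i])
    st$segs[[i]]$A <- area_from_pressure(rep(P, length(snap$r0)), snap$r0, law)
    st$segs[[i]]$Q <- rep(q, length(snap$r0))
    if (length(st$segs[[i]]$qhist)) {
      st$segs[[i]]$qhist <- rep(q, length(st$segs[[i]]$qhist))
      st$segs[[i]]$q_out_prev <- q
    }
  }
  st$q_in_prev <- q_seg(sim$net$root_id)
  sa_restore(sim, st)
  invisible(sim)
}

#' Run the arterial model with a prescribed inflow
#'
#' Advances the network for `periods` cardiac periods driven by an inflow
#' waveform at the aortic root, recording every probe at every step.  This is
#' the isolated-arterial ("SA-only") mode; the coupled mode replaces the
#' prescribed inflow with the ventricular exchange (see
#' [run_until_periodic()]).
#'
#' @param net an [arterial_network()].
#' @param inflow an [make_inflow()] waveform (or any function of time, s ->
#'   mL/s).
#' @param periods number of cardiac periods to run.
#' @param settings a [solver_settings()].
#' @param tree a [tree_params()].
#' @param sim optionally, an existing [sa_sim()] to continue (net/settings
#'   ignored then).
#' @param decimate decimation factor for the returned series.
#' @return An object of class `sa_result`: list with `series` (see
#'   [sa_series()]), `diag`, `periods`, `settings`, and the simulator in
#'   `sim` for continuation.
#' @export
run_sa <- function(net, inflow, periods = 4, settings = solver_settings(),
                   tree = tree_params(), sim = NULL, decimate = 1L) {
  if (periods < 1) stop("periods must be >= 1")
  if (is.null(sim)) sim <- sa_sim(net, settings, tree)
  qf <- if (inherits(inflow, "inflow_waveform")) inflow$fun else inflow
  st <- sa_diag_(sim$ptr)
  n <- sim$settings$n_per_period
  for (k in seq_len(periods)) {
    tt <- st$t + sim$settings$dt * (seq_len(n) + (k - 1) * n)
    sa_run_steps(sim, qf(tt %% sim$settings$t_period))
  }
  structure(list(series = sa_series(sim, decimate), diag = sa_diagnostics(sim),
                 periods = periods, settings = sim$settings, sim = sim),
            class = "sa_result")
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf("Arterial run: %d period(s), %d samples, max CFL %.3f\n",
              x$periods, length(x$series$t), x$diag$max_cfl))
  invisible(x)
}

#' Relative pressure difference between consecutive periods
#'
#' Periodicity metric: `max_{probe,time} |P_k - P_{k-1}| / max P_k` computed
#' on the recorded probe matrix for the last two full periods.
#'
#' @param series a series list from [sa_series()] (undecimated).
#' @param n_per_period samples per period.
#' @return Scalar relative difference (fraction; multiply by 100 for %).
#' @export
period_pressure_diff <- function(series, n_per_period) {
  n <- nrow(series$P)
  if (n < 2 * n_per_period) stop("need at least two full periods")
  last <- series$P[(n - n_per_period + 1):n, , drop = FALSE]
  prev <- series$P[(n - 2 * n_per_period + 1):(n - n_per_period), , drop = FALSE]
  max(abs(last - prev)) / max(last)
}
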