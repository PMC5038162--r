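# Configuration, inflow waveforms, test fixtures, run serialisation.

#' Prescribed aortic inflow waveform
#'
#' Smooth systolic pulse `Q(t) = Q_peak * sin(pi t / t_ej)^p` on
#' `[0, t_ej]`, zero for the rest of the period.  The exponent `p` is solved
#' from the volume constraint `int Q dt = SV` (the closed form of the
#' integral is `Q_peak t_ej * Gamma(p/2 + 1/2) / (sqrt(pi) Gamma(p/2 + 1))`),
#' so the waveform has exact peak `Q_peak`, exact duration `t_ej`, and the
#' requested stroke volume; `SV = Q_peak t_ej / 2` gives exactly the
#' squared-sine pulse (`p = 2`).
#'
#' @param SV stroke volume (mL).
#' @param Q_peak peak flow (mL/s).
#' @param t_ej ejection duration (s).
#' @param period cardiac period (s).
#' @return Object of class `inflow_waveform` with a vectorised `fun(t)`
#'   (t in `[0, period)`; callers wrap time modulo the period).
#' @export
make_inflow <- function(SV = 72.6, Q_peak = 532, t_ej = 0.22, period = 0.9) {
  if (any(c(SV, Q_peak, t_ej, period) <= 0)) stop("all inflow parameters must be positive")
  if (t_ej >= period) stop("t_ej must be shorter than the period")
  ratio <- SV / (Q_peak * t_ej)
  if (ratio >= 1) {
    stop(sprintf("infeasible inflow: SV must be below Q_peak * t_ej = %.3g mL", Q_peak * t_ej))
  }
  shape_int <- function(p) exp(lgamma(p / 2 + 0.5) - lgamma(p / 2 + 1)) / sqrt(pi)
  p_exp <- stats::uniroot(function(p) shape_int(p) - ratio,
                          interval = c(1e-4, 400), tol = 1e-12)$root
  fun <- function(t) {
    q <- numeric(length(t))
    syst <- t >= 0 & t <= t_ej
    q[syst] <- Q_peak * sin(pi * t[syst] / t_ej)^p_exp
    q
  }
  vol <- stats::integrate(fun, 0, t_ej, rel.tol = 1e-10)$value
  if (abs(vol - SV) > 1e-3 * SV) {
    stop("internal error: inflow volume misses SV by more than 0.1%")
  }
  structure(list(fun = fun, SV = SV, Q_peak = Q_peak, t_ej = t_ej,
                 period = period, exponent = p_exp),
            class = "inflow_waveform")
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf("Inflow pulse: SV %.1f mL, peak %.0f mL/s, t_ej %.0f ms, exponent %.3f\n",
              x$SV, x$Q_peak, 1e3 * x$t_ej, x$exponent))
  invisible(x)
}

#' Built-in test networks
#'
#' Small fixture networks used throughout the test-suite plus the default
#' 24-artery tree: `single_vessel` (one uniform terminal vessel),
#' `symmetric_bifurcation` (a parent with two identical daughters), and
#' `default24` (see [default_network()]).
#'
#' @param kind one of `"single_vessel"`, `"symmetric_bifurcation"`,
#'   `"default24"`.
#' @param tube_law a [tube_law_params()].
#' @return An [arterial_network()].
#' @export
make_test_network <- function(kind = c("single_vessel", "symmetric_bifurcation",
                                       "default24"),
                              tube_law = tube_law_params()) {
  kind <- match.arg(kind)
  if (kind == "single_vessel") {
    seg <- tibble::tibble(id = 1L, name = "vessel", length_cm = 10,
                          r_top_cm = 0.3, r_bottom_cm = 0.3,
                          daughter_1 = NA_integer_, daughter_2 = NA_integer_,
                          bed_root_radius_cm = 0.3)
    arterial_network(seg, tube_law)
  } else if (kind == "symmetric_bifurcation") {
    seg <- tibble::tibble(
      id = 1:3,
      name = c("parent", "daughter_a", "daughter_b"),
      length_cm = c(8, 8, 8),
      r_top_cm = c(0.5, 0.35, 0.35), r_bottom_cm = c(0.5, 0.35, 0.35),
      daughter_1 = c(2L, NA, NA), daughter_2 = c(3L, NA, NA),
      bed_root_radius_cm = c(NA, 0.35, 0.35))
    arterial_network(seg, tube_law)
  } else {
    default_network(tube_law)
  }
}

#' Full run configuration
#'
#' Bundles everything a simulation needs: the network, wall laws (large
#' arteries and vascular beds kept separate so arterial-stiffening scenarios
#' leave the beds untouched), structured-tree parameters, the reduced
#' ventricle, solver and coupling settings, the initialisation inflow and
#' the scenario id.
#'
#' @param net an [arterial_network()].
#' @param tree a [tree_params()].
#' @param lv a [reduced_lv()].
#' @param solver a [solver_settings()].
#' @param coupling a [coupling_settings()].
#' @param inflow an [make_inflow()] waveform for initialisation / iso runs.
#' @param bed_tube_law wall law for the small vessels (default: same as the
#'   network's).
#' @param case_id scenario label.
#' @param iso if `TRUE` the run is arterial-only with the prescribed inflow.
#' @param beds optional precomputed bed impedance spectra (named by terminal
#'   segment id) reused across runs that share tree parameters.
#' @return Object of class `lvsa_config`.
#' @export
lvsa_config <- function(net, tree = tree_params(), lv = reduced_lv(),
                        solver = solver_settings(),
                        coupling = coupling_settings(),
                        inflow = make_inflow(period = solver$t_period),
                        bed_tube_law = NULL, case_id = "baseline",
                        iso = FALSE, beds = NULL) {
  if (is.null(bed_tube_law)) bed_tube_law <- net$tube_law
  structure(list(net = net, tree = tree, lv = lv, solver = solver,
                 coupling = coupling, inflow = inflow,
                 bed_tube_law = bed_tube_law, case_id = case_id, iso = iso,
                 beds = beds, bed_leaf_impedance = NULL),
            class = "lvsa_config")
}

#' Default baseline configuration
#'
#' The study conditions: default 24-artery network, structured-tree beds
#' (xi = 2.76, termination at 100 um), reduced LV, 0.9 s period with 8192
#' steps.  The structured trees resolve the arterial side of each vascular
#' bed; the downstream arteriolar/capillary resistance beyond the 100 um
#' leaves is represented by a uniform constant leaf impedance, solved so
#' that the total DC resistance satisfies the physiological anchor
#' `mean arterial pressure = R_total * CO` at the baseline cardiac output
#' (the external pressure `P0` stays at zero, keeping the large arteries at
#' a physiological transmural pressure).
#'
#' @param mean_pressure_mmHg anchor for the DC pressure relation.
#' @param cardiac_output_mL_s baseline cardiac output used in the anchor.
#' @param ... overrides passed to [lvsa_config()].
#' @return An `lvsa_config`.
#' @export
default_config <- function(mean_pressure_mmHg = 100,
                           cardiac_output_mL_s = 72.6 / 0.9, ...) {
  law <- tube_law_params()
  net <- default_network(law)
  term <- net$segments$bed_root_radius_cm
  term <- term[!is.na(term)]
  mu <- law$rho * law$nu
  R_target <- mmHg_to_cgs(mean_pressure_mmHg) / cardiac_output_mL_s - law$P0
  r_tot <- function(z_leaf) {
    R <- vapply(term, tree_dc_resistance, numeric(1),
                p = tree_params(leaf_impedance = z_leaf), mu = mu)
    1 / sum(1 / R)
  }
  if (r_tot(0) >= R_target) {
    z_leaf <- 0
  } else {
    z_leaf <- exp(stats::uniroot(function(x) r_tot(exp(x)) - R_target,
                                 interval = c(log(1), log(1e12)),
                                 tol = 1e-9)$root)
  }
  lvsa_config(net = net, tree = tree_params(leaf_impedance = z_leaf), ...)
}

#' Write / read a configuration file
#'
#' Serialises the scalar parameter blocks of an [lvsa_config()] (wall law,
#' tree, ventricle, solver, coupling, inflow, case) to YAML or JSON, with a
#' path to the network table; [read_config()] rebuilds the configuration,
#' re-deriving everything the constructors derive (grids, impedances, EDV).
#' Units follow the constructors: pressures mmHg, lengths cm, times s.
#'
#' @param config an [lvsa_config()].
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param network_path where the network table is (to be) stored; defaults
#'   to the packaged 24-artery table.
#' @return [write_config()]: `path` invisibly; [read_config()]: an
#'   `lvsa_config`.
#' @export
write_config <- function(config, path, network_path = NULL) {
  law <- config$net$tube_law
  lv <- config$lv
  payload <- list(
    network = network_path %||% "default24",
    case_id = config$case_id,
    iso = config$iso,
    tube_law = list(k1 = law$k1, k2 = law$k2, k3 = law$k3,
                    P0_mmHg = cgs_to_mmHg(law$P0), rho = law$rho, nu = law$nu,
                    delta_star = law$delta_star),
    tree = unclass(config$tree),
    chamber = list(Ri = lv$geom$Ri, Ro = lv$geom$Ro),
    ho = unclass(lv$hop),
    activation = unclass(lv$actp),
    edp_mmHg = lv$edp,
    solver = unclass(config$solver)[c("t_period", "n_per_period", "cfl_limit",
                                      "cfl_target", "junction_tolerance",
                                      "max_junction_iters")],
    coupling = unclass(config$coupling),
    inflow = list(SV = config$inflow$SV, Q_peak = config$inflow$Q_peak,
                  t_ej = config$inflow$t_ej, period = config$inflow$period))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_config
#' @export
read_config <- function(path) {
  p <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  law <- do.call(tube_law_params, p$tube_law)
  net <- if (identical(p$network, "default24")) {
    default_network(law)
  } else {
    read_network(p$network, law)
  }
  tree <- do.call(tree_params, p$tree[c("xi", "gamma", "r_min", "lr_ratio",
                                        "leaf_impedance")])
  geom <- chamber_geometry(p$chamber$Ri, p$chamber$Ro)
  hop <- do.call(ho_params, p$ho[c("a", "b", "af", "bf", "as_", "bs", "afs",
                                   "bfs", "passive_scale", "stiffness_scale")])
  actp <- do.call(activation_params, p$activation)
  solver <- do.call(solver_settings, p$solver)
  coupling <- do.call(coupling_settings, p$coupling)
  inflow <- do.call(make_inflow, p$inflow)
  lvsa_config(net = net, tree = tree,
              lv = reduced_lv(geom, hop, actp, edp = p$edp_mmHg),
              solver = solver, coupling = coupling, inflow = inflow,
              case_id = p$case_id, iso = isTRUE(p$iso))
}

#' Write / read a simulation run directory
#'
#' One CSV per probe (`probe_<segment>.csv` with columns `t_s`, `P_mmHg`,
#' `Q_mL_per_s`, `A_cm2`), the root-inlet series, and a JSON manifest with
#' the case id, settings, convergence information and file checksums.
#'
#' @param series a series list (from [sa_series()] or a run object).
#' @param path output directory (created if needed).
#' @param manifest named list merged into the manifest (case id, convergence
#'   flags, calibration report, ...).
#' @param decimate keep every n-th sample when writing.
#' @return [write_run()]: `path` invisibly.  [read_run()]: a list with
#'   `series` (numerically identical to what was written) and `manifest`.
#' @export
write_run <- function(series, path, manifest = list(), decimate = 1L) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  idx <- seq_along(series$t)
  if (decimate > 1L) {
    idx <- unique(c(seq(1L, length(idx), by = as.integer(decimate)), length(idx)))
  }
  files <- character(0)
  for (nm in colnames(series$P)) {
    df <- data.frame(t_s = series$t[idx], P_mmHg = series$P[idx, nm],
                     Q_mL_per_s = series$Q[idx, nm], A_cm2 = series$A[idx, nm])
    f <- file.path(path, paste0("probe_", nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  f_in <- file.path(path, "inlet.csv")
  utils::write.csv(as.data.frame(series$inlet[idx, ]), f_in, row.names = FALSE)
  files <- c(files, f_in)
  man <- c(list(format_version = 1L,
                package_version = as.character(utils::packageVersion("lvsa")),
                n_samples = length(idx), decimate = as.integer(decimate),
                probes = colnames(series$P),
                checksums = as.list(tools::md5sum(files))),
           manifest)
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  man <- jsonlite::fromJSON(mf)
  if (is.null(man$format_version) || man$format_version != 1L) {
    stop("unsupported run format version: ", man$format_version)
  }
  probes <- man$probes
  cols <- lapply(probes, function(nm) {
    utils::read.csv(file.path(path, paste0("probe_", nm, ".csv")))
  })
  t <- cols[[1]]$t_s
  bind <- function(field) {
    m <- do.call(cbind, lapply(cols, `[[`, field))
    colnames(m) <- probes
    m
  }
  inlet <- tibble::as_tibble(utils::read.csv(file.path(path, "inlet.csv")))
  list(series = list(t = t, P = bind("P_mmHg"), Q = bind("Q_mL_per_s"),
                     A = bind("A_cm2"), inlet = inlet),
       manifest = man)
}
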