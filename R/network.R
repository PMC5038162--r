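# Large-artery network: geometry, topology and the elastic tube law.

#' Tube-law (wall) parameters for the large arteries
#'
#' Material constants of the pressure--area relation closing the 1D flow
#' equations.  The wall stiffness varies with unstressed radius as
#' `Eh/r0 = k1 * exp(k2 * r0) + k3`, so small vessels are relatively stiffer
#' than the aorta.  Defaults are the standard structured-tree systemic-artery
#' values in CGS units.
#'
#' @param k1 stiffness coefficient (g s^-2 cm^-1).
#' @param k2 exponential rate (cm^-1, negative).
#' @param k3 stiffness offset (g s^-2 cm^-1).
#' @param P0_mmHg external reference pressure (mmHg); the cross-section is
#'   `A0` when the transmural pressure equals `P0`.  Stored internally in
#'   dyn cm^-2.
#' @param rho blood density (g cm^-3).
#' @param nu kinematic viscosity (cm^2 s^-1).
#' @param delta_star boundary-layer width (cm) entering the wall-friction
#'   term.  Default is the oscillatory (Womersley) boundary-layer estimate
#'   `sqrt(nu * t_period / (2*pi))`.
#' @param t_period cardiac period (s), used only for the `delta_star` default.
#' @return An object of class `tube_law_params`.
#' @examples
#' p <- tube_law_params()
#' wall_stiffness(1.0, p)   # aortic Eh/r0, g s^-2 cm^-1
#' @export
tube_law_params <- function(k1 = 2e7, k2 = -22.53, k3 = 8.65e5,
                            P0_mmHg = 0, rho = 1.055, nu = 0.046,
                            delta_star = NULL, t_period = 0.9) {
  if (k1 < 0) stop("k1 must be >= 0")
  if (k3 <= 0) stop("k3 must be > 0")
  if (rho <= 0 || nu <= 0) stop("rho and nu must be > 0")
  if (is.null(delta_star)) delta_star <- sqrt(nu * t_period / (2 * pi))
  if (delta_star <= 0) stop("delta_star must be > 0")
  structure(
    list(k1 = k1, k2 = k2, k3 = k3,
         P0 = mmHg_to_cgs(P0_mmHg), rho = rho, nu = nu,
         delta_star = delta_star),
    class = "tube_law_params")
}

#' @export
print.tube_law_params <- function(x, ...) {
  cat("Tube-law parameters (CGS):\n")
  cat(sprintf("  k1 = %.4g, k2 = %.4g, k3 = %.4g g s^-2 cm^-1\n",
              x$k1, x$k2, x$k3))
  cat(sprintf("  P0 = %.2f mmHg, rho = %.3f g cm^-3, nu = %.3f cm^2 s^-1, delta* = %.4f cm\n",
              cgs_to_mmHg(x$P0), x$rho, x$nu, x$delta_star))
  invisible(x)
}

#' Wall stiffness Eh/r0 of a vessel
#'
#' `Eh/r0 = k1 * exp(k2 * r0) + k3`, strictly decreasing in `r0` when
#' `k1 > 0` and `k2 < 0`.
#'
#' @param r0 unstressed radius (cm), vectorised.
#' @param p a [tube_law_params()] object.
#' @return Eh/r0 in g s^-2 cm^-1.
#' @export
wall_stiffness <- function(r0, p) {
  if (any(r0 <= 0)) stop("unstressed radius r0 must be positive")
  p$k1 * exp(p$k2 * r0) + p$k3
}

# 4/3 * Eh/r0, the coefficient of the tube law; used throughout the solver.
tube_f <- function(r0, p) (4 / 3) * wall_stiffness(r0, p)

#' Pressure from cross-sectional area (tube law)
#'
#' `P = P0 + (4/3) (Eh/r0) (1 - sqrt(A0/A))` with `A0 = pi r0^2`.  Pressure
#' equals the external pressure `P0` exactly at the unstressed area.
#'
#' @param A cross-sectional area (cm^2), vectorised.
#' @param r0 unstressed radius (cm).
#' @param p a [tube_law_params()] object.
#' @return Pressure in dyn cm^-2 (CGS); use [cgs_to_mmHg()] for mmHg.
#' @export
pressure_from_area <- function(A, r0, p) {
  if (any(A <= 0)) stop("area must be positive")
  A0 <- pi * r0^2
  p$P0 + tube_f(r0, p) * (1 - sqrt(A0 / A))
}

#' Area from pressure (analytic tube-law inverse)
#'
#' The tube law has a pressure asymptote `P0 + (4/3) Eh/r0`; pressures at or
#' above it correspond to unbounded distension and are rejected.
#'
#' @param P pressure (dyn cm^-2), vectorised.
#' @inheritParams pressure_from_area
#' @return Area in cm^2.
#' @export
area_from_pressure <- function(P, r0, p) {
  f <- tube_f(r0, p)
  if (any(P - p$P0 >= f)) {
    stop(sprintf(
      "pressure at/above the tube-law asymptote P0 + 4/3*Eh/r0 = %.6g dyn cm^-2 (%.4g mmHg)",
      p$P0 + f, cgs_to_mmHg(p$P0 + f)))
  }
  A0 <- pi * r0^2
  A0 / (1 - (P - p$P0) / f)^2
}

#' Pulse-wave speed
#'
#' `c = sqrt((A/rho) dP/dA)` evaluated analytically for the tube law:
#' `c^2 = (2/(3 rho)) (Eh/r0) sqrt(A0/A)`.
#'
#' @inheritParams pressure_from_area
#' @return Wave speed in cm s^-1.
#' @export
wave_speed <- function(A, r0, p) {
  if (any(A <= 0)) stop("area must be positive")
  A0 <- pi * r0^2
  sqrt((2 / (3 * p$rho)) * wall_stiffness(r0, p) * sqrt(A0 / A))
}

#' Arterial network object
#'
#' Builds a validated large-artery network from a segment table.  The
#' connectivity must form a rooted tree in which every segment has 0, 1 or 2
#' daughters: 2 at a bifurcation, 1 at a series (anatomical continuation)
#' junction, 0 at a terminal vessel.  Terminal vessels must carry the root
#' radius of their vascular bed; non-terminals must not.
#'
#' @param segments a data frame with columns `id`, `name`, `length_cm`,
#'   `r_top_cm`, `r_bottom_cm`, `daughter_1`, `daughter_2`,
#'   `bed_root_radius_cm` (daughters and bed radius `NA` where absent).
#' @param tube_law a [tube_law_params()] object.
#' @return An object of class `arterial_network`: list with `segments`
#'   (tibble), `root_id`, `tube_law`.
#' @export
arterial_network <- function(segments, tube_law = tube_law_params()) {
  seg <- tibble::as_tibble(segments)
  req <- c("id", "name", "length_cm", "r_top_cm", "r_bottom_cm",
           "daughter_1", "daughter_2", "bed_root_radius_cm")
  missing_cols <- setdiff(req, names(seg))
  if (length(missing_cols)) {
    stop("segment table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(seg$id)) stop("segment ids must be unique")
  if (any(seg$length_cm <= 0)) stop("segment lengths must be positive")
  if (any(seg$r_top_cm <= 0) || any(seg$r_bottom_cm <= 0)) {
    stop("segment radii must be positive")
  }
  if (any(seg$r_bottom_cm > seg$r_top_cm + 1e-12)) {
    stop("r_bottom must not exceed r_top (taper is proximal to distal)")
  }
  # daughters referenced must exist; find the root
  kids <- c(seg$daughter_1, seg$daughter_2)
  kids <- kids[!is.na(kids)]
  if (anyDuplicated(kids)) stop("a segment has more than one parent")
  if (!all(kids %in% seg$id)) stop("daughter ids reference unknown segments")
  root <- setdiff(seg$id, kids)
  if (length(root) != 1) {
    stop("network must have exactly one root segment, found ", length(root))
  }
  # 2-daughter rows must have both or one slot filled consistently
  terminal <- is.na(seg$daughter_1) & is.na(seg$daughter_2)
  only_d2 <- is.na(seg$daughter_1) & !is.na(seg$daughter_2)
  if (any(only_d2)) stop("daughter_1 must be filled before daughter_2")
  has_bed <- !is.na(seg$bed_root_radius_cm)
  if (!all(terminal == has_bed)) {
    stop("terminal segments (and only those) must carry bed_root_radius_cm")
  }
  if (any(seg$bed_root_radius_cm[has_bed] <= 0)) {
    stop("bed root radii must be positive")
  }
  # connectivity: every segment reachable from the root
  reach <- new.env(); n_seen <- 0L
  stack <- root
  while (length(stack)) {
    s <- stack[[1]]; stack <- stack[-1]
    key <- as.character(s)
    if (!is.null(reach[[key]])) stop("cycle detected in network topology")
    reach[[key]] <- TRUE; n_seen <- n_seen + 1L
    row <- seg[seg$id == s, ]
    stack <- c(stack, row$daughter_1[!is.na(row$daughter_1)],
               row$daughter_2[!is.na(row$daughter_2)])
  }
  if (n_seen != nrow(seg)) stop("network is not connected: unreachable segments")
  structure(list(segments = seg, root_id = root, tube_law = tube_law),
            class = "arterial_network")
}

#' @export
print.arterial_network <- function(x, ...) {
  nt <- sum(is.na(x$segments$daughter_1) & is.na(x$segments$daughter_2))
  cat(sprintf("Arterial network: %d segments (%d terminal), root = %s\n",
              nrow(x$segments), nt,
              x$segments$name[x$segments$id == x$root_id]))
  invisible(x)
}

#' Terminal segment ids of a network
#' @param net an [arterial_network()].
#' @return Integer vector of terminal segment ids.
#' @export
terminal_ids <- function(net) {
  seg <- net$segments
  seg$id[is.na(seg$daughter_1) & is.na(seg$daughter_2)]
}

#' Unstressed-radius taper along a segment
#'
#' The unstressed radius follows an exponential taper
#' `r0(x) = r_top * (r_bottom/r_top)^(x/L)`, which keeps `Eh/r0` smooth and
#' matches the structured-tree systemic-artery literature.
#'
#' @param seg one row of a network segment table (list or 1-row data frame).
#' @param x positions along the segment, 0 (proximal) to `length_cm`.
#' @return Unstressed radii (cm), monotone from `r_top` to `r_bottom`.
#' @export
taper_radius <- function(seg, x) {
  L <- seg$length_cm
  if (any(x < -1e-12 | x > L + 1e-12)) stop("x outside segment")
  seg$r_top_cm * (seg$r_bottom_cm / seg$r_top_cm)^(x / L)
}

#' Read / write a network segment table
#'
#' CSV (or JSON) with the column layout documented in [arterial_network()].
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param tube_law a [tube_law_params()] for the resulting network.
#' @return [read_network()] returns an `arterial_network`;
#'   [write_network()] returns `path` invisibly.
#' @export
read_network <- function(path, tube_law = tube_law_params()) {
  ext <- tolower(tools::file_ext(path))
  seg <- if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  arterial_network(seg, tube_law)
}

#' @rdname read_network
#' @param net an `arterial_network` to serialise.
#' @export
write_network <- function(net, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(net$segments, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(net$segments, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' The default 24-artery systemic network
#'
#' The segment table shipped with the package: aorta, head/arm vessels,
#' coeliac group and leg vessels (24 segments, 12 terminal vascular beds),
#' with lengths, radii and bed root radii taken from the standard
#' structured-tree systemic-artery literature.  It is a synthetic transcription
#' assembled from published values, not a measured dataset.
#'
#' @param tube_law a [tube_law_params()] object.
#' @return An `arterial_network` with 24 segments.
#' @examples
#' net <- default_network()
#' length(terminal_ids(net))  # 12 vascular beds
#' @export
default_network <- function(tube_law = tube_law_params()) {
  path <- system.file("extdata", "network_24.csv", package = "lvsa",
                      mustWork = TRUE)
  read_network(path, tube_law)
}
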