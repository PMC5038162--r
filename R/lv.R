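# Reduced-order left ventricle: thick-walled incompressible spherical shell,
# Holzapfel-Ogden passive myocardium, phenomenological active-tension twitch.

#' Holzapfel-Ogden passive material parameters
#'
#' Constants of the Holzapfel-Ogden strain-energy function for passive
#' myocardium (`a`-type constants in kPa, `b`-type dimensionless).  In the
#' reduced equibiaxial shell kinematics used here the fibre and sheet
#' families lie in the wall tangent plane and the `afs` shear term carries no
#' stress (the fibre/sheet shear invariant vanishes); `afs` is retained so
#' stiffness scaling acts on the full `a`-type set.  Defaults are the
#' original human-myocardium fit; `passive_scale` is the calibration
#' multiplier (matched to an end-diastolic volume at 8 mmHg) and
#' `stiffness_scale` the scenario multiplier, both applied to all `a`-type
#' constants.
#'
#' @param a,b isotropic matrix constants.
#' @param af,bf fibre-family constants.
#' @param as_,bs sheet-family constants.
#' @param afs,bfs fibre-sheet shear constants (no stress in this kinematics).
#' @param passive_scale calibration multiplier on a-type constants.
#' @param stiffness_scale scenario multiplier on a-type constants.
#' @return Object of class `ho_params`.
#' @export
ho_params <- function(a = 0.059, b = 8.023, af = 18.472, bf = 16.026,
                      as_ = 2.481, bs = 11.120, afs = 0.216, bfs = 11.436,
                      passive_scale = 1, stiffness_scale = 1) {
  vals <- c(a, b, af, bf, as_, bs, afs, bfs)
  if (any(vals < 0)) stop("Holzapfel-Ogden constants must be non-negative")
  if (passive_scale <= 0 || stiffness_scale <= 0) stop("scales must be positive")
  structure(list(a = a, b = b, af = af, bf = bf, as_ = as_, bs = bs,
                 afs = afs, bfs = bfs, passive_scale = passive_scale,
                 stiffness_scale = stiffness_scale),
            class = "ho_params")
}

#' Active-tension (twitch) parameters
#'
#' The full myofilament kinetics are replaced by a normalised
#' phenomenological twitch: a product of rising and falling exponential
#' saturations, zero before `t_onset`, peak normalised to one, smoothly
#' tapered to zero at `t_onset + twitch_duration`.  Peak active tension is
#' `T0` times an optional linear length-dependence factor
#' `max(0, 1 + beta_length (lambda - 1))` (a Frank-Starling surrogate).
#'
#' @param T0 contractility scale (kPa).
#' @param t_onset activation onset within the cycle (s).
#' @param tau_rise,tau_fall rise/decay time constants (s).
#' @param twitch_duration total twitch support (s); must fit in the cycle.
#' @param beta_length length-dependence slope (dimensionless).
#' @return Object of class `activation_params`.
#' @export
activation_params <- function(T0 = 29, t_onset = 0, tau_rise = 0.139,
                              tau_fall = 0.26, twitch_duration = 0.88,
                              beta_length = 4.9) {
  if (T0 < 0) stop("T0 must be >= 0")
  if (tau_rise <= 0 || tau_fall <= 0 || twitch_duration <= 0) {
    stop("time constants must be positive")
  }
  structure(list(T0 = T0, t_onset = t_onset, tau_rise = tau_rise,
                 tau_fall = tau_fall, twitch_duration = twitch_duration,
                 beta_length = beta_length),
            class = "activation_params")
}

# normalised twitch: 0 outside [t_onset, t_onset + duration], peak exactly 1
twitch <- function(t, p) {
  s <- t - p$t_onset
  out <- numeric(length(s))
  inside <- s > 0 & s < p$twitch_duration
  if (any(inside)) {
    si <- s[inside]
    base <- (1 - exp(-si / p$tau_rise)) * exp(-si / p$tau_fall)
    s_pk <- p$tau_rise * log(1 + p$tau_fall / p$tau_rise)
    norm <- (1 - exp(-s_pk / p$tau_rise)) * exp(-s_pk / p$tau_fall)
    # cosine taper over the last 15% so the twitch ends at exactly zero
    t0 <- 0.85 * p$twitch_duration
    w <- ifelse(si <= t0, 1,
                0.5 * (1 + cos(pi * (si - t0) / (0.15 * p$twitch_duration))))
    out[inside] <- base / norm * w
  }
  out
}

#' Active tension
#'
#' `T0 * twitch(t) * max(0, 1 + beta_length (lam - 1))` in kPa, with `lam`
#' the mid-wall circumferential stretch.
#'
#' @param t time within the cycle (s), vectorised.
#' @param lam mid-wall circumferential stretch (1 = unloaded).
#' @param p an [activation_params()] object.
#' @return Active tension (kPa).
#' @export
activation <- function(t, lam = 1, p = activation_params()) {
  p$T0 * twitch(t, p) * pmax(0, 1 + p$beta_length * (lam - 1))
}

#' Passive in-plane minus radial Cauchy stress difference
#'
#' Holzapfel-Ogden stress for the incompressible equibiaxial shell state
#' (`lambda_theta = lambda_phi = lam`, `lambda_r = lam^-2`) with the fibre
#' and sheet families uniformly distributed in the tangent plane:
#' `I1 = 2 lam^2 + lam^-4`, in-plane `I4 = lam^2`, fibre terms active in
#' extension only.  Returns `sigma_thetatheta - sigma_rr` in kPa; zero at
#' `lam = 1` and linear in the a-type constants (so stiffness scaling scales
#' stress exactly).
#'
#' @param lam in-plane stretch (> 0), vectorised.
#' @param p an [ho_params()] object.
#' @return Stress difference (kPa).
#' @export
ho_passive_stress <- function(lam, p = ho_params()) {
  if (any(lam <= 0)) stop("stretch must be positive")
  sc <- p$passive_scale * p$stiffness_scale
  l2 <- lam^2
  I1 <- 2 * l2 + lam^-4
  iso <- p$a * exp(p$b * (I1 - 3)) * (l2 - lam^-4)
  e4 <- l2 - 1                      # I4 - 1 for in-plane fibres
  ext <- pmax(e4, 0)                # tension-only fibre response
  fib <- (p$af * ext * exp(p$bf * ext^2) +
            p$as_ * ext * exp(p$bs * ext^2)) * l2
  sc * (iso + fib)
}

#' Chamber geometry of the reduced ventricle
#'
#' Unloaded thick-walled spherical shell.  Defaults give an unloaded cavity
#' of about 100 mL and a wall volume of about 140 mL, so that filling to a
#' normal end-diastolic volume at 8 mmHg produces fibre stretches around
#' 1.1--1.15, the strain range the Holzapfel-Ogden exponentials are
#' calibrated for; calibration, not the defaults, carries the accuracy
#' burden.
#'
#' @param Ri unloaded inner radius (cm).
#' @param Ro unloaded outer radius (cm).
#' @return Object of class `chamber_geometry` with derived `V_cavity` and
#'   `V_wall` (mL).
#' @export
chamber_geometry <- function(Ri = 2.88, Ro = 3.86) {
  if (Ri <= 0 || Ro <= Ri) stop("need 0 < Ri < Ro")
  gl <- pracma::gaussLegendre(64, Ri, Ro)
  structure(list(Ri = Ri, Ro = Ro,
                 V_cavity = 4 * pi / 3 * Ri^3,
                 V_wall = 4 * pi / 3 * (Ro^3 - Ri^3),
                 quad = list(R = gl$x, w = gl$w)),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("LV shell: Ri = %.3f cm, Ro = %.3f cm, cavity %.1f mL, wall %.1f mL\n",
              x$Ri, x$Ro, x$V_cavity, x$V_wall))
  invisible(x)
}

# Gauss-Legendre rule cached in the geometry object (64 points on [Ri, Ro])
shell_quadrature <- function(geom) {
  if (!is.null(geom$quad)) return(geom$quad)
  gl <- pracma::gaussLegendre(64, geom$Ri, geom$Ro)
  list(R = gl$x, w = gl$w)
}

#' Cavity pressure of the contracting shell
#'
#' Incompressibility maps every reference shell radius `R` to a deformed
#' radius `(ri^3 + R^3 - Ri^3)^(1/3)` with `ri = (3V/4pi)^(1/3)`; the cavity
#' pressure is the thick-shell equilibrium integral
#' `P = int_ri^ro 2 (sigma_theta - sigma_r) / r dr`, with the passive
#' stress difference integrated by 64-point Gauss-Legendre quadrature and
#' the active tension (evaluated at the mid-wall stretch) contributing
#' `2 T_act ln(ro/ri)` in closed form.
#'
#' @param V cavity volume (mL).
#' @param t time within the cycle (s); ignored when `actp` is `NULL`.
#' @param geom a [chamber_geometry()].
#' @param hop an [ho_params()].
#' @param actp an [activation_params()], or `NULL` for the passive chamber.
#' @return Cavity pressure in mmHg (transmural, i.e. relative to the
#'   pericardial/thoracic reference).
#' @export
cavity_pressure <- function(V, t = 0, geom = chamber_geometry(),
                            hop = ho_params(), actp = NULL) {
  if (any(V <= 0)) stop("cavity volume must be positive")
  quad <- shell_quadrature(geom)
  one <- function(v, tt) {
    ri3 <- 3 * v / (4 * pi)
    shift <- ri3 - geom$Ri^3
    r <- (quad$R^3 + shift)^(1 / 3)
    lam <- r / quad$R
    # integral over deformed radius, transformed to reference radius:
    # dr = R^2 / r^2 dR  ->  integrand 2 sigma / r * R^2 / r^2
    passive <- sum(quad$w * 2 * ho_passive_stress(lam, hop) * quad$R^2 / r^3)
    act <- 0
    if (!is.null(actp)) {
      ri <- ri3^(1 / 3)
      ro <- (geom$Ro^3 + shift)^(1 / 3)
      R_mid <- 0.5 * (geom$Ri + geom$Ro)
      lam_mid <- (R_mid^3 + shift)^(1 / 3) / R_mid
      act <- 2 * activation(tt, lam_mid, actp) * log(ro / ri)
    }
    kPa_to_mmHg(passive + act)
  }
  if (length(t) == 1) t <- rep(t, length(V))
  vapply(seq_along(V), function(i) one(V[i], t[i]), numeric(1))
}

#' Passive inflation volume at a target pressure
#'
#' Root-finds the cavity volume at which the passive chamber pressure equals
#' `P_target` (mmHg).  The passive pressure-volume curve is zero at the
#' unloaded cavity volume and strictly increasing, so the root is unique.
#'
#' @param P_target target pressure (mmHg, >= 0).
#' @param geom a [chamber_geometry()].
#' @param hop an [ho_params()].
#' @param tol relative tolerance on the volume.
#' @return Cavity volume (mL).
#' @export
passive_inflate <- function(P_target, geom = chamber_geometry(),
                            hop = ho_params(), tol = 1e-10) {
  if (P_target < 0) stop("P_target must be >= 0")
  V0 <- geom$V_cavity
  if (P_target == 0) return(V0)
  hi <- 2 * V0
  for (k in 1:60) {
    if (cavity_pressure(hi, geom = geom, hop = hop) >= P_target) break
    hi <- hi * 1.5
    if (k == 60) stop(sprintf(
      "cannot bracket %.3g mmHg: passive pressure reaches only %.3g mmHg at V = %.3g mL",
      P_target, cavity_pressure(hi, geom = geom, hop = hop), hi))
  }
  stats::uniroot(function(v) cavity_pressure(v, geom = geom, hop = hop) - P_target,
                 interval = c(V0, hi), tol = tol * V0)$root
}

#' Bundle the reduced ventricle
#'
#' @param geom a [chamber_geometry()].
#' @param hop an [ho_params()].
#' @param actp an [activation_params()].
#' @param edp end-diastolic pressure (mmHg), fixed across scenarios.
#' @return Object of class `reduced_lv` (also carries the end-diastolic
#'   volume implied by `edp`).
#' @export
reduced_lv <- function(geom = chamber_geometry(), hop = ho_params(),
                       actp = activation_params(), edp = 8) {
  structure(list(geom = geom, hop = hop, actp = actp, edp = edp,
                 EDV = passive_inflate(edp, geom, hop)),
            class = "reduced_lv")
}

#' @export
print.reduced_lv <- function(x, ...) {
  cat(sprintf("Reduced LV: EDV %.1f mL at EDP %.1f mmHg, T0 = %.1f kPa, passive scale %.3g\n",
              x$EDV, x$edp, x$actp$T0, x$hop$passive_scale))
  invisible(x)
}
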