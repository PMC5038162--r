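# Structured-tree vascular beds: generation, vessel counts, root impedance.

#' Structured-tree parameters
#'
#' An asymmetric structured tree bifurcates each parent of radius `r` into
#' daughters `alpha*r` and `beta*r` until the radius falls below `r_min`.
#' The scaling factors follow from the radius exponent `xi`
#' (`r_p^xi = r_d1^xi + r_d2^xi`) and the daughter-radius ratio squared
#' `gamma = (r_d1/r_d2)^2` with `r_d1` the larger daughter, so `gamma >= 1`
#' internally.  Configurations may supply the literature's asymmetry ratio
#' (< 1, e.g. 0.41); it is normalised by reciprocal.
#'
#' @param xi radius exponent, physiological range 2.33--3 (warns outside).
#' @param gamma daughter-radius ratio squared; values < 1 are interpreted as
#'   the asymmetry-ratio convention and inverted.  Default 1/0.41.
#' @param r_min termination radius in cm (default 0.01 cm = 100 um).
#' @param lr_ratio small-vessel length-to-radius ratio (default 50).
#' @param leaf_impedance terminal impedance attached beyond the leaves
#'   (CGS, default 0).
#' @return An object of class `tree_params`.
#' @export
tree_params <- function(xi = 2.76, gamma = 1 / 0.41, r_min = 0.01,
                        lr_ratio = 50, leaf_impedance = 0) {
  if (xi <= 0) stop("xi must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (gamma < 1) gamma <- 1 / gamma
  if (xi < 2.33 || xi > 3) {
    warning(sprintf("radius exponent xi = %.3g outside the physiological range [2.33, 3]", xi))
  }
  if (r_min <= 0) stop("r_min must be positive")
  if (lr_ratio <= 0) stop("lr_ratio must be positive")
  structure(list(xi = xi, gamma = gamma, r_min = r_min,
                 lr_ratio = lr_ratio, leaf_impedance = leaf_impedance),
            class = "tree_params")
}

#' Daughter-radius scaling factors of a structured tree
#'
#' With `gamma = (r_d1/r_d2)^2`, the radius exponent relation gives
#' `alpha = (1 + gamma^(-xi/2))^(-1/xi)` and `beta = alpha/sqrt(gamma)`; the
#' pair satisfies `alpha^xi + beta^xi = 1` exactly and `0 < beta <= alpha < 1`.
#'
#' @param xi radius exponent (> 0).
#' @param gamma daughter-radius ratio squared (>= 1; values < 1 are inverted
#'   as in [tree_params()]).
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @examples
#' alpha_beta(3, 1)  # symmetric: both 2^(-1/3)
#' @export
alpha_beta <- function(xi, gamma) {
  if (xi <= 0 || gamma <= 0) stop("xi and gamma must be positive")
  if (gamma < 1) gamma <- 1 / gamma
  a <- (1 + gamma^(-xi / 2))^(-1 / xi)
  c(alpha = a, beta = a / sqrt(gamma))
}

# area ratio eta = (1+gamma)/(1+gamma^(xi/2))^(2/xi); exposed for checks
area_ratio <- function(xi, gamma) {
  if (gamma < 1) gamma <- 1 / gamma
  (1 + gamma) / (1 + gamma^(xi / 2))^(2 / xi)
}

#' Build an explicit structured tree
#'
#' Materialises the vessel records of one vascular bed.  A vessel whose
#' radius is at least `r_min` bifurcates; one below `r_min` is a leaf.
#' Vessel lengths are `lr_ratio * radius`.  Intended for small trees
#' (tests, inspection); vessel counting and impedance use memoised
#' recursions that do not materialise records.
#'
#' @param root_radius radius (cm) of the bed's root vessel.
#' @param p a [tree_params()] object.
#' @param max_vessels safety cap on the number of materialised records.
#' @return Object of class `structured_tree_bed`: list with `root_radius`,
#'   `vessels` (tibble: id, parent, depth, radius, length, is_leaf),
#'   `vessel_count`, `leaf_count`, `params`.
#' @export
build_tree <- function(root_radius, p = tree_params(), max_vessels = 2e6) {
  if (root_radius <= 0) stop("root_radius must be positive")
  ab <- alpha_beta(p$xi, p$gamma)
  if (ab["alpha"] >= 1) stop("tree parameters give alpha >= 1: tree would not terminate")
  n_est <- count_tree_vessels(root_radius, p)
  if (n_est > max_vessels) {
    stop(sprintf("tree has %d vessels, above max_vessels = %d; use count_tree_vessels()/root_impedance() which do not materialise records",
                 n_est, max_vessels))
  }
  id <- integer(n_est); parent <- integer(n_est); depth <- integer(n_est)
  radius <- numeric(n_est); leaf <- logical(n_est)
  # iterative preorder traversal
  k <- 0L
  stack_r <- root_radius; stack_p <- 0L; stack_d <- 0L
  while (length(stack_r)) {
    r <- stack_r[[1]]; pa <- stack_p[[1]]; de <- stack_d[[1]]
    stack_r <- stack_r[-1]; stack_p <- stack_p[-1]; stack_d <- stack_d[-1]
    k <- k + 1L
    id[k] <- k; parent[k] <- pa; depth[k] <- de; radius[k] <- r
    if (r >= p$r_min) {
      stack_r <- c(ab[["alpha"]] * r, ab[["beta"]] * r, stack_r)
      stack_p <- c(k, k, stack_p)
      stack_d <- c(de + 1L, de + 1L, stack_d)
    } else {
      leaf[k] <- TRUE
    }
  }
  vessels <- tibble::tibble(id = id, parent = parent, depth = depth,
                            radius = radius, length = p$lr_ratio * radius,
                            is_leaf = leaf)
  structure(list(root_radius = root_radius, vessels = vessels,
                 vessel_count = k, leaf_count = sum(leaf), params = p),
            class = "structured_tree_bed")
}

#' @export
print.structured_tree_bed <- function(x, ...) {
  cat(sprintf("Structured-tree bed: root %.4g cm, %d vessels (%d leaves), xi = %.3g\n",
              x$root_radius, x$vessel_count, x$leaf_count, x$params$xi))
  invisible(x)
}

#' Count vessels in one structured tree
#'
#' Memoised recursion over distinct radii (radii repeat because each vessel's
#' radius is `alpha^i * beta^j * root`), so beds with hundreds of thousands
#' of vessels count in milliseconds.
#'
#' @inheritParams build_tree
#' @return Integer-valued count (double, exact for counts below 2^53).
#' @export
count_tree_vessels <- function(root_radius, p = tree_params()) {
  if (root_radius <= 0) stop("root_radius must be positive")
  ab <- alpha_beta(p$xi, p$gamma)
  al <- ab[["alpha"]]; be <- ab[["beta"]]
  # count over the (i, j) lattice of alpha/beta applications, bottom-up by
  # radius; memo via environment keyed on (i, j)
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    r <- root_radius * al^i * be^j
    v <- if (r < p$r_min) 1 else 1 + Recall(i + 1L, j) + Recall(i, j + 1L)
    memo[[key]] <- v
    v
  }
  cnt(0L, 0L)
}

#' @rdname count_tree_vessels
#' @details `count_tree_leaves()` counts only the terminal (leaf) vessels.
#' @export
count_tree_leaves <- function(root_radius, p = tree_params()) {
  if (root_radius <= 0) stop("root_radius must be positive")
  ab <- alpha_beta(p$xi, p$gamma)
  al <- ab[["alpha"]]; be <- ab[["beta"]]
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    r <- root_radius * al^i * be^j
    v <- if (r < p$r_min) 1 else Recall(i + 1L, j) + Recall(i, j + 1L)
    memo[[key]] <- v
    v
  }
  cnt(0L, 0L)
}

#' Total small-vessel count of a network's vascular beds
#'
#' Sums [count_tree_vessels()] over every terminal segment's bed.  Lowering
#' the radius exponent (rarefaction) reduces this count in every bed.
#'
#' @param net an [arterial_network()] whose terminal segments carry bed
#'   root radii.
#' @param p a [tree_params()] object.
#' @return Total number of small vessels across all beds.
#' @examples
#' net <- default_network()
#' n_base <- count_network_vessels(net, tree_params(xi = 2.76))
#' n_rare <- count_network_vessels(net, tree_params(xi = 2.4))
#' 100 * (1 - n_rare / n_base)  # percent reduction under rarefaction
#' @export
count_network_vessels <- function(net, p = tree_params()) {
  term <- net$segments[is.na(net$segments$daughter_1) &
                         is.na(net$segments$daughter_2), ]
  if (any(is.na(term$bed_root_radius_cm))) {
    stop("terminal segment(s) without bed_root_radius_cm: ",
         paste(term$name[is.na(term$bed_root_radius_cm)], collapse = ", "))
  }
  sum(vapply(term$bed_root_radius_cm, count_tree_vessels, numeric(1), p = p))
}

#' DC (Poiseuille) resistance of a structured tree
#'
#' Series/parallel combination of per-vessel Poiseuille resistances
#' `8 mu l / (pi r^4)` from the leaves (terminal impedance
#' `leaf_impedance`) to the root.  This equals the zero-frequency limit of
#' [root_impedance()].
#'
#' @inheritParams build_tree
#' @param mu dynamic viscosity (g cm^-1 s^-1).
#' @return Resistance in dyn s cm^-5.
#' @export
tree_dc_resistance <- function(root_radius, p = tree_params(),
                               mu = 1.055 * 0.046) {
  ab <- alpha_beta(p$xi, p$gamma)
  al <- ab[["alpha"]]; be <- ab[["beta"]]
  memo <- new.env(parent = emptyenv())
  res <- function(i, j) {
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    r <- root_radius * al^i * be^j
    own <- 8 * mu * (p$lr_ratio * r) / (pi * r^4)
    v <- if (r < p$r_min) {
      own + p$leaf_impedance
    } else {
      z1 <- Recall(i + 1L, j); z2 <- Recall(i, j + 1L)
      own + 1 / (1 / z1 + 1 / z2)
    }
    memo[[key]] <- v
    v
  }
  res(0L, 0L)
}

#' Root impedance spectrum and periodic impulse response of a vascular bed
#'
#' Input impedance of the structured tree at the bed root, computed from the
#' linearised (Womersley) oscillatory flow solution in each small vessel and
#' combined recursively from the leaves (terminal impedance
#' `p$leaf_impedance`) to the root.  Each vessel acts as a lossy transmission
#' line with complex wave speed `c = sqrt(A0 (1 - F10) / (rho C))` and
#' admittance-like factor `g = sqrt(C A0 (1 - F10) / rho)`, where `F10` is
#' the Womersley friction function and `C = 3 A0 r0 / (2 Eh)` the linearised
#' tube-law compliance per unit length.  At zero frequency the impedance
#' equals the Poiseuille series/parallel resistance.  The periodic impulse
#' response `z(t)` is the inverse DFT of the Hermitian-extended spectrum,
#' scaled so that the terminal boundary condition is the periodic convolution
#' `P(t) - P0 = sum_k z(k dt) Q(t - k dt) dt`.
#'
#' @param root_radius bed root radius (cm).
#' @param p a [tree_params()] object.
#' @param tube_law a [tube_law_params()]; supplies density, viscosity and the
#'   small-vessel stiffness law.
#' @param t_period cardiac period (s).
#' @param n_freq number of time samples per period `N` (power of two).
#' @return Object of class `impedance_spectrum`: list with `omega`
#'   (0..N/2 angular frequencies), `Z` (complex impedances, CGS),
#'   `z_time` (real impulse response, length N), `dt`, `R_dc`, `root_radius`.
#' @export
root_impedance <- function(root_radius, p = tree_params(),
                           tube_law = tube_law_params(),
                           t_period = 0.9, n_freq = 8192) {
  if (root_radius <= 0) stop("root_radius must be positive")
  if (n_freq < 4 || bitwAnd(n_freq, n_freq - 1L) != 0) {
    stop("n_freq must be a power of two")
  }
  ab <- alpha_beta(p$xi, p$gamma)
  al <- ab[["alpha"]]; be <- ab[["beta"]]
  nu <- tube_law$nu; rho <- tube_law$rho; mu <- rho * nu
  kh <- n_freq / 2
  omega <- 2 * pi * (1:kh) / t_period   # omega = 0 handled separately

  memo <- new.env(parent = emptyenv())
  z_in <- function(i, j) {
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    r <- root_radius * al^i * be^j
    if (r < p$r_min) {
      zl <- list(z0 = p$leaf_impedance,
                 z = rep(p$leaf_impedance + 0i, kh))
    } else {
      za <- Recall(i + 1L, j); zb <- Recall(i, j + 1L)
      zl <- list(z0 = 1 / (1 / za$z0 + 1 / zb$z0),
                 z = 1 / (1 / za$z + 1 / zb$z))
    }
    L <- p$lr_ratio * r
    A0 <- pi * r^2
    Eh_r0 <- wall_stiffness(r, tube_law)
    comp <- 3 * A0 / (2 * Eh_r0)            # dA/dP per unit length
    # Womersley friction function over all frequencies
    w <- r * sqrt(omega / nu)
    F10 <- womersley_f10(w)
    cw <- sqrt(A0 * (1 - F10) / (rho * comp))
    g <- comp * cw
    kl <- omega * L / cw
    zlw <- zl$z
    num <- (1i / g) * sin(kl) + zlw * cos(kl)
    den <- cos(kl) + 1i * g * zlw * sin(kl)
    zv <- num / den
    z0 <- 8 * mu * L / (pi * r^4) + zl$z0
    if (any(!is.finite(Re(zv))) || any(!is.finite(Im(zv)))) {
      stop(sprintf("non-finite impedance in vessel at lattice (%d, %d), radius %.4g cm", i, j, r))
    }
    v <- list(z0 = z0, z = zv)
    memo[[key]] <- v
    v
  }
  zr <- z_in(0L, 0L)
  # Hermitian extension -> real impulse response
  Zhalf <- c(zr$z0 + 0i, zr$z)                 # k = 0..N/2
  # Hermitian extension; the Nyquist bin must be real for a real response
  Zfull <- c(Zhalf[1:kh], Re(Zhalf[kh + 1]) + 0i, Conj(rev(zr$z[-kh])))
  dt <- t_period / n_freq
  zt_c <- stats::fft(Zfull, inverse = TRUE) / n_freq
  rel_im <- max(abs(Im(zt_c))) / max(abs(zt_c))
  if (rel_im > 1e-8) {
    warning(sprintf("impulse response has relative imaginary part %.2g", rel_im))
  }
  z_time <- Re(zt_c) / dt
  structure(list(omega = c(0, omega), Z = Zhalf, z_time = z_time, dt = dt,
                 R_dc = zr$z0, root_radius = root_radius,
                 t_period = t_period, n = n_freq),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: root %.4g cm, N = %d, R_dc = %.4g dyn s cm^-5 (%.3g mmHg s/mL)\n",
              x$root_radius, x$n, x$R_dc, x$R_dc / MMHG_DYN))
  invisible(x)
}

#' Serialise a bed or an impedance spectrum for inspection
#'
#' @param bed a `structured_tree_bed` from [build_tree()].
#' @param path output path (JSON for beds, CSV for spectra).
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  jsonlite::write_json(
    list(root_radius = bed$root_radius,
         params = unclass(bed$params),
         vessels = bed$vessels),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bed
#' @param spec an `impedance_spectrum` from [root_impedance()].
#' @export
write_impedance <- function(spec, path) {
  utils::write.csv(
    data.frame(freq_Hz = spec$omega / (2 * pi),
               Re_Z = Re(spec$Z), Im_Z = Im(spec$Z)),
    path, row.names = FALSE)
  invisible(path)
}
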