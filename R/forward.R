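# Frequency-domain diffusion forward models.
#
# Conventions (documented, and used consistently by every solver and fit):
#   * D = 1 / (3 (mua + musp))            (mua-inclusive diffusion coefficient)
#   * time dependence exp(-i omega t); complex wavenumber
#     k = sqrt((mua + i omega / c_m) / D) with Re k > 0, so |Phi| decays and
#     the phase lag  -Arg(Phi)  increases with separation.
#   * extrapolated boundary at z = -zb, zb = 2 D (1 + Reff) / (1 - Reff),
#     Reff from the standard polynomial fit to the Fresnel reflection
#     integrals; isotropic point source at depth z0 = 1 / (mua + musp).

.C0 <- 2.99792458e10  # vacuum speed of light, cm/s

#' Default angular modulation frequency
#'
#' @param freq_hz modulation frequency in Hz (default 140 MHz).
#' @return omega in rad/s.
#' @export
default_omega <- function(freq_hz = 140e6) 2 * pi * freq_hz

# Effective internal reflection coefficient for a refractive-index mismatch
# n_in / n_out (polynomial fit to the Fresnel integrals).
reff_fresnel <- function(n_rel) {
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

diffusion_coefficient <- function(props) 1 / (3 * (props$mua + props$musp))

#' Semi-infinite homogeneous fluence (closed form)
#'
#' Extrapolated-boundary image-source solution of the frequency-domain
#' diffusion equation for a unit point source on a homogeneous semi-infinite
#' medium, evaluated on the surface at source-detector separation \code{rho}.
#' |Phi| decreases and the phase lag -Arg(Phi) increases strictly with rho.
#'
#' @param props \code{optical_props} of the medium.
#' @param rho source-detector separation(s), cm; must exceed one transport
#'   mean free path 1/(mua + musp).
#' @param omega angular modulation frequency, rad/s.
#' @param n_index refractive index of the medium.
#' @return complex fluence, same length as \code{rho}.
#' @examples
#' Mod(fluence_semi_infinite(optical_props(0.05, 7), c(4, 5)))
#' @export
fluence_semi_infinite <- function(props, rho, omega = default_omega(),
                                  n_index = 1.4) {
  stopifnot(inherits(props, "optical_props"))
  mut <- props$mua + props$musp
  if (any(rho < 1 / mut))
    stop("rho below one transport mean free path: diffusion solution invalid")
  cm <- .C0 / n_index
  D <- diffusion_coefficient(props)
  k <- sqrt((props$mua + 1i * omega / cm) / D)
  z0 <- 1 / mut
  zb <- 2 * D * (1 + reff_fresnel(n_index)) / (1 - reff_fresnel(n_index))
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (exp(-k * r1) / r1 - exp(-k * r2) / r2) / (4 * pi * D)
}

# Gauss-Legendre nodes/weights and Bessel kernel for the two-layer Hankel
# integral, cached per (separations, n_nodes, s_max) since they are
# independent of the optical properties.
.hankel_cache <- new.env(parent = emptyenv())

hankel_kernel <- function(rho, n_nodes = 512, s_max = 40) {
  key <- paste0(n_nodes, ":", s_max, ":",
                paste(signif(rho, 12), collapse = ","))
  hit <- .hankel_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- pracma::gaussLegendre(n_nodes, 0, s_max)
  J <- matrix(besselJ(as.vector(outer(gl$x, rho)), 0),
              nrow = n_nodes, ncol = length(rho))
  out <- list(s = gl$x, wJs = J * (gl$w * gl$x))
  .hankel_cache[[key]] <- out
  out
}

# Two-layer fluence at the surface for per-pair separations rho and per-pair
# interface depths l (cm): semi-infinite term for the top-layer properties
# plus the interface correction, obtained by matching the 1D Hankel-space
# solutions at z = l.  All exponentials are written in decaying form, so the
# integrand is overflow-free for any s.
two_layer_fluence_pairs <- function(rho, l, tissue, chest, omega, n_index,
                                    kernel = NULL) {
  mut1 <- tissue$mua + tissue$musp
  z0 <- 1 / mut1
  if (any(l <= z0))
    stop("interface depth must exceed the source depth z0")
  cm <- .C0 / n_index
  D1 <- diffusion_coefficient(tissue)
  D2 <- diffusion_coefficient(chest)
  reff <- reff_fresnel(n_index)
  zb <- 2 * D1 * (1 + reff) / (1 - reff)
  w1 <- (tissue$mua + 1i * omega / cm) / D1
  w2 <- (chest$mua + 1i * omega / cm) / D2
  if (is.null(kernel)) kernel <- hankel_kernel(rho)
  s <- kernel$s
  a1 <- sqrt(s^2 + w1)           # Re > 0
  a2 <- sqrt(s^2 + w2)
  d1a1 <- D1 * a1
  d2a2 <- D2 * a2
  # s-only factor of the interface correction
  f_s <- (1 - exp(-2 * a1 * (z0 + zb))) * (1 - exp(-2 * a1 * zb)) *
    (d1a1 - d2a2) / (2 * d1a1)
  # depth-dependent factors (n_nodes x n_pairs)
  E <- exp(-outer(a1, 2 * l - z0))
  E2u <- exp(-2 * outer(a1, l + zb))
  Q <- sweep(1 + E2u, 1, d1a1, `*`) + sweep(1 - E2u, 1, d2a2, `*`)
  corr_hat <- sweep(E / Q, 1, f_s, `*`)
  phi_corr <- colSums(kernel$wJs * corr_hat) / (2 * pi)
  phi0 <- fluence_semi_infinite(tissue, rho, omega, n_index)
  phi0 + phi_corr
}

#' Two-layer forward model
#'
#' Frequency-domain fluence for a breast-tissue layer over a semi-infinite
#' chest-wall layer, for all 126 probe pairs.  The default analytic method
#' evaluates the flat-interface two-layer Green's function (Hankel transform
#' over the lateral spatial frequency) at each pair's local interface depth
#' beneath the source-detector midpoint, which carries the tilt to first
#' order; \code{method = "fd"} voxelizes the tilted medium and runs the 3D
#' finite-difference solver.  With identical layers the analytic method
#' reduces exactly to the homogeneous closed form.
#'
#' @param medium a \code{two_layer_medium}.
#' @param probe a \code{probe_layout}.
#' @param omega angular modulation frequency, rad/s.
#' @param method "analytic" (default) or "fd".
#' @param spacing voxel size for \code{method = "fd"}, cm.
#' @return an \code{fd_measurement} with 126 pairs.
#' @export
fluence_two_layer <- function(medium, probe, omega = default_omega(),
                              method = c("analytic", "fd"), spacing = 0.25) {
  stopifnot(inherits(medium, "two_layer_medium"), inherits(probe, "probe_layout"))
  method <- match.arg(method)
  geom <- medium$chestwall
  if (abs(geom$tilt_deg) > 20)
    stop("two-layer solver supports |tilt| <= 20 degrees")
  rho <- separations(probe)
  l <- interface_depth(geom, pair_midpoint_x(probe))
  if (any(l < 0.5) || any(l > 6))
    stop("chest-wall depth outside solver domain (0.5 - 6 cm) for some pairs")
  if (method == "analytic") {
    phi <- two_layer_fluence_pairs(rho, l, medium$tissue, medium$chest,
                                   omega, medium$refractive_index)
    measurement_from_fluence(phi, rho, omega / (2 * pi),
                             meta = list(solver = "two_layer_analytic"))
  } else {
    fd_two_layer(medium, probe, omega, spacing)
  }
}

# Fast re-usable two-layer forward for the Nelder-Mead fit: geometry-dependent
# quantities (kernel, depths) are precomputed once, and the returned closure
# maps a property quadruple to (log_amplitude, phase).
two_layer_model_fn <- function(probe, geom, omega = default_omega(),
                               n_index = 1.4) {
  rho <- separations(probe)
  l <- interface_depth(geom, pair_midpoint_x(probe))
  kernel <- hankel_kernel(rho)
  freq <- omega / (2 * pi)
  function(mua, musp, mua_chest, musp_chest) {
    phi <- two_layer_fluence_pairs(
      rho, l,
      structure(list(mua = mua, musp = musp), class = "optical_props"),
      structure(list(mua = mua_chest, musp = musp_chest), class = "optical_props"),
      omega, n_index, kernel = kernel)
    list(log_amplitude = log(Mod(phi)),
         phase = unwrap_by_rho(rho, -Arg(phi)))
  }
}
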