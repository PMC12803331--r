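#' HGO hyperelastic material parameters
#'
#' Container for the uncoupled Holzapfel-Gasser-Ogden (HGO) constitutive
#' model of the vessel wall: an isotropic ground matrix reinforced by two
#' symmetric fiber families with dispersion. The deviatoric strain energy is
#'
#' \deqn{\tilde\Psi = \frac{c}{2}(\tilde I_1 - 3) +
#'   \frac{k_1}{2 k_2}\sum_{\alpha=1,2}\left[e^{k_2 \langle\tilde
#'   E_\alpha\rangle^2} - 1\right],}
#'
#' with fiber strain
#' \eqn{\tilde E_\alpha = \kappa(\tilde I_1 - 3) + (1-3\kappa)(\tilde
#' I_{4\alpha} - 1)} and the volumetric part
#' \eqn{U(J) = (k/2)[(J^2-1)/2 - \log J]}. The angle brackets denote the
#' tension-only switch: a fiber family contributes only while its fiber
#' strain is positive (see `tension_only`).
#'
#' @param c Ground-matrix shear modulus (kPa), > 0.
#' @param k1 Fiber modulus (kPa), >= 0.
#' @param k2 Dimensionless fiber exponential coefficient, > 0.
#' @param gamma Mean fiber orientation angle from the circumferential
#'   direction, degrees in `[0, 90]`. The two families sit at `+gamma` and
#'   `-gamma` in the circumferential-axial tangent plane.
#' @param kappa Fiber dispersion, in `[0, 1/3]` (0 = perfectly aligned,
#'   1/3 = isotropic).
#' @param k_bulk Bulk modulus (kPa), > 0.
#' @param rho Density (kg/mm^3).
#' @param tension_only Logical; if `TRUE` (default, the standard HGO
#'   convention) a fiber family is excluded when its fiber strain is
#'   compressive.
#' @return An object of class `"hgo_params"`.
#' @seealso [baseline_materials()] for the published RVOT values.
#' @export
#' @examples
#' p <- hgo_params(c = 200, k1 = 13480, k2 = 1.06, gamma = 18.85, kappa = 0.33)
#' cauchy_stress(hgo_kinematics(diag(3), p$gamma, p$kappa), p)
hgo_params <- function(c = 200, k1 = 13480, k2 = 1.06, gamma = 18.85,
                       kappa = 0.33, k_bulk = 1500, rho = 1.02e-6,
                       tension_only = TRUE) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  if (c <= 0) stop("ground-matrix shear modulus 'c' must be > 0")
  if (k1 < 0) stop("fiber modulus 'k1' must be >= 0")
  if (k2 <= 0) stop("fiber exponential coefficient 'k2' must be > 0")
  if (gamma < 0 || gamma > 90) stop("'gamma' must be in [0, 90] degrees")
  if (kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("fiber dispersion 'kappa' must be in [0, 1/3]")
  if (k_bulk <= 0) stop("bulk modulus 'k_bulk' must be > 0")
  structure(
    list(c = c, k1 = k1, k2 = k2, gamma = gamma, kappa = min(kappa, 1 / 3),
         k_bulk = k_bulk, rho = rho, tension_only = isTRUE(tension_only)),
    class = "hgo_params"
  )
}

#' @export
print.hgo_params <- function(x, ...) {
  cat("HGO material (uncoupled)\n")
  cat(sprintf("  c = %g kPa, k1 = %g kPa, k2 = %g\n", x$c, x$k1, x$k2))
  cat(sprintf("  gamma = %g deg, kappa = %g, k_bulk = %g kPa\n",
              x$gamma, x$kappa, x$k_bulk))
  cat(sprintf("  rho = %g kg/mm^3, tension-only fibers: %s\n",
              x$rho, x$tension_only))
  invisible(x)
}

#' Isotropic elastic material parameters
#'
#' Isotropic comparator material used for the transannular patch and the
#' crimping tube. At finite strain it is realized as a compressible
#' neo-Hookean solid matched to `(E, nu)` in the small-strain limit
#' (shear modulus `mu = E/(2(1+nu))`, bulk modulus `K = E/(3(1-2nu))`);
#' a small-strain Hooke law is not objective at deployment strains.
#'
#' @param E Young's modulus (kPa), > 0.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @param rho Density (kg/mm^3).
#' @return An object of class `"isotropic_elastic"`.
#' @export
isotropic_elastic <- function(E, nu, rho = 1.41e-6) {
  if (E <= 0) stop("Young's modulus must be > 0")
  if (nu <= -1 || nu >= 0.5) stop("Poisson ratio must be in (-1, 0.5)")
  structure(list(E = E, nu = nu, rho = rho,
                 mu = E / (2 * (1 + nu)), K = E / (3 * (1 - 2 * nu))),
            class = "isotropic_elastic")
}

#' @export
print.isotropic_elastic <- function(x, ...) {
  cat(sprintf("Isotropic elastic: E = %g kPa, nu = %g (mu = %g, K = %g kPa)\n",
              x$E, x$nu, x$mu, x$K))
  invisible(x)
}

# Map an isotropic material onto the HGO machinery: neo-Hookean ground
# matrix, no fibers, matched bulk modulus.
as_hgo <- function(m) {
  if (inherits(m, "hgo_params")) return(m)
  if (inherits(m, "isotropic_elastic"))
    return(hgo_params(c = m$mu, k1 = 0, k2 = 1, gamma = 0, kappa = 0,
                      k_bulk = m$K, rho = m$rho))
  stop("unsupported material object")
}

#' Kinematic state for the HGO model
#'
#' Computes the deformation measures entering the HGO strain energy from a
#' deformation gradient: `J = det F`, the deviatoric right Cauchy-Green
#' tensor `C~ = J^(-2/3) F'F`, its first invariant, the fiber pseudo
#' invariants `I~4a = a0a . C~ a0a` for the two families at `+gamma` and
#' `-gamma` from the circumferential direction, and the dispersed fiber
#' strains `E~a = kappa (I~1 - 3) + (1 - 3 kappa)(I~4a - 1)`.
#'
#' The local frame is right-handed `(circumferential, axial, radial)`, so
#' the reference fiber directions are `(cos gamma, +/- sin gamma, 0)`.
#'
#' @param F Deformation gradient, a 3x3 matrix with `det F > 0`.
#' @param gamma Mean fiber angle, degrees.
#' @param kappa Fiber dispersion in `[0, 1/3]`.
#' @return An object of class `"kinematic_state"`: list with `F`, `J`,
#'   `Cdev`, `I1`, `a0` (2 x 3, one row per family), `I4` (length 2),
#'   `Efib` (length 2), `gamma`, `kappa`.
#' @export
hgo_kinematics <- function(F, gamma, kappa = 1 / 3) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("invalid deformation: det F must be > 0")
  C <- crossprod(F)                      # F'F
  Cdev <- J^(-2 / 3) * C
  I1 <- sum(diag(Cdev))
  g <- gamma * pi / 180
  a0 <- rbind(c(cos(g), sin(g), 0),
              c(cos(g), -sin(g), 0))
  I4 <- c(drop(a0[1, ] %*% Cdev %*% a0[1, ]),
          drop(a0[2, ] %*% Cdev %*% a0[2, ]))
  Efib <- kappa * (I1 - 3) + (1 - 3 * kappa) * (I4 - 1)
  structure(list(F = F, J = J, Cdev = Cdev, I1 = I1, a0 = a0, I4 = I4,
                 Efib = Efib, gamma = gamma, kappa = kappa),
            class = "kinematic_state")
}

#' @export
print.kinematic_state <- function(x, ...) {
  cat(sprintf("Kinematic state: J = %.6g, I1~ = %.6g\n", x$J, x$I1))
  cat(sprintf("  I4~ = (%.6g, %.6g), fiber strains = (%.4g, %.4g)\n",
              x$I4[1], x$I4[2], x$Efib[1], x$Efib[2]))
  invisible(x)
}

# volumetric energy and its derivatives; U(1) = 0, U'(1) = 0, U''(1) = k
vol_energy <- function(J, k) (k / 2) * ((J^2 - 1) / 2 - log(J))
vol_pressure <- function(J, k) (k / 2) * (J - 1 / J)   # U'(J)

# fiber stress measure psi_a = dPsi/dE~_a = k1 E~ exp(k2 E~^2), with the
# tension-only switch applied
fiber_psi <- function(Efib, p) {
  arg <- p$k2 * Efib^2
  if (any(arg > 700))
    stop(sprintf("overflow in fiber exponential (fiber strain %.4g)",
                 Efib[which.max(arg)]))
  psi <- p$k1 * Efib * exp(arg)
  if (p$tension_only) psi[Efib <= 0] <- 0
  psi
}

#' HGO strain-energy density
#'
#' Evaluates the uncoupled HGO strain energy (deviatoric ground matrix +
#' dispersed fiber families + volumetric part) at a kinematic state. Units
#' kPa (energy per unit reference volume).
#'
#' @param state A [hgo_kinematics()] state. Its `gamma`/`kappa` must match
#'   the parameters (they are re-derived if they differ).
#' @param p An [hgo_params] object.
#' @return Scalar energy density in kPa.
#' @export
strain_energy <- function(state, p) {
  stopifnot(inherits(state, "kinematic_state"), inherits(p, "hgo_params"))
  if (state$gamma != p$gamma || state$kappa != p$kappa)
    state <- hgo_kinematics(state$F, p$gamma, p$kappa)
  E <- state$Efib
  arg <- p$k2 * E^2
  if (any(arg > 700))
    stop(sprintf("overflow in fiber exponential (fiber strain %.4g)",
                 E[which.max(arg)]))
  term <- exp(arg) - 1
  if (p$tension_only) term[E <= 0] <- 0
  p$c / 2 * (state$I1 - 3) + p$k1 / (2 * p$k2) * sum(term) +
    vol_energy(state$J, p$k_bulk)
}

#' Cauchy stress of the HGO model
#'
#' Analytic Cauchy stress of the uncoupled formulation: the deviatoric
#' push-forward `sigma_dev = (2/J) dev[ F~ (dPsi~/dC~) F~' ]` plus the
#' volumetric pressure `U'(J) I`.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress (kPa) in the
#'   (circumferential, axial, radial) frame of the state.
#' @export
cauchy_stress <- function(state, p) {
  stopifnot(inherits(state, "kinematic_state"), inherits(p, "hgo_params"))
  if (state$gamma != p$gamma || state$kappa != p$kappa)
    state <- hgo_kinematics(state$F, p$gamma, p$kappa)
  J <- state$J
  psi <- fiber_psi(state$Efib, p)
  # dPsi~/dC~ = (c/2) I + sum_a psi_a (kappa I + (1-3kappa) a0a x a0a)
  S <- (p$c / 2 + p$kappa * sum(psi)) * diag(3)
  for (a in 1:2)
    S <- S + psi[a] * (1 - 3 * p$kappa) * tcrossprod(state$a0[a, ])
  Ft <- J^(-1 / 3) * state$F
  T <- (2 / J) * Ft %*% S %*% t(Ft)
  dev <- T - sum(diag(T)) / 3 * diag(3)
  sig <- dev + vol_pressure(J, p$k_bulk) * diag(3)
  (sig + t(sig)) / 2
}

#' Cauchy stress of an isotropic elastic material at finite strain
#'
#' Compressible neo-Hookean stress matched to `(E, nu)` at small strain,
#' evaluated through the same uncoupled deviatoric/volumetric split as the
#' HGO model (ground matrix `mu = E/(2(1+nu))`, bulk `K = E/(3(1-2nu))`).
#' Reduces to linear isotropic elasticity for infinitesimal strains.
#'
#' @param F Deformation gradient (3x3, `det F > 0`).
#' @param m An [isotropic_elastic] object.
#' @return Symmetric 3x3 Cauchy stress (kPa).
#' @export
isotropic_stress <- function(F, m) {
  stopifnot(inherits(m, "isotropic_elastic"))
  p <- as_hgo(m)
  cauchy_stress(hgo_kinematics(F, p$gamma, p$kappa), p)
}

#' Isotropic strain-energy density
#'
#' Energy counterpart of [isotropic_stress()].
#' @inheritParams isotropic_stress
#' @return Scalar energy density (kPa).
#' @export
isotropic_energy <- function(F, m) {
  p <- as_hgo(m)
  strain_energy(hgo_kinematics(F, p$gamma, p$kappa), p)
}

# --- fast closed-form path for the plane-strain ring map ------------------
#
# For the incompressible plane-strain inflation map the deformation gradient
# is diag(lt, 1, 1/lt) in the (circ, axial, radial) frame, J = 1. Both fiber
# families see the same stretch, the theta-z shears cancel, and the
# constitutive (pressure-free) stress is diagonal. Returns the three
# diagonal components of T = 2 F (dPsi~/dC) F' (defined up to a pressure,
# which drops out of differences) for a vector of hoop stretches.
ring_stress_components <- function(lt, p) {
  p <- as_hgo(p)
  lt2 <- lt^2
  I1 <- lt2 + 1 + 1 / lt2
  g <- p$gamma * pi / 180
  cg2 <- cos(g)^2
  I4 <- lt2 * cg2 + (1 - cg2)
  Efib <- p$kappa * (I1 - 3) + (1 - 3 * p$kappa) * (I4 - 1)
  arg <- p$k2 * Efib^2
  if (any(arg > 700)) stop("overflow in fiber exponential")
  psi <- p$k1 * Efib * exp(arg)
  if (p$tension_only) psi[Efib <= 0] <- 0
  base <- p$c + 4 * p$kappa * psi   # two families, each kappa*I term
  list(
    Ttheta = base * lt2 + 4 * (1 - 3 * p$kappa) * psi * lt2 * cg2,
    Tz = base + 4 * (1 - 3 * p$kappa) * psi * (1 - cg2),
    Tr = base / lt2,
    Efib = Efib
  )
}

# incompressible plane-strain strain-energy density at hoop stretch lt
ring_energy_density <- function(lt, p) {
  p <- as_hgo(p)
  lt2 <- lt^2
  I1 <- lt2 + 1 + 1 / lt2
  g <- p$gamma * pi / 180
  cg2 <- cos(g)^2
  I4 <- lt2 * cg2 + (1 - cg2)
  Efib <- p$kappa * (I1 - 3) + (1 - 3 * p$kappa) * (I4 - 1)
  term <- exp(p$k2 * Efib^2) - 1
  if (p$tension_only) term[Efib <= 0] <- 0
  p$c / 2 * (I1 - 3) + p$k1 / (2 * p$k2) * 2 * term
}
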