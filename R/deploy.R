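#' Per-station thick-walled ring specification
#'
#' The reduced-order surrogate treats each axial station of the vessel as an
#' independent thick-walled ring in plane strain (`lambda_z = 1`) inflated
#' by the stent radial-force law. The deformation is the exactly
#' incompressible inflation map `r(R) = sqrt(r_i^2 + R^2 - R_i^2)`.
#'
#' @param R_inner Reference inner radius, mm.
#' @param thickness Wall thickness, mm.
#' @param sectors Data frame with columns `arc_frac` (summing to 1) and
#'   `material_id`.
#' @param n_layers Radial quadrature/sampling layers (1-6).
#' @param lambda_z Axial stretch (default 1; only 1 is supported by the
#'   incompressible map used here).
#' @return An object of class `"ring_spec"`.
#' @export
ring_spec <- function(R_inner, thickness, sectors = NULL, n_layers = 4,
                      lambda_z = 1) {
  stopifnot(R_inner > 0, thickness > 0, lambda_z > 0)
  if (is.null(sectors))
    sectors <- data.frame(arc_frac = 1, material_id = 1L)
  if (abs(sum(sectors$arc_frac) - 1) > 1e-12)
    stop("sector arc fractions must sum to 1")
  if (any(sectors$arc_frac <= 0)) stop("sector arc fractions must be > 0")
  structure(list(R_inner = R_inner, thickness = thickness,
                 sectors = sectors, n_layers = n_layers,
                 lambda_z = lambda_z),
            class = "ring_spec")
}

# Gauss-Legendre nodes/weights on [-1, 1] (3-point rule per layer panel)
gauss3 <- list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
               w = c(5 / 9, 8 / 9, 5 / 9))

# panel quadrature nodes over the reference wall [R_i, R_o]
ring_quad <- function(R_inner, thickness, n_layers) {
  edges <- R_inner + thickness * (0:n_layers) / n_layers
  mid <- (edges[-1] + edges[-(n_layers + 1)]) / 2
  half <- diff(edges) / 2
  R <- as.vector(outer(gauss3$x, half) + rep(mid, each = 3))
  w <- as.vector(outer(gauss3$w, half))
  list(R = R, w = w)
}

#' Wall pressure of an inflated thick-walled ring
#'
#' Internal pressure required to hold a (homogeneous) HGO or isotropic ring
#' at deployed inner radius `r_i` under the incompressible plane-strain map:
#' `p_w = int_{r_i}^{r_o} (sigma_tt - sigma_rr)/r dr`, evaluated in the
#' reference variable with Gauss quadrature over `n_layers` panels.
#'
#' @param ring A [ring_spec()] (its first sector's material is used unless
#'   `material` is given).
#' @param r_i Deployed inner radius, mm (`>= R_inner` for inflation; any
#'   `r_i` with `r_i^2 > R_inner^2 - R^2` is admissible).
#' @param material An [hgo_params] or [isotropic_elastic] object.
#' @return Pressure in kPa (0 at `r_i = R_inner`).
#' @export
wall_pressure <- function(ring, r_i, material) {
  stopifnot(inherits(ring, "ring_spec"), r_i > 0)
  q <- ring_quad(ring$R_inner, ring$thickness, ring$n_layers)
  r2 <- r_i^2 + q$R^2 - ring$R_inner^2
  if (any(r2 <= 0)) stop("over-compression: deformed radius is not real")
  lt <- sqrt(r2) / q$R
  s <- ring_stress_components(lt, material)
  # dr/dR = R/r and 1/r  =>  integrand (Dsigma/r) dr = Dsigma * R / r^2 dR
  sum((s$Ttheta - s$Tr) * q$R / r2 * q$w)
}

#' Stent radial contact pressure
#'
#' Linear self-expansion law: the device pushes on the wall with pressure
#' `K_s * max(0, (r_free - r_i)/r_free)`, vanishing at and beyond its free
#' radius. Stations outside the device extent (`r_free = 0`) feel nothing.
#'
#' @param stent A [stent_profile()] spec.
#' @param r_i Deployed inner radius, mm.
#' @param station Station index into the stent's per-station free radius.
#' @return Pressure in kPa.
#' @export
stent_pressure <- function(stent, r_i, station) {
  stopifnot(inherits(stent, "stent_spec"), r_i > 0)
  rf <- stent$r_free[station]
  if (is.na(rf) || rf <= 0) return(0)
  stent$K_s * max(0, (rf - r_i) / rf)
}

# strain energy of a ring sector per unit axial length and unit arc
# fraction: int W(lambda(R)) 2 pi R dR (incompressible, reference volume)
ring_sector_energy <- function(R_inner, thickness, n_layers, r_i, material) {
  q <- ring_quad(R_inner, thickness, n_layers)
  lt <- sqrt(r_i^2 + q$R^2 - R_inner^2) / q$R
  sum(ring_energy_density(lt, material) * 2 * pi * q$R * q$w)
}

# invert the sector pressure-stretch law q(lambda) = p (lambda at the inner
# surface); q is strictly increasing with q(1) = 0
invert_sector_pressure <- function(p, R_inner, thickness, n_layers,
                                   material, lam_hi = 3) {
  if (p <= 0) return(1)
  qfun <- function(lam)
    wall_pressure(ring_spec(R_inner, thickness, n_layers = n_layers),
                  lam * R_inner, material)
  hi <- lam_hi
  while (qfun(hi) < p) {
    hi <- hi * 1.5
    if (hi > 50) stop("sector pressure law cannot reach requested pressure")
  }
  lo <- 1
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (qfun(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Solve the equilibrium of one station
#'
#' Finds the deployed inner radius at which the wall pressure balances the
#' stent pressure. Homogeneous stations use bracketed bisection on
#' `[R_inner, r_free]` (the bracket is guaranteed: wall pressure increases
#' and stent pressure decreases with radius) followed by Newton polishing.
#' Heterogeneous (patch) stations solve a composite-ring model in one of
#' two couplings:
#'
#' * `"parallel"` (default): all sectors share the hoop stretch (the patch
#'   deforms with the surrounding wall, as an embedded flush patch does)
#'   and the sector wall pressures add arc-weighted,
#'   `sum_s phi_s q_s(lambda) = p_stent(lambda R)`. A stiffer patch then
#'   carries more stress and strains less as its stiffness grows, the
#'   behaviour observed for embedded transannular patches.
#' * `"series"`: all sectors carry the same transmural pressure, each
#'   inverts its own thick-wall pressure-stretch law
#'   (`lambda_s = q_s^{-1}(p)`, capped at the device free radius), and the
#'   mean stretch closes the ring. This coupling lets a stiff sector
#'   stretch strictly less than its neighbours, but at shared load the
#'   softer sector carries the higher peak stress.
#'
#' Both couplings reduce exactly to the homogeneous path when all sectors
#' share one material. If the stent does not touch the station the
#' identity solution is returned.
#'
#' @param ring A [ring_spec()].
#' @param stent A [stent_profile()] spec.
#' @param materials List of material objects indexed by material id.
#' @param station Station index for the stent profile.
#' @param coupling Composite-ring coupling for heterogeneous stations:
#'   `"parallel"` (shared stretch) or `"series"` (shared pressure).
#' @return An object of class `"ring_solution"`: `r_i` (mean deployed inner
#'   radius), `lambda_sector` (per-sector inner-surface hoop stretch),
#'   `p_wall`, `p_stent`, `residual`, `converged`, `iterations`, `contact`,
#'   and per-sector through-wall node fields `fields` (list of data frames
#'   with `t`, `lambda`, `E1`, `sig1`, `sig_tt`, `sig_zz`, `sig_rr`).
#' @export
solve_station <- function(ring, stent, materials, station = 1L,
                          coupling = c("parallel", "series")) {
  stopifnot(inherits(ring, "ring_spec"))
  coupling <- match.arg(coupling)
  mats <- lapply(ring$sectors$material_id, function(id) materials[[id]])
  rf <- stent$r_free[station]
  no_contact <- is.na(rf) || rf <= 0 ||
    stent_pressure(stent, ring$R_inner, station) <= 0
  if (no_contact) {
    lam <- rep(1, nrow(ring$sectors))
    return(ring_solution(ring, mats, lam, p = 0, p_s = 0, iter = 0L,
                         contact = FALSE))
  }
  homogeneous <- length(unique(ring$sectors$material_id)) == 1L
  if (homogeneous) {
    f <- function(r) wall_pressure(ring, r, mats[[1]]) -
      stent_pressure(stent, r, station)
    lo <- ring$R_inner
    hi <- rf
    it <- 0L
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      it <- it + 1L
    }
    r <- (lo + hi) / 2
    # Newton polish with a finite-difference slope
    for (k in 1:2) {
      h <- 1e-7
      slope <- (f(r + h) - f(r - h)) / (2 * h)
      if (is.finite(slope) && slope > 0) r <- r - f(r) / slope
      it <- it + 1L
    }
    lam <- rep(r / ring$R_inner, nrow(ring$sectors))
    p <- wall_pressure(ring, r, mats[[1]])
    p_s <- stent_pressure(stent, r, station)
  } else if (coupling == "parallel") {
    # shared hoop stretch; arc-weighted sector pressures balance the stent
    f <- function(r) {
      pw <- sum(ring$sectors$arc_frac * vapply(mats, function(m)
        wall_pressure(ring, r, m), numeric(1)))
      pw - stent_pressure(stent, r, station)
    }
    lo <- ring$R_inner
    hi <- rf
    it <- 0L
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      it <- it + 1L
    }
    r <- (lo + hi) / 2
    for (k in 1:2) {
      h <- 1e-7
      slope <- (f(r + h) - f(r - h)) / (2 * h)
      if (is.finite(slope) && slope > 0) r <- r - f(r) / slope
      it <- it + 1L
    }
    lam <- rep(r / ring$R_inner, nrow(ring$sectors))
    p <- sum(ring$sectors$arc_frac * vapply(mats, function(m)
      wall_pressure(ring, r, m), numeric(1)))
    p_s <- stent_pressure(stent, r, station)
  } else {
    # composite: bracketed bisection on the shared transmural pressure.
    # Sector stretches are capped at the stent free radius: the pressure is
    # delivered by the device frame, which cannot push any sector beyond
    # its own free size.
    lam_cap <- rf / ring$R_inner
    lam_of_p <- function(p) pmin(lam_cap, vapply(mats, function(m)
      tryCatch(
        invert_sector_pressure(p, ring$R_inner, ring$thickness,
                               ring$n_layers, m,
                               lam_hi = max(1.5, 1.5 * rf / ring$R_inner)),
        # a sector whose thick-wall law saturates below p would expand past
        # the frame: the cap applies
        error = function(e) Inf),
      numeric(1)))
    # a very soft sector can be unable to carry a high trial pressure (its
    # thick-wall law saturates at a finite limit pressure); at such p the
    # sector has expanded past the stent, so the residual sign is positive
    g <- function(p) {
      lam <- tryCatch(lam_of_p(p), error = function(e) NULL)
      if (is.null(lam)) return(1)
      rbar <- sum(ring$sectors$arc_frac * lam) * ring$R_inner
      p - stent_pressure(stent, rbar, station)
    }
    lo <- 0
    hi <- stent_pressure(stent, ring$R_inner, station)  # p* <= p_s(R_i)
    if (g(hi) < 0) stop("no sign change in composite pressure bracket")
    it <- 0L
    while (hi - lo > 1e-12 * max(1, stent$K_s)) {
      mid <- (lo + hi) / 2
      if (g(mid) < 0) lo <- mid else hi <- mid
      it <- it + 1L
    }
    p <- (lo + hi) / 2
    lam <- lam_of_p(p)
    r <- sum(ring$sectors$arc_frac * lam) * ring$R_inner
    p_s <- stent_pressure(stent, r, station)
  }
  ring_solution(ring, mats, lam, p = p, p_s = p_s, iter = it, contact = TRUE)
}

# assemble through-wall node fields for each sector at its inner stretch
ring_solution <- function(ring, mats, lam, p, p_s, iter, contact) {
  nL <- ring$n_layers
  tt <- (0:nL) / nL
  Rn <- ring$R_inner + ring$thickness * tt
  fields <- vector("list", length(lam))
  for (s in seq_along(lam)) {
    r_i <- lam[s] * ring$R_inner
    rn2 <- r_i^2 + Rn^2 - ring$R_inner^2
    ltn <- sqrt(rn2) / Rn
    sc <- ring_stress_components(ltn, mats[[s]])
    dth <- sc$Ttheta - sc$Tr
    dz <- sc$Tz - sc$Tr
    # radial equilibrium: sig_rr(r) = -int_r^{r_o} dth/rho drho, outer
    # surface traction-free; composite trapezoid on the node grid
    integrand <- dth * Rn / rn2          # per unit dR
    sig_rr <- numeric(nL + 1)
    for (l in nL:1) {
      dR <- Rn[l + 1] - Rn[l]
      sig_rr[l] <- sig_rr[l + 1] - dR * (integrand[l] + integrand[l + 1]) / 2
    }
    sig_tt <- sig_rr + dth
    sig_zz <- sig_rr + dz
    E_tt <- (ltn^2 - 1) / 2
    E_rr <- (1 / ltn^2 - 1) / 2
    fields[[s]] <- data.frame(
      t = tt, lambda = ltn,
      E1 = pmax(E_tt, 0, E_rr),
      sig1 = pmax(sig_tt, sig_zz, sig_rr),
      sig_tt = sig_tt, sig_zz = sig_zz, sig_rr = sig_rr
    )
  }
  structure(
    list(r_i = sum(ring$sectors$arc_frac * lam) * ring$R_inner,
         lambda_sector = lam, p_wall = p, p_stent = p_s,
         residual = abs(p - p_s), converged = abs(p - p_s) < 1e-8,
         iterations = iter, contact = contact, ring = ring,
         fields = fields),
    class = "ring_solution"
  )
}

#' @export
print.ring_solution <- function(x, ...) {
  cat(sprintf("Ring solution: r_i = %.4f mm (R_i = %.4f), p = %.4g kPa\n",
              x$r_i, x$ring$R_inner, x$p_wall))
  cat(sprintf("  contact: %s, residual %.2e kPa, %d iterations\n",
              x$contact, x$residual, x$iterations))
  invisible(x)
}

#' Deploy the stent through the whole vessel
#'
#' Solves every axial station independently and assembles the deployed
#' geometry, the element-wise field table, and bookkeeping. Stations whose
#' equilibrium solve fails are recorded as non-converged and excluded from
#' the field table with a warning; the deployment aborts if more than 10%
#' of contact stations fail.
#'
#' @param geom A [rvot_tube()] geometry (optionally with an embedded patch).
#' @param stent A [stent_profile()] spec.
#' @param materials List of material objects indexed by material id, e.g.
#'   `list(hgo_params(), isotropic_elastic(1100, 0.495))`.
#' @param coupling Composite-ring coupling for heterogeneous stations; see
#'   [solve_station()].
#' @return An object of class `"deployment"`: `stations` (data frame with
#'   `z`, `R_inner`, `r_i`, `p`, `contact`, `converged`, `iterations`),
#'   `solutions` (per-station [solve_station()] results), `fields` (data
#'   frame with `station_mm`, `sector_id`, `material_id`, `distance_ratio`,
#'   `volume_mm3`, `stress1_kPa`, `strain1`), `surface` (deployed
#'   [surface_mesh]), plus the inputs.
#' @export
deploy <- function(geom, stent, materials,
                   coupling = c("parallel", "series")) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(stent, "stent_spec"))
  coupling <- match.arg(coupling)
  if (stent$z_end <= min(geom$z) || stent$z_start >= max(geom$z))
    stop("geometry and stent do not overlap axially")
  n <- length(geom$z)
  sols <- vector("list", n)
  ok <- logical(n)
  for (j in seq_len(n)) {
    ring <- ring_spec(geom$R_inner[j], geom$thickness,
                      sectors = geom$sectors[[j]], n_layers = geom$n_layers)
    sols[[j]] <- tryCatch(solve_station(ring, stent, materials, station = j,
                                        coupling = coupling),
                          error = function(e) e)
    ok[j] <- inherits(sols[[j]], "ring_solution")
  }
  n_contact <- sum(vapply(sols[ok], function(s) s$contact, logical(1)))
  n_fail <- sum(!ok)
  if (n_fail > 0)
    warning(sprintf("%d station(s) failed to converge and were excluded",
                    n_fail))
  if (n_fail > 0.10 * max(1L, n_contact + n_fail))
    stop("more than 10% of stations failed to converge")
  stations <- data.frame(
    z = geom$z,
    R_inner = geom$R_inner,
    r_i = vapply(seq_len(n), function(j)
      if (ok[j]) sols[[j]]$r_i else NA_real_, numeric(1)),
    p = vapply(seq_len(n), function(j)
      if (ok[j]) sols[[j]]$p_wall else NA_real_, numeric(1)),
    contact = vapply(seq_len(n), function(j)
      if (ok[j]) sols[[j]]$contact else NA, logical(1)),
    converged = ok,
    iterations = vapply(seq_len(n), function(j)
      if (ok[j]) sols[[j]]$iterations else NA_integer_, integer(1))
  )
  fields <- assemble_field_table(geom, sols, ok)
  surface <- deployed_surface(geom, stations, sols, ok)
  structure(list(stations = stations, solutions = sols, fields = fields,
                 surface = surface, geometry = geom, stent = stent,
                 materials = materials, coupling = coupling),
            class = "deployment")
}

# tributary axial widths of the stations (half cells at the ends)
station_widths <- function(z) {
  n <- length(z)
  w <- numeric(n)
  w[1] <- (z[2] - z[1]) / 2
  w[n] <- (z[n] - z[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / 2
  w
}

assemble_field_table <- function(geom, sols, ok) {
  wz <- station_widths(geom$z)
  nL <- geom$n_layers
  rows <- list()
  for (j in seq_along(geom$z)) {
    if (!ok[j]) next
    sol <- sols[[j]]
    sec <- geom$sectors[[j]]
    # tributary radial shells of the through-wall nodes
    edges <- geom$R_inner[j] +
      geom$thickness * c(0, (seq_len(nL) - 0.5) / nL, 1)
    shell <- pi * diff(edges^2) * wz[j]
    for (s in seq_len(nrow(sec))) {
      f <- sol$fields[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        station_mm = geom$z[j], sector_id = s,
        material_id = sec$material_id[s],
        distance_ratio = f$t,
        volume_mm3 = sec$arc_frac[s] * shell,
        stress1_kPa = f$sig1, strain1 = f$E1
      )
    }
  }
  do.call(rbind, rows)
}

# rebuild the deployed inner surface: station rings at the deployed mean
# radius, vertex angles redistributed by cumulative sector stretch
deployed_surface <- function(geom, stations, sols, ok) {
  v <- geom$surface$vertices
  n_theta <- geom$n_theta
  newv <- v
  for (j in seq_along(geom$z)) {
    idx <- (j - 1L) * n_theta + seq_len(n_theta)
    if (!ok[j]) next
    sol <- sols[[j]]
    sec <- geom$sectors[[j]]
    th <- atan2(v[idx, 2], v[idx, 1])
    if (nrow(sec) == 1L || diff(range(sol$lambda_sector)) < 1e-14) {
      r <- sol$r_i
      newv[idx, 1] <- r * cos(th)
      newv[idx, 2] <- r * sin(th)
    } else {
      thc <- if (!is.null(geom$patch)) geom$patch$center_theta else 0
      half <- sec$arc_frac[1] * pi        # patch sector half-angle
      d <- (th - thc + pi) %% (2 * pi) - pi
      lam <- ifelse(abs(d) <= half, sol$lambda_sector[1],
                    sol$lambda_sector[2])
      lbar <- sum(sec$arc_frac * sol$lambda_sector)
      r <- lbar * geom$R_inner[j]
      # redistribute angle by cumulative stretch relative to patch center
      dn <- sign(d) * ifelse(abs(d) <= half, abs(d) * lam,
                             half * sol$lambda_sector[1] +
                               (abs(d) - half) * sol$lambda_sector[2]) / lbar
      newv[idx, 1] <- r * cos(thc + dn)
      newv[idx, 2] <- r * sin(thc + dn)
    }
  }
  surface_mesh(newv, geom$surface$faces, geom$surface$material_id)
}

#' @export
print.deployment <- function(x, ...) {
  st <- x$stations
  cat("TPV deployment (per-station ring surrogate)\n")
  cat(sprintf("  %d stations, %d in contact, %d non-converged\n",
              nrow(st), sum(st$contact, na.rm = TRUE), sum(!st$converged)))
  iw <- which(st$contact)
  if (length(iw)) {
    j <- iw[which.min(st$R_inner[iw])]
    cat(sprintf("  waist: R = %.2f -> r = %.2f mm (%.0f%% of free radius)\n",
                st$R_inner[j], st$r_i[j],
                100 * st$r_i[j] / x$stent$free_radius))
  }
  cat(sprintf("  max 1st principal stress %.1f kPa, strain %.4f\n",
              max(x$fields$stress1_kPa), max(x$fields$strain1)))
  invisible(x)
}

#' @export
summary.deployment <- function(object, ...) {
  f <- object$fields
  out <- list(
    stress = field_statistics(f$stress1_kPa, f$volume_mm3),
    strain = field_statistics(f$strain1, f$volume_mm3),
    enclosed_volume = sum(stent_enclosed_volume(object, object$stent))
  )
  class(out) <- "summary.deployment"
  out
}

#' @export
print.summary.deployment <- function(x, ...) {
  cat("Deployment field summary (volume-weighted)\n")
  cat(sprintf("  stress1 (kPa): max %.2f, 95th %.2f, 75th %.2f, mean %.2f\n",
              x$stress$max, x$stress$p95, x$stress$p75, x$stress$mean))
  cat(sprintf("  strain1:       max %.4f, 95th %.4f, 75th %.4f, mean %.4f\n",
              x$strain$max, x$strain$p95, x$strain$p75, x$strain$mean))
  cat(sprintf("  stent enclosed volume %.0f mm^3\n", x$enclosed_volume))
  invisible(x)
}

#' Staged release as a sequence of stent profiles
#'
#' The staged release of the device (compressed, distal half open, fully
#' open) is represented as an ordered list of stent profiles; each produces
#' an independent quasi-static deployment, the last being the endpoint.
#'
#' @param geom,materials As in [deploy()].
#' @param stents Ordered list of [stent_profile()] specs.
#' @return List of `"deployment"` objects, one per stage.
#' @export
deploy_staged <- function(geom, stents, materials) {
  lapply(stents, function(s) deploy(geom, s, materials))
}

#' Export a deployment result
#'
#' Writes the element field table as CSV, the deployed surface as PLY or
#' STL, and a VTK unstructured grid of the deployed surface with point-data
#' arrays `stress_1st_principal` and `lagrangian_strain_1st_principal`
#' (inner-surface values).
#'
#' @param result A [deploy()] result.
#' @param dir Output directory (created if needed).
#' @param basename File stem.
#' @return Character vector of written paths, invisibly.
#' @export
export_deployment <- function(result, dir, basename = "deployment") {
  stopifnot(inherits(result, "deployment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    csv = file.path(dir, paste0(basename, "_fields.csv")),
    ply = file.path(dir, paste0(basename, "_surface.ply")),
    vtk = file.path(dir, paste0(basename, "_surface.vtk"))
  )
  utils::write.csv(result$fields, paths["csv"], row.names = FALSE)
  write_mesh(result$surface, paths["ply"])
  pd <- surface_point_fields(result)
  write_vtk(result$surface$vertices, result$surface$faces, paths["vtk"],
            point_data = pd)
  invisible(paths)
}

# per-vertex inner-surface stress/strain for VTK export
surface_point_fields <- function(result) {
  geom <- result$geometry
  n_theta <- geom$n_theta
  n <- length(geom$z)
  s1 <- numeric(n * n_theta)
  e1 <- numeric(n * n_theta)
  v <- geom$surface$vertices
  for (j in seq_len(n)) {
    idx <- (j - 1L) * n_theta + seq_len(n_theta)
    sol <- result$solutions[[j]]
    if (!inherits(sol, "ring_solution")) next
    sec <- geom$sectors[[j]]
    if (nrow(sec) == 1L) {
      s1[idx] <- sol$fields[[1]]$sig1[1]
      e1[idx] <- sol$fields[[1]]$E1[1]
    } else {
      thc <- if (!is.null(geom$patch)) geom$patch$center_theta else 0
      th <- atan2(v[idx, 2], v[idx, 1])
      d <- abs((th - thc + pi) %% (2 * pi) - pi)
      s_id <- ifelse(d <= sec$arc_frac[1] * pi, 1L, 2L)
      s1[idx] <- vapply(s_id, function(s) sol$fields[[s]]$sig1[1], numeric(1))
      e1[idx] <- vapply(s_id, function(s) sol$fields[[s]]$E1[1], numeric(1))
    }
  }
  list(stress_1st_principal = s1, lagrangian_strain_1st_principal = e1)
}
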