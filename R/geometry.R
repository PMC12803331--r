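#' Parametric radius profiles for the idealized RVOT
#'
#' The idealized vessel that stands in for the segmented patient anatomy is
#' a tube of revolution about the z axis with an axially varying inner
#' radius. `radius_profile_waist()` builds the default smooth
#' flare-waist-flare curve (a Gaussian waist between two flares), which
#' reproduces the stent-vessel impingement pattern of the study: the
#' self-expanding device contacts the wall around the narrowed region and is
#' free at the flared ends. `radius_profile_constant()` is the cylindrical
#' comparator.
#'
#' @param r_flare Flare (end) inner radius, mm.
#' @param r_waist Waist (minimum) inner radius, mm.
#' @param z_waist Axial location of the waist, mm (default mid-vessel).
#' @param width Gaussian width of the waist, mm.
#' @param length Vessel length, mm.
#' @return A function of `z` (mm) returning the inner radius (mm).
#' @export
#' @examples
#' f <- radius_profile_waist(16, 9, length = 60)
#' f(c(0, 30, 60))
radius_profile_waist <- function(r_flare = 16, r_waist = 9, z_waist = NULL,
                                 width = 10, length = 60) {
  if (is.null(z_waist)) z_waist <- length / 2
  stopifnot(r_flare > 0, r_waist > 0, width > 0)
  function(z) r_flare - (r_flare - r_waist) * exp(-((z - z_waist) / width)^2)
}

#' @rdname radius_profile_waist
#' @param r Constant inner radius, mm.
#' @export
radius_profile_constant <- function(r = 12.5) {
  stopifnot(r > 0)
  function(z) rep_len(r, length(z))
}

#' @rdname radius_profile_waist
#' @param r_base Wide (flared) inner radius away from the narrowings, mm.
#' @param waists List of narrowings, each `c(z =, r =, w =)`: center (mm),
#'   minimum radius (mm) and Gaussian width (mm). The default places two
#'   slightly asymmetric narrowings near the distal and proximal thirds of
#'   the vessel, so that both ends of a centered device impinge the wall
#'   while the mid-vessel stays wide -- the contact pattern seen in
#'   deployed RVOTs.
#' @export
radius_profile_rvot <- function(r_base = 16,
                                waists = list(c(z = 16, r = 9, w = 8),
                                              c(z = 44, r = 10, w = 8))) {
  stopifnot(r_base > 0, length(waists) >= 1)
  function(z) {
    R <- rep_len(r_base, length(z))
    for (wst in waists)
      R <- R - (r_base - wst[["r"]]) * exp(-((z - wst[["z"]]) / wst[["w"]])^2)
    R
  }
}

#' Generate the idealized RVOT tube geometry
#'
#' Builds the synthetic vessel: axial stations with a reference inner
#' radius, a closed quad surface mesh of the inner wall (circumferentially
#' closed, open at both ends), a layered hexahedral solid mesh extruded
#' outward through the wall thickness, and a per-station circumferential
#' sector decomposition (initially a single full-circle sector of the
#' vessel material, id 1).
#'
#' @param radius_profile Function of axial coordinate `z` (mm) returning the
#'   inner radius (mm); see [radius_profile_waist()].
#' @param length Vessel length, mm (> 0). Axial coordinate runs
#'   distal (z = 0) to proximal (z = length).
#' @param mesh_size Target surface mesh edge length, mm (default 1.5).
#' @param n_layers Number of radial solid-mesh layers through the wall,
#'   integer 1-6 (default 4).
#' @param thickness Wall thickness, mm (default 1.5); the solid mesh is the
#'   surface extruded outward by this amount.
#' @return An object of class `"vessel_geometry"`: list with `z` (stations),
#'   `R_inner`, `thickness`, `n_layers`, `mesh_size`, `sectors` (per-station
#'   list of data frames with `arc_frac`, `material_id`), `surface`
#'   (a `surface_mesh`: `vertices`, `faces` quads, `material_id` per face),
#'   `n_theta`, and `radius_profile`.
#' @export
#' @examples
#' geom <- rvot_tube(radius_profile_constant(12.5), length = 60, n_layers = 4)
#' geom
rvot_tube <- function(radius_profile, length, mesh_size = 1.5, n_layers = 4,
                      thickness = 1.5) {
  stopifnot(is.function(radius_profile), length > 0, mesh_size > 0,
            thickness > 0)
  if (n_layers < 1 || n_layers > 6) stop("n_layers must be between 1 and 6")
  n_z <- max(2L, as.integer(round(length / mesh_size)) + 1L)
  z <- seq(0, length, length.out = n_z)
  R <- radius_profile(z)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("geometry error: radius profile must be positive everywhere")
  # one circumferential division count for the whole tube (keeps the quads
  # conforming); sized to the mean radius
  n_theta <- max(8L, as.integer(round(2 * pi * mean(R) / mesh_size)))
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- do.call(rbind, lapply(seq_len(n_z), function(j)
    cbind(R[j] * cos(theta), R[j] * sin(theta), z[j])))
  idx <- function(j, k) (j - 1L) * n_theta + ((k - 1L) %% n_theta) + 1L
  faces <- matrix(0L, nrow = (n_z - 1L) * n_theta, ncol = 4L)
  f <- 0L
  for (j in seq_len(n_z - 1L)) for (k in seq_len(n_theta)) {
    f <- f + 1L
    faces[f, ] <- c(idx(j, k), idx(j, k + 1L), idx(j + 1L, k + 1L),
                    idx(j + 1L, k))
  }
  surface <- surface_mesh(verts, faces,
                          material_id = rep(1L, nrow(faces)))
  sectors <- lapply(seq_len(n_z), function(j)
    data.frame(arc_frac = 1, material_id = 1L))
  structure(
    list(z = z, R_inner = R, thickness = thickness, n_layers = n_layers,
         mesh_size = mesh_size, n_theta = n_theta, sectors = sectors,
         surface = surface, radius_profile = radius_profile,
         length = length),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("Idealized RVOT tube\n")
  cat(sprintf("  length %g mm, %d stations, wall %g mm, %d layer(s)\n",
              x$length, length(x$z), x$thickness, x$n_layers))
  cat(sprintf("  inner radius %.2f-%.2f mm, %d x %d quad surface mesh\n",
              min(x$R_inner), max(x$R_inner), length(x$z) - 1L, x$n_theta))
  n_mat <- length(unique(unlist(lapply(x$sectors, `[[`, "material_id"))))
  if (n_mat > 1L) cat(sprintf("  %d materials (patch embedded)\n", n_mat))
  invisible(x)
}

# mid-wall radius used for unrolled arc-length coordinates
midwall_radius <- function(geom) geom$R_inner + geom$thickness / 2

#' Transannular patch region
#'
#' Diamond-shaped patch on the unrolled vessel surface. In unrolled
#' coordinates (circumferential arc length `u = R_mid * theta`, axial `v = z`)
#' membership is `|u - u0|/(du/2) + |v - v0|/(dv/2) <= 1`, where `du`/`dv`
#' are the circumferential/axial diagonals. By default the long diagonal
#' `d1` lies along the vessel axis. Arc length uses the mid-wall radius, the
#' patch being a through-wall region.
#'
#' @param position `"position_1_distal"` or `"position_2_proximal"` (label
#'   only; the location is set by `center_z`/`center_theta`).
#' @param d1 Long diagonal, mm (default 30).
#' @param d2 Short diagonal, mm (default 20).
#' @param center_z Axial center, mm.
#' @param center_theta Circumferential center angle, rad (default 0).
#' @param long_axis `"axial"` (default) or `"circumferential"`: direction of
#'   the long diagonal.
#' @return An object of class `"patch_region"`.
#' @export
patch_region <- function(position = c("position_1_distal",
                                      "position_2_proximal"),
                         d1 = 30, d2 = 20, center_z, center_theta = 0,
                         long_axis = c("axial", "circumferential")) {
  position <- match.arg(position)
  long_axis <- match.arg(long_axis)
  if (d1 < 0 || d2 < 0 || (d1 < d2))
    stop("patch diagonals must satisfy d1 >= d2 >= 0")
  structure(list(position = position, d1 = d1, d2 = d2, center_z = center_z,
                 center_theta = center_theta, long_axis = long_axis),
            class = "patch_region")
}

#' @export
print.patch_region <- function(x, ...) {
  cat(sprintf("Transannular patch (%s): %g x %g mm diamond at z = %g mm\n",
              x$position, x$d1, x$d2, x$center_z))
  invisible(x)
}

# axial and circumferential half-diagonals
patch_half_diagonals <- function(patch) {
  if (patch$long_axis == "axial")
    c(v = patch$d1 / 2, u = patch$d2 / 2)
  else
    c(v = patch$d2 / 2, u = patch$d1 / 2)
}

#' Embed a transannular patch into the vessel geometry
#'
#' Updates the per-station sector decomposition: at each axial station
#' intersecting the diamond, a patch-material sector (material id 2) with
#' angular width equal to the diamond cross-width at that station replaces
#' part of the vessel sector. Surface quads whose centroid falls inside the
#' diamond are relabeled. Embedding is idempotent and a degenerate patch
#' (`d1 = d2 = 0`) leaves the geometry unchanged.
#'
#' @param geom A [rvot_tube()] geometry.
#' @param patch A [patch_region()].
#' @param material_id Integer id given to patch sectors/faces (default 2).
#' @return The modified `vessel_geometry`, with the patch recorded in
#'   `$patch`.
#' @export
embed_patch <- function(geom, patch, material_id = 2L) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(patch, "patch_region"))
  hd <- patch_half_diagonals(patch)
  if (hd[["v"]] == 0 && hd[["u"]] == 0) return(geom)
  if (patch$center_z - hd[["v"]] < min(geom$z) - 1e-9 ||
      patch$center_z + hd[["v"]] > max(geom$z) + 1e-9)
    stop("patch extends outside the vessel axial extent")
  Rm <- midwall_radius(geom)
  for (j in seq_along(geom$z)) {
    dv <- abs(geom$z[j] - patch$center_z)
    if (dv >= hd[["v"]]) next
    # cross half-width in arc length at this station
    wu <- hd[["u"]] * (1 - dv / hd[["v"]])
    ang <- 2 * wu / Rm[j]                     # angular width, rad
    if (ang >= 2 * pi)
      stop("patch arc spans the full circumference")
    frac <- ang / (2 * pi)
    geom$sectors[[j]] <- data.frame(
      arc_frac = c(frac, 1 - frac),
      material_id = c(material_id, 1L)
    )
  }
  # relabel surface quads by centroid membership
  vm <- geom$surface$vertices
  fc <- face_centroids(geom$surface)
  th <- atan2(fc[, 2], fc[, 1])
  dth <- (th - patch$center_theta + pi) %% (2 * pi) - pi
  jc <- pmax(1L, pmin(length(geom$z) - 1L,
                      findInterval(fc[, 3], geom$z)))
  u <- abs(dth) * (Rm[jc] + Rm[jc + 1L]) / 2
  v <- abs(fc[, 3] - patch$center_z)
  inside <- u / hd[["u"]] + v / hd[["v"]] <= 1
  geom$surface$material_id[inside] <- material_id
  geom$surface$material_id[!inside &
    geom$surface$material_id == material_id] <- 1L
  geom$patch <- patch
  geom
}

#' Stent deployment profile
#'
#' Describes the self-expanding device as a free (unconstrained) radius
#' profile along the vessel and a linear radial-force law: the contact
#' pressure exerted on the wall at deployed radius `r` is
#' `K_s * max(0, (r_free - r)/r_free)`. The device extent is divided into
#' equal distal/middle/proximal thirds for regional enclosed-volume
#' reporting. Beam-frame constants of the device are carried as metadata
#' only.
#'
#' @param geom A [rvot_tube()] geometry (the stent extent is clipped to it).
#' @param free_radius Free (unconstrained) radius, mm. Default 12.5 mm for a
#'   25 mm device.
#' @param stiffness Radial stiffness `K_s`, kPa per unit relative recoil.
#' @param z_start,z_end Axial extent of the device, mm; defaults center a
#'   45 mm device in the vessel.
#' @return An object of class `"stent_spec"`: `r_free` (per-station free
#'   radius, 0 where the device is absent), `K_s`, `z_start`, `z_end`,
#'   `thirds` (two interior boundaries), `oversized` (per-station flag),
#'   `metadata`.
#' @export
stent_profile <- function(geom, free_radius = 12.5, stiffness = 400,
                          z_start = NULL, z_end = NULL) {
  stopifnot(inherits(geom, "vessel_geometry"), free_radius > 0,
            stiffness >= 0)
  L_dev <- 45
  if (is.null(z_start)) z_start <- max(min(geom$z),
                                       mean(range(geom$z)) - L_dev / 2)
  if (is.null(z_end)) z_end <- min(max(geom$z),
                                   mean(range(geom$z)) + L_dev / 2)
  if (z_end <= z_start) stop("stent extent is empty")
  z_start <- max(z_start, min(geom$z))
  z_end <- min(z_end, max(geom$z))
  on_dev <- geom$z >= z_start - 1e-9 & geom$z <= z_end + 1e-9
  r_free <- ifelse(on_dev, free_radius, 0)
  oversized <- on_dev & (free_radius > geom$R_inner)
  if (any(oversized))
    message(sprintf("stent oversized at %d of %d stations",
                    sum(oversized), sum(on_dev)))
  thirds <- z_start + (z_end - z_start) * c(1, 2) / 3
  structure(
    list(r_free = r_free, free_radius = free_radius, K_s = stiffness,
         z_start = z_start, z_end = z_end, thirds = thirds,
         oversized = oversized,
         metadata = baseline_materials()$tpv25),
    class = "stent_spec"
  )
}

#' @export
print.stent_spec <- function(x, ...) {
  cat(sprintf("Stent: free radius %g mm, K_s = %g kPa, z in [%g, %g] mm\n",
              x$free_radius, x$K_s, x$z_start, x$z_end))
  cat(sprintf("  thirds boundaries at z = %g, %g mm; oversized at %d stations\n",
              x$thirds[1], x$thirds[2], sum(x$oversized)))
  invisible(x)
}

# ---- mesh helpers --------------------------------------------------------

#' Surface mesh container
#'
#' Minimal quad/triangle surface mesh: an `n x 3` vertex matrix (mm) and an
#' integer face matrix (`m x 4` quads or `m x 3` triangles, 1-based).
#'
#' @param vertices Numeric matrix `n x 3`.
#' @param faces Integer matrix `m x 3` or `m x 4`.
#' @param material_id Optional integer vector of per-face labels.
#' @return An object of class `"surface_mesh"`.
#' @export
surface_mesh <- function(vertices, faces, material_id = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), nrow = NROW(faces))
  stopifnot(ncol(vertices) == 3L, ncol(faces) %in% c(3L, 4L),
            min(faces) >= 1L, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces,
                 material_id = material_id),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d %s faces\n",
              nrow(x$vertices), nrow(x$faces),
              if (ncol(x$faces) == 4L) "quad" else "triangle"))
  invisible(x)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- matrix(0, nrow(f), 3L)
  for (k in seq_len(ncol(f))) out <- out + v[f[, k], , drop = FALSE]
  out / ncol(f)
}

# area of each face (quads split into two triangles)
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  tri_area <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  if (ncol(f) == 3L) tri_area(f[, 1], f[, 2], f[, 3])
  else tri_area(f[, 1], f[, 2], f[, 3]) + tri_area(f[, 1], f[, 3], f[, 4])
}

# edge-face incidence: returns table of how many faces share each edge
edge_face_counts <- function(mesh) {
  f <- mesh$faces
  m <- ncol(f)
  e1 <- integer(0); e2 <- integer(0)
  for (k in seq_len(m)) {
    a <- f[, k]; b <- f[, (k %% m) + 1L]
    e1 <- c(e1, pmin(a, b)); e2 <- c(e2, pmax(a, b))
  }
  key <- paste(e1, e2)
  table(key)
}

#' Surface-mesh topology checks
#'
#' `mesh_edge_check()` verifies that every edge is shared by at most two
#' faces, and reports the number of boundary edges (shared by one face);
#' an open tube has exactly two boundary rings. `mesh_euler()` returns the
#' Euler characteristic V - E + F (0 for an open tube).
#'
#' @param mesh A [surface_mesh].
#' @return `mesh_edge_check()`: list with `ok` (no edge shared by > 2 faces),
#'   `n_boundary`, `n_interior`. `mesh_euler()`: integer.
#' @export
mesh_edge_check <- function(mesh) {
  counts <- edge_face_counts(mesh)
  list(ok = all(counts <= 2L),
       n_boundary = sum(counts == 1L),
       n_interior = sum(counts == 2L))
}

#' @rdname mesh_edge_check
#' @export
mesh_euler <- function(mesh) {
  counts <- edge_face_counts(mesh)
  nrow(mesh$vertices) - length(counts) + nrow(mesh$faces)
}

#' Layered hexahedral solid mesh of the vessel wall
#'
#' Extrudes the inner surface outward along the radial direction through the
#' wall thickness in `n_layers` equal layers, producing hexahedral cells
#' labeled by the material id of their parent surface quad.
#'
#' @param geom A [rvot_tube()] geometry.
#' @return List with `vertices` (mm), `cells` (`m x 8` integer, VTK
#'   hexahedron ordering), `material_id`, `volumes` (mm^3 per cell).
#' @export
solid_mesh <- function(geom) {
  stopifnot(inherits(geom, "vessel_geometry"))
  v <- geom$surface$vertices
  nL <- geom$n_layers
  nv <- nrow(v)
  rad <- cbind(v[, 1], v[, 2], 0)
  nrm <- rad / sqrt(rowSums(rad^2))
  verts <- do.call(rbind, lapply(0:nL, function(l)
    v + nrm * (geom$thickness * l / nL)))
  f <- geom$surface$faces
  cells <- do.call(rbind, lapply(seq_len(nL), function(l) {
    lo <- (l - 1L) * nv
    hi <- l * nv
    cbind(f + lo, f + hi)
  }))
  mat <- rep(geom$surface$material_id %||% rep(1L, nrow(f)), nL)
  vols <- hex_volumes(verts, cells)
  if (any(vols <= 0)) stop("geometry error: non-positive solid cell volume")
  list(vertices = verts, cells = cells, material_id = mat, volumes = vols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hexahedron volumes by decomposition into 6 tetrahedra (VTK node order:
# bottom quad 1-4, top quad 5-8)
hex_volumes <- function(verts, cells) {
  tet_vol <- function(a, b, c, d) {
    u <- verts[b, , drop = FALSE] - verts[a, , drop = FALSE]
    v <- verts[c, , drop = FALSE] - verts[a, , drop = FALSE]
    w <- verts[d, , drop = FALSE] - verts[a, , drop = FALSE]
    (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
  # six signed tetrahedra around the 1-7 diagonal
  k <- cells
  tet_vol(k[, 1], k[, 2], k[, 3], k[, 7]) +
    tet_vol(k[, 1], k[, 3], k[, 4], k[, 7]) +
    tet_vol(k[, 1], k[, 4], k[, 8], k[, 7]) +
    tet_vol(k[, 1], k[, 8], k[, 5], k[, 7]) +
    tet_vol(k[, 1], k[, 5], k[, 6], k[, 7]) +
    tet_vol(k[, 1], k[, 6], k[, 2], k[, 7])
}
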