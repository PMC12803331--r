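#' Volume-weighted empirical percentiles
#'
#' Weighted quantile with the inclusive linear-interpolation convention:
#' after sorting, each observation is assigned the plotting position
#' `p_i = (C_i - w_i) / (W - w_i)` (cumulative weight `C_i`, total `W`),
#' which reduces to the standard `(i-1)/(n-1)` rule for equal weights, and
#' quantiles are linearly interpolated between neighbouring positions.
#' Quantiles are invariant under rescaling of the weights.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length (default: equal).
#' @param probs Quantile levels in `[0, 1]`.
#' @return Numeric vector of quantiles, named by `probs`.
#' @export
#' @examples
#' weighted_percentile(1:100, probs = 0.95)  # 95.05, as quantile() type 7
weighted_percentile <- function(values, weights = NULL, probs) {
  if (length(values) == 0L) stop("empty input")
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights > 0),
            all(probs >= 0 & probs <= 1))
  if (length(values) == 1L)   # single value: every quantile equals it
    return(stats::setNames(rep(values, length(probs)), probs))
  o <- order(values)
  v <- values[o]
  w <- weights[o]
  W <- sum(w)
  cw <- cumsum(w)
  p <- (cw - w) / (W - w)
  out <- stats::approx(p, v, xout = probs, rule = 2, ties = "ordered")$y
  names(out) <- probs
  out
}

# max / percentile / mean block used by reports
field_statistics <- function(values, weights) {
  q <- weighted_percentile(values, weights, c(0.75, 0.95, 0.99))
  list(max = max(values), p99 = q[["0.99"]], p95 = q[["0.95"]],
       p75 = q[["0.75"]], mean = sum(values * weights) / sum(weights))
}

#' Intramural strain profile at a station
#'
#' First principal Lagrangian strain through the wall thickness, against
#' the distance ratio `t` (0 = inner surface, 1 = outer surface).
#'
#' @param result A [deploy()] result.
#' @param station Station index (or axial coordinate if `by_z = TRUE`).
#' @param sector Sector index within the station (default 1).
#' @param by_z Interpret `station` as an axial coordinate in mm.
#' @return Data frame with columns `distance_ratio`, `strain1`.
#' @export
intramural_profile <- function(result, station, sector = 1L, by_z = FALSE) {
  stopifnot(inherits(result, "deployment"))
  if (by_z) station <- which.min(abs(result$geometry$z - station))
  sol <- result$solutions[[station]]
  if (!inherits(sol, "ring_solution")) stop("station did not converge")
  f <- sol$fields[[sector]]
  data.frame(distance_ratio = f$t, strain1 = f$E1)
}

#' Mesh-layer convergence study
#'
#' Re-runs the deployment with 1 through `max_layers` radial wall layers
#' and tracks the volume-weighted 95th and 99th percentile first principal
#' strain; the selected layer count is the smallest `n >= 2` whose change
#' from `n - 1` falls below `criterion_pct` percent for both percentiles.
#'
#' @param geom_fn Function of one argument `n_layers` returning the
#'   [rvot_tube()] geometry (keeps the surface fixed while the radial
#'   discretization varies).
#' @param stent,materials As in [deploy()].
#' @param layers Integer vector of layer counts (default 1:6).
#' @param criterion_pct Convergence criterion, percent change (default 1).
#' @return An object of class `"convergence_study"`: data frame `table`
#'   with `n_layers`, `strain_p95`, `strain_p99`, `change_p95_pct`,
#'   `change_p99_pct`; `selected` (integer or `NA` if no count converges);
#'   `criterion_pct`.
#' @export
convergence_study <- function(geom_fn, stent, materials, layers = 1:6,
                              criterion_pct = 1) {
  stopifnot(criterion_pct > 0)
  p95 <- p99 <- numeric(length(layers))
  for (i in seq_along(layers)) {
    res <- deploy(geom_fn(layers[i]), stent, materials)
    q <- weighted_percentile(res$fields$strain1, res$fields$volume_mm3,
                             c(0.95, 0.99))
    p95[i] <- q[["0.95"]]
    p99[i] <- q[["0.99"]]
  }
  ch95 <- c(NA, abs(diff(p95)) / abs(p95[-length(p95)]) * 100)
  ch99 <- c(NA, abs(diff(p99)) / abs(p99[-length(p99)]) * 100)
  meets <- !is.na(ch95) & ch95 < criterion_pct & ch99 < criterion_pct
  selected <- if (any(meets)) layers[which(meets)[1]] else NA_integer_
  structure(list(
    table = data.frame(n_layers = layers, strain_p95 = p95, strain_p99 = p99,
                       change_p95_pct = ch95, change_p99_pct = ch99),
    selected = selected, criterion_pct = criterion_pct),
    class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat("Mesh-layer convergence study\n")
  print(x$table, row.names = FALSE, digits = 5)
  if (is.na(x$selected))
    cat(sprintf("no layer count met the %.3g%% criterion\n", x$criterion_pct))
  else
    cat(sprintf("selected n_layers = %d (criterion %.3g%%)\n",
                x$selected, x$criterion_pct))
  invisible(x)
}

# ---- geometry comparison metrics ----------------------------------------

# area-weighted random sampling of points on a triangulated surface
sample_surface_points <- function(mesh, n) {
  tri <- triangulate_faces(mesh$faces)
  v <- mesh$vertices
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  pick <- sample.int(nrow(tri), n, replace = TRUE, prob = area)
  u <- stats::runif(n)
  w <- stats::runif(n)
  flip <- u + w > 1
  u[flip] <- 1 - u[flip]
  w[flip] <- 1 - w[flip]
  a[pick, , drop = FALSE] + u * e1[pick, , drop = FALSE] +
    w * e2[pick, , drop = FALSE]
}

# exact distances from one point to every triangle (Eberly's region
# classification), returning the minimum
point_mesh_distance <- function(p, tri_a, tri_e1, tri_e2, prefilter = TRUE,
                                centroids = NULL, circum = NULL) {
  if (prefilter && !is.null(centroids)) {
    dc <- sqrt(rowSums(sweep(centroids, 2, p)^2))
    ub <- min(dc + circum)
    keep <- which(dc - circum <= ub)
  } else keep <- seq_len(nrow(tri_a))
  A <- tri_a[keep, , drop = FALSE]
  E1 <- tri_e1[keep, , drop = FALSE]
  E2 <- tri_e2[keep, , drop = FALSE]
  D <- sweep(A, 2, p)
  a11 <- rowSums(E1 * E1)
  a12 <- rowSums(E1 * E2)
  a22 <- rowSums(E2 * E2)
  b1 <- rowSums(E1 * D)
  b2 <- rowSums(E2 * D)
  det <- pmax(a11 * a22 - a12^2, 1e-300)
  s <- (a12 * b2 - a22 * b1) / det
  t <- (a12 * b1 - a11 * b2) / det
  # clamp to the triangle s >= 0, t >= 0, s + t <= 1
  outside <- s + t > 1 | s < 0 | t < 0
  if (any(outside)) {
    io <- which(outside)
    for (k in io) {
      # minimize along each of the three edges and take the best
      s0 <- min(max(-b1[k] / max(a11[k], 1e-300), 0), 1)   # edge t = 0
      t0 <- min(max(-b2[k] / max(a22[k], 1e-300), 0), 1)   # edge s = 0
      denom <- max(a11[k] - 2 * a12[k] + a22[k], 1e-300)   # edge s + t = 1
      t1 <- min(max((a11[k] - a12[k] + b1[k] - b2[k]) / denom, 0), 1)
      cands <- rbind(c(s0, 0), c(0, t0), c(1 - t1, t1))
      qv <- apply(cands, 1, function(st)
        a11[k] * st[1]^2 + 2 * a12[k] * st[1] * st[2] + a22[k] * st[2]^2 +
          2 * b1[k] * st[1] + 2 * b2[k] * st[2])
      best <- cands[which.min(qv), ]
      s[k] <- best[1]; t[k] <- best[2]
    }
  }
  q <- a11 * s^2 + 2 * a12 * s * t + a22 * t^2 + 2 * b1 * s + 2 * b2 * t +
    rowSums(D * D)
  sqrt(max(min(q), 0))
}

prep_triangles <- function(mesh) {
  tri <- triangulate_faces(mesh$faces)
  v <- mesh$vertices
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  cen <- (a + b + c_) / 3
  circ <- sqrt(pmax(rowSums((a - cen)^2),
                    rowSums((b - cen)^2),
                    rowSums((c_ - cen)^2)))
  list(a = a, e1 = b - a, e2 = c_ - a, cen = cen, circ = circ)
}

#' Surface-mesh comparison distances
#'
#' Hausdorff distance, mean symmetric distance and 95th-percentile
#' symmetric distance between two surfaces, from dense seeded point
#' sampling on both surfaces with exact point-to-triangle distances to the
#' other surface. The symmetric set pools both directions, making all three
#' metrics symmetric in the arguments. Plain point matrices are accepted
#' too, in which case the computation degenerates to the exact brute-force
#' point-set distances.
#'
#' @param mesh_a,mesh_b [surface_mesh] objects or `n x 3` point matrices.
#' @param n_samples Number of surface sample points per direction.
#' @param seed RNG seed for the surface sampling.
#' @return Named numeric vector: `hausdorff`, `mean_symmetric`,
#'   `p95_symmetric` (mm).
#' @export
mesh_distances <- function(mesh_a, mesh_b, n_samples = 1000, seed = 1) {
  point_mode <- !inherits(mesh_a, "surface_mesh") &&
    !inherits(mesh_b, "surface_mesh")
  if (point_mode) {
    A <- as.matrix(mesh_a)
    B <- as.matrix(mesh_b)
    if (nrow(A) == 0L || nrow(B) == 0L) stop("degenerate (empty) input")
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    dab <- sqrt(apply(d2, 1, min))
    dba <- sqrt(apply(d2, 2, min))
  } else {
    stopifnot(inherits(mesh_a, "surface_mesh"),
              inherits(mesh_b, "surface_mesh"))
    if (nrow(mesh_a$faces) == 0L || nrow(mesh_b$faces) == 0L)
      stop("degenerate (empty) mesh")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pa <- rbind(mesh_a$vertices, sample_surface_points(mesh_a, n_samples))
    pb <- rbind(mesh_b$vertices, sample_surface_points(mesh_b, n_samples))
    ta <- prep_triangles(mesh_a)
    tb <- prep_triangles(mesh_b)
    dab <- vapply(seq_len(nrow(pa)), function(i)
      point_mesh_distance(pa[i, ], tb$a, tb$e1, tb$e2, centroids = tb$cen,
                          circum = tb$circ), numeric(1))
    dba <- vapply(seq_len(nrow(pb)), function(i)
      point_mesh_distance(pb[i, ], ta$a, ta$e1, ta$e2, centroids = ta$cen,
                          circum = ta$circ), numeric(1))
  }
  pooled <- c(dab, dba)
  c(hausdorff = max(max(dab), max(dba)),
    mean_symmetric = mean(pooled),
    p95_symmetric = unname(weighted_percentile(pooled, probs = 0.95)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Perimeter-derived diameter
#'
#' Cross-section perimeter divided by pi. For a deployment the station
#' rings of the deployed surface are used and the narrowest station (the
#' minimum over stations) is reported unless one is requested.
#'
#' @param x A [deploy()] result, or an `n x 2` matrix of planar polygon
#'   vertices in order.
#' @param station Optional station index; default: the narrowest.
#' @return Diameter in mm (for a deployment, with attribute `station`).
#' @export
perimeter_derived_diameter <- function(x, station = NULL) {
  if (is.matrix(x)) {
    pts <- x
    per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
    return(per / pi)
  }
  stopifnot(inherits(x, "deployment"))
  v <- x$surface$vertices
  n_theta <- x$geometry$n_theta
  n <- length(x$geometry$z)
  d <- vapply(seq_len(n), function(j) {
    idx <- (j - 1L) * n_theta + seq_len(n_theta)
    perimeter_derived_diameter(v[idx, 1:2])
  }, numeric(1))
  if (is.null(station)) station <- which.min(d)
  structure(d[station], station = station)
}

#' Stent enclosed volume by thirds
#'
#' Volume enclosed by the deployed inner surface within the distal, middle
#' and proximal thirds of the device extent, by trapezoidal integration of
#' `pi r_i(z)^2` along the axis.
#'
#' @param result A [deploy()] result.
#' @param stent The [stent_profile()] (defaults to the one deployed).
#' @return Named numeric vector `c(distal, middle, proximal)` in mm^3.
#' @export
stent_enclosed_volume <- function(result, stent = result$stent) {
  st <- result$stations
  r_of_z <- stats::approxfun(st$z, st$r_i, rule = 2)
  bounds <- c(stent$z_start, stent$thirds, stent$z_end)
  out <- numeric(3)
  for (k in 1:3) {
    zz <- seq(bounds[k], bounds[k + 1], length.out = 101)
    rr <- r_of_z(zz)
    out[k] <- sum(diff(zz) * (pi * rr[-1]^2 + pi * rr[-101]^2) / 2)
  }
  names(out) <- c("distal", "middle", "proximal")
  out
}

#' Outcome metrics report
#'
#' Volume-weighted percentile statistics of the first principal Cauchy
#' stress and Lagrangian strain (whole vessel and, if a patch is embedded,
#' patch-only), the regional stent enclosed volumes, the perimeter-derived
#' diameter at the narrowest station, and (optionally) geometry-comparison
#' distances against a baseline deployed surface.
#'
#' @param result A [deploy()] result.
#' @param baseline_surface Optional [surface_mesh] to compare the deployed
#'   surface against (Hausdorff / mean / 95th-percentile symmetric
#'   distance).
#' @param n_samples,seed Passed to [mesh_distances()].
#' @return An object of class `"metrics_report"` (nested list; see fields).
#' @export
metrics_report <- function(result, baseline_surface = NULL,
                           n_samples = 500, seed = 1) {
  stopifnot(inherits(result, "deployment"))
  f <- result$fields
  rep_block <- function(sub) list(
    stress = field_statistics(sub$stress1_kPa, sub$volume_mm3),
    strain = field_statistics(sub$strain1, sub$volume_mm3))
  out <- list(whole = rep_block(f))
  if (any(f$material_id != 1L))
    out$patch <- rep_block(f[f$material_id != 1L, ])
  out$enclosed_volume <- stent_enclosed_volume(result, result$stent)
  d <- perimeter_derived_diameter(result)
  out$narrowest_diameter <- as.numeric(d)
  out$narrowest_station <- attr(d, "station")
  if (!is.null(baseline_surface))
    out$geometry <- mesh_distances(result$surface, baseline_surface,
                                   n_samples = n_samples, seed = seed)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  pb <- function(nm, b) {
    cat(sprintf("  %s stress1 (kPa): max %.2f / 95th %.2f / 75th %.2f / mean %.2f\n",
                nm, b$stress$max, b$stress$p95, b$stress$p75, b$stress$mean))
    cat(sprintf("  %s strain1:       max %.4f / 95th %.4f / 75th %.4f / mean %.4f\n",
                nm, b$strain$max, b$strain$p95, b$strain$p75, b$strain$mean))
  }
  cat("Metrics report\n")
  pb("whole", x$whole)
  if (!is.null(x$patch)) pb("patch", x$patch)
  cat(sprintf("  enclosed volume (mm^3): distal %.0f, middle %.0f, proximal %.0f\n",
              x$enclosed_volume[1], x$enclosed_volume[2],
              x$enclosed_volume[3]))
  cat(sprintf("  narrowest perimeter-derived diameter %.2f mm (station %d)\n",
              x$narrowest_diameter, x$narrowest_station))
  if (!is.null(x$geometry))
    cat(sprintf("  vs baseline: Hausdorff %.3f, mean %.3f, 95th %.3f mm\n",
                x$geometry["hausdorff"], x$geometry["mean_symmetric"],
                x$geometry["p95_symmetric"]))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report A [metrics_report()].
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (ext == "csv") {
    rows <- list()
    for (scope in intersect(c("whole", "patch"), names(report)))
      for (fld in c("stress", "strain")) {
        b <- report[[scope]][[fld]]
        rows[[length(rows) + 1L]] <- data.frame(
          scope = scope, field = fld, max = b$max, p99 = b$p99, p95 = b$p95,
          p75 = b$p75, mean = b$mean)
      }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else stop("unsupported metrics format: ", ext)
  invisible(path)
}
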