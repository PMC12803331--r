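test_that("weighted percentiles follow the inclusive interpolation rule", {
  expect_equal(unname(weighted_percentile(1:100, probs = 0.95)), 95.05)
  expect_equal(unname(weighted_percentile(1:100, probs = c(0, 1))),
               c(1, 100))
  # single value: every quantile equals it
  expect_equal(unname(weighted_percentile(3.7, 2, c(0.1, 0.5, 0.9))),
               rep(3.7, 3))
  # weight rescaling leaves quantiles unchanged
  set.seed(1)
  v <- rnorm(50)
  w <- runif(50, 0.5, 2)
  q1 <- weighted_percentile(v, w, c(0.25, 0.75, 0.95))
  expect_equal(weighted_percentile(v, 2 * w, c(0.25, 0.75, 0.95)), q1)
  # reordering invariance
  o <- sample(50)
  expect_equal(weighted_percentile(v[o], w[o], c(0.25, 0.75, 0.95)), q1)
  # percentile ordering: 75th <= 95th <= 99th <= max
  q <- weighted_percentile(v, w, c(0.75, 0.95, 0.99))
  expect_true(all(diff(q) >= 0) && q[3] <= max(v))
  expect_error(weighted_percentile(numeric(0), probs = 0.5), "empty")
})

test_that("intramural strain decays outward with exact endpoints", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  j <- which.min(geom$R_inner)
  pr <- intramural_profile(res, j)
  expect_equal(pr$distance_ratio[1], 0)
  expect_equal(pr$distance_ratio[nrow(pr)], 1)
  expect_true(all(diff(pr$strain1) < 0))   # hoop strain decays outward
  # unloaded station: zero profile
  pr0 <- intramural_profile(res, which.max(geom$R_inner))
  expect_lt(max(abs(pr0$strain1)), 1e-12)
})

test_that("convergence study selects the first stable layer count", {
  cfg <- coarse_config()
  mats <- build_materials(cfg)
  st <- build_stent(cfg, build_geometry(cfg, n_layers = 1))
  cs <- convergence_study(function(nl) build_geometry(cfg, n_layers = nl),
                          st, mats, layers = 1:6, criterion_pct = 1)
  expect_equal(nrow(cs$table), 6)
  expect_true(all(is.finite(cs$table$strain_p95)))
  expect_true(all(is.finite(cs$table$change_p95_pct[-1])))
  # any-change criterion selects the first candidate
  cs100 <- convergence_study(function(nl) build_geometry(cfg, n_layers = nl),
                             st, mats, layers = 1:3, criterion_pct = 100)
  expect_equal(cs100$selected, 2L)
  # deterministic given the configuration
  cs2 <- convergence_study(function(nl) build_geometry(cfg, n_layers = nl),
                           st, mats, layers = 1:6, criterion_pct = 1)
  expect_identical(cs$table, cs2$table)
  expect_identical(cs$selected, cs2$selected)
})

test_that("mesh distances vanish on identical meshes and see offsets", {
  m <- small_cylinder(r = 10, length = 20, mesh_size = 1)$surface
  d0 <- mesh_distances(m, m, n_samples = 100, seed = 1)
  expect_lt(max(abs(d0)), 1e-6)

  # concentric cylinders 10 and 11 mm: all three metrics near 1 mm
  m2 <- small_cylinder(r = 11, length = 20, mesh_size = 1)$surface
  d <- mesh_distances(m, m2, n_samples = 400, seed = 2)
  expect_equal(unname(d["hausdorff"]), 1, tolerance = 0.05)
  expect_equal(unname(d["mean_symmetric"]), 1, tolerance = 0.05)
  expect_equal(unname(d["p95_symmetric"]), 1, tolerance = 0.05)

  # symmetry under swapping the meshes
  d_swap <- mesh_distances(m2, m, n_samples = 400, seed = 2)
  expect_equal(unname(d_swap["hausdorff"]), unname(d["hausdorff"]),
               tolerance = 0.05)
})

test_that("point-cloud mode equals the exact brute-force distances", {
  set.seed(5)
  A <- matrix(rnorm(60), ncol = 3)
  B <- matrix(rnorm(90), ncol = 3)
  d <- mesh_distances(A, B)
  ref_ab <- apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))
  ref_ba <- apply(B, 1, function(p) min(sqrt(colSums((t(A) - p)^2))))
  expect_equal(unname(d["hausdorff"]), max(ref_ab, ref_ba))
  expect_equal(unname(d["mean_symmetric"]), mean(c(ref_ab, ref_ba)))
  expect_equal(unname(d["p95_symmetric"]),
               unname(weighted_percentile(c(ref_ab, ref_ba), probs = 0.95)))
})

test_that("point-to-triangle distances are exact on known cases", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(1:3, 1))
  tp <- tpvuq:::prep_triangles(tri)
  d <- function(p) tpvuq:::point_mesh_distance(p, tp$a, tp$e1, tp$e2,
                                               centroids = tp$cen,
                                               circum = tp$circ)
  expect_equal(d(c(0.2, 0.2, 1)), 1)                 # above the face
  expect_equal(d(c(2, 2, 0)), sqrt(2 * 1.5^2))       # beyond the hypotenuse
  expect_equal(d(c(-1, -1, 0)), sqrt(2))             # beyond a vertex
  expect_equal(d(c(0.5, -2, 0)), 2)                  # beyond an edge
  expect_equal(d(c(0.25, 0.25, 0)), 0)               # inside
})

test_that("perimeter-derived diameter matches closed forms", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(7 * cos(th), 7 * sin(th))
  expect_equal(perimeter_derived_diameter(circle), 14, tolerance = 1e-4)

  # ellipse a = 6, b = 4 against numeric arc length
  ell <- cbind(6 * cos(th), 4 * sin(th))
  arc <- stats::integrate(function(t) sqrt(36 * sin(t)^2 + 16 * cos(t)^2),
                          0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(perimeter_derived_diameter(ell), arc / pi, tolerance = 1e-4)

  # rigid rotation invariance
  a <- 0.7
  rot <- ell %*% rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  expect_equal(perimeter_derived_diameter(rot),
               perimeter_derived_diameter(ell), tolerance = 1e-10)

  # deployment: the narrowest station is reported
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  d <- perimeter_derived_diameter(res)
  expect_lt(as.numeric(d), 2 * st$free_radius)
  expect_equal(res$stations$z[attr(d, "station")],
               res$stations$z[which.min(res$stations$r_i)])
})

test_that("enclosed volumes split into consistent thirds", {
  geom <- small_cylinder(r = 12, length = 30, mesh_size = 1.5)
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  v <- stent_enclosed_volume(res, st)
  r <- res$stations$r_i[1]
  expect_equal(unname(v), rep(pi * r^2 * 10, 3), tolerance = 1e-10)
  expect_equal(sum(v), pi * r^2 * 30, tolerance = 1e-10)

  # divergence-theorem volume of the deployed triangulated surface
  m <- res$surface
  tri <- tpvuq:::triangulate_faces(m$faces)
  a <- m$vertices[tri[, 1], ]; b <- m$vertices[tri[, 2], ]
  c_ <- m$vertices[tri[, 3], ]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  cen <- (a + b + c_) / 3
  v_mesh <- abs(sum((cen[, 1] * n[, 1] + cen[, 2] * n[, 2]) / 2))
  expect_equal(sum(v), v_mesh, tolerance = 0.005)
})

test_that("metrics report combines field, volume and geometry blocks", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  gp <- embed_patch(geom, patch_region("position_1_distal", d1 = 16,
                                       d2 = 12, center_z = 15))
  resp <- deploy(gp, st, list(hgo_params(),
                              isotropic_elastic(4.4e3, 0.495)))
  rep <- metrics_report(resp, baseline_surface = res$surface,
                        n_samples = 100, seed = 3)
  expect_s3_class(rep, "metrics_report")
  expect_true(all(c("whole", "patch", "enclosed_volume",
                    "narrowest_diameter", "geometry") %in% names(rep)))
  expect_true(all(rep$geometry >= 0))
  expect_true(rep$whole$stress$p75 <= rep$whole$stress$p95)
  expect_true(rep$whole$stress$p95 <= rep$whole$stress$p99)
  expect_true(rep$whole$stress$p99 <= rep$whole$stress$max)
  td <- withr::local_tempdir()
  write_metrics(rep, file.path(td, "m.json"))
  js <- jsonlite::read_json(file.path(td, "m.json"))
  expect_equal(js$whole$stress$max, rep$whole$stress$max, tolerance = 1e-9)
  write_metrics(rep, file.path(td, "m.csv"))
  expect_equal(nrow(read.csv(file.path(td, "m.csv"))), 4)
})
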