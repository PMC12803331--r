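test_that("wall pressure vanishes at the reference radius and grows with r", {
  ring <- ring_spec(9, 1.5, n_layers = 4)
  p <- hgo_params()
  expect_equal(wall_pressure(ring, 9, p), 0)
  r <- seq(9, 1.5 * 9, length.out = 40)
  pw <- vapply(r, function(ri) wall_pressure(ring, ri, p), numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("neo-Hookean wall pressure matches brute-force quadrature", {
  mu <- 250
  m <- hgo_params(c = mu, k1 = 0, k2 = 1, gamma = 0, kappa = 0)
  R_i <- 10; H <- 2
  for (nl in c(1, 4)) {
    ring <- ring_spec(R_i, H, n_layers = nl)
    for (r_i in c(10.8, 12, 13.5)) {
      # independent high-resolution quadrature of the closed-form
      # incompressible thick-wall integrand mu (lt^2 - lt^-2) / r
      ref <- stats::integrate(function(R) {
        r2 <- r_i^2 + R^2 - R_i^2
        lt2 <- r2 / R^2
        mu * (lt2 - 1 / lt2) * R / r2
      }, R_i, R_i + H, rel.tol = 1e-12)$value
      expect_equal(wall_pressure(ring, r_i, m), ref,
                   tolerance = if (nl == 1) 1e-3 else 1e-4)
    }
  }
})

test_that("stent radial-force law is linear with cut-off", {
  geom <- small_cylinder(r = 12, length = 30)
  st <- suppressMessages(stent_profile(geom, free_radius = 10,
                                       stiffness = 40,
                                       z_start = 0, z_end = 30))
  expect_equal(stent_pressure(st, 10, 1), 0)
  expect_equal(stent_pressure(st, 5, 1), 20)
  expect_equal(stent_pressure(st, 12, 1), 0)   # beyond free radius
  r <- seq(4, 12, 0.5)
  ps <- vapply(r, function(ri) stent_pressure(st, ri, 1), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("station equilibrium balances wall against stent pressure", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  mats <- list(hgo_params())
  j <- which.min(geom$R_inner)
  ring <- ring_spec(geom$R_inner[j], geom$thickness, n_layers = 4)
  sol <- solve_station(ring, st, mats, station = j)
  expect_true(sol$contact)
  expect_lt(sol$residual, 1e-8)
  expect_gt(sol$r_i, ring$R_inner)
  expect_lt(sol$r_i, st$free_radius)
})

test_that("equilibrium radius minimizes the total potential energy", {
  # brute-force 1-D scan oracle: wall strain energy minus stent work
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  mats <- list(hgo_params())
  j <- which.min(geom$R_inner)
  R_i <- geom$R_inner[j]
  ring <- ring_spec(R_i, geom$thickness, n_layers = 4)
  sol <- solve_station(ring, st, mats, station = j)

  potential <- function(r_i) {
    wall <- tpvuq:::ring_sector_energy(R_i, geom$thickness, 12, r_i,
                                       mats[[1]])
    work <- stats::integrate(function(rho)
      vapply(rho, function(x) stent_pressure(st, x, j), numeric(1)) *
        2 * pi * rho, R_i, r_i, rel.tol = 1e-10)$value
    wall - work
  }
  opt <- stats::optimize(potential, c(R_i, st$free_radius), tol = 1e-9)
  expect_equal(sol$r_i, opt$minimum, tolerance = 1e-4)
})

test_that("identity solution is returned where the stent does not touch", {
  geom <- small_cylinder(r = 13, length = 30)
  st <- suppressMessages(stent_profile(geom, free_radius = 12.5,
                                       z_start = 0, z_end = 30))
  sol <- solve_station(ring_spec(13, 1.5, n_layers = 2), st,
                       list(hgo_params()), station = 1)
  expect_false(sol$contact)
  expect_equal(sol$r_i, 13)
  expect_true(all(abs(sol$fields[[1]]$sig1) < 1e-10))
  expect_true(all(abs(sol$fields[[1]]$E1) < 1e-12))
})

test_that("composite and homogeneous paths agree for a uniform ring", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  p <- hgo_params()
  j <- which.min(geom$R_inner)
  ring_h <- ring_spec(geom$R_inner[j], 1.5, n_layers = 4)
  ring_c <- ring_spec(geom$R_inner[j], 1.5,
                      sectors = data.frame(arc_frac = c(0.3, 0.7),
                                           material_id = c(2L, 1L)),
                      n_layers = 4)
  sh <- solve_station(ring_h, st, list(p, p), station = j)
  for (cpl in c("parallel", "series")) {
    sc <- solve_station(ring_c, st, list(p, p), station = j, coupling = cpl)
    expect_lt(abs(sc$r_i - sh$r_i), 1e-8)
  }
})

test_that("a much stiffer sector stretches strictly less (series model)", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  j <- which.min(geom$R_inner)
  ring <- ring_spec(geom$R_inner[j], 1.5,
                    sectors = data.frame(arc_frac = c(0.3, 0.7),
                                         material_id = c(2L, 1L)),
                    n_layers = 4)
  sol <- solve_station(ring, st,
                       list(hgo_params(), isotropic_elastic(8.8e3, 0.495)),
                       station = j, coupling = "series")
  expect_lt(sol$lambda_sector[1], sol$lambda_sector[2])
})

test_that("uniform cylinder deploys identically at every station", {
  geom <- small_cylinder(r = 12, length = 30, mesh_size = 1.5)
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  ri <- res$stations$r_i
  expect_lt(diff(range(ri)), 1e-10)
  expect_true(all(res$stations$converged))
})

test_that("incompressibility holds through the wall", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  for (j in which(res$stations$contact)) {
    f <- res$solutions[[j]]$fields[[1]]
    # first principal Green-Lagrange strain is the hoop one under inflation
    expect_equal(f$E1, (f$lambda^2 - 1) / 2, tolerance = 1e-12)
    # deformed radii obey the exactly incompressible plane-strain map
    R <- geom$R_inner[j] + geom$thickness * f$t
    r <- f$lambda * R
    expect_true(all(abs(r^2 - (res$solutions[[j]]$lambda_sector[1]^2 *
                                 geom$R_inner[j]^2 + R^2 -
                                 geom$R_inner[j]^2)) < 1e-8))
  }
})

test_that("maximum stress occurs inside the stent contact zone", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  f <- res$fields
  z_max <- f$station_mm[which.max(f$stress1_kPa)]
  contact_z <- res$stations$z[which(res$stations$contact)]
  expect_true(z_max %in% contact_z)
})

test_that("deployed volume grows with stent stiffness", {
  geom <- small_waist_geom()
  vols <- vapply(c(100, 400, 800), function(K) {
    st <- suppressMessages(stent_profile(geom, stiffness = K,
                                         z_start = 0, z_end = 30))
    res <- deploy(geom, st, list(hgo_params()))
    sum(stent_enclosed_volume(res, st))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("field-table volume weights partition the wall volume", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  wz <- tpvuq:::station_widths(geom$z)
  wall <- sum(pi * ((geom$R_inner + geom$thickness)^2 - geom$R_inner^2) * wz)
  expect_equal(sum(res$fields$volume_mm3), wall, tolerance = 1e-8)
  expect_true(all(res$fields$volume_mm3 > 0))
})

test_that("staged release ends at the direct deployment endpoint", {
  geom <- small_waist_geom()
  free <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  crimped <- suppressMessages(stent_profile(geom, free_radius = 1e-6,
                                            z_start = 0, z_end = 30))
  stages <- deploy_staged(geom, list(crimped, free), list(hgo_params()))
  direct <- deploy(geom, free, list(hgo_params()))
  expect_equal(stages[[2]]$stations$r_i, direct$stations$r_i)
  expect_equal(stages[[1]]$stations$r_i, geom$R_inner)  # crimped: no contact
})

test_that("deployment exports field CSV, surface and VTK", {
  geom <- small_waist_geom()
  st <- suppressMessages(stent_profile(geom, z_start = 0, z_end = 30))
  res <- deploy(geom, st, list(hgo_params()))
  td <- withr::local_tempdir()
  paths <- export_deployment(res, td, "dep")
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths["csv"])
  expect_identical(names(tab),
                   c("station_mm", "sector_id", "material_id",
                     "distance_ratio", "volume_mm3", "stress1_kPa",
                     "strain1"))
  m <- read_mesh(paths["ply"])
  expect_equal(nrow(m$vertices), nrow(res$surface$vertices))
  expect_match(readLines(paths["vtk"], n = 4)[4], "UNSTRUCTURED_GRID")
})
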