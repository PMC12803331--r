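# shared fixtures: cheap geometries and a coarse study configuration used
# by the unit tests (the acceptance tests run the full default conditions)

table1_hgo <- function(...) hgo_params(...)

small_cylinder <- function(r = 12, length = 30, mesh_size = 3, n_layers = 2) {
  rvot_tube(radius_profile_constant(r), length = length,
            mesh_size = mesh_size, n_layers = n_layers)
}

small_waist_geom <- function(n_layers = 4, mesh_size = 3) {
  rvot_tube(radius_profile_waist(16, 9, z_waist = 15, width = 8, length = 30),
            length = 30, mesh_size = mesh_size, n_layers = n_layers)
}

coarse_config <- function() {
  cfg <- default_config()
  cfg$geometry$mesh_size <- 3
  cfg
}

# deterministic random deformation gradients near the identity
random_states <- function(n, scale = 0.2, seed = 42) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    F <- diag(3) + scale * matrix(stats::rnorm(9), 3)
    if (det(F) > 0.3) {
      i <- i + 1L
      out[[i]] <- F
    }
  }
  out
}

# independent finite-difference Cauchy stress: sigma = (1/J) dPsi/dF F^T
fd_cauchy <- function(F, p, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(hgo_kinematics(Fp, p$gamma, p$kappa), p) -
                strain_energy(hgo_kinematics(Fm, p$gamma, p$kappa), p)) /
      (2 * h)
  }
  S <- P %*% t(F) / det(F)
  (S + t(S)) / 2
}
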