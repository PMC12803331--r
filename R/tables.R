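#' Baseline material parameters for the simulation components
#'
#' Published baseline values for the three components of the deployment
#' model: the RVOT vessel wall (uncoupled HGO), the TPV25 device frame
#' (nitinol beam constants, recorded as metadata only -- no beam finite
#' elements are solved here), and the crimping tube (neo-Hookean).
#'
#' Units follow the mm/kPa/kg convention used throughout the package:
#' stresses and moduli in kPa, lengths in mm, densities in kg/mm^3.
#'
#' @return A named list with elements `rvot` (an [hgo_params] object),
#'   `tpv25` (a named list of recorded beam constants) and `tube`
#'   (an [isotropic_elastic] object).
#' @export
#' @examples
#' baseline_materials()$rvot
baseline_materials <- function() {
  list(
    rvot = hgo_params(
      c = 200, k1 = 13480, k2 = 1.06, gamma = 18.85, kappa = 0.33,
      k_bulk = 1500, rho = 1.02e-6
    ),
    # Beam-frame constants kept verbatim for provenance. The printed
    # cross-section area 0.111045 mm^2 differs from pi*r^2 at r = 0.1875 mm
    # (0.110447 mm^2); it is stored as printed and never used in computation.
    tpv25 = list(
      rho = 6.5e-6, E = 4.0e7, G = 1.5e7,
      beam_diameter = 0.375, A = 0.111045, I = 0.000970722
    ),
    tube = isotropic_elastic(E = 4.0e7, nu = 0.33, rho = 6.5e-6)
  )
}

#' Published arterial-layer variability statistics (media layer)
#'
#' Mean and standard deviation of constitutive parameters reported for the
#' media layer of adult arteries, together with the standard deviation
#' expressed as a percentage of the mean, as printed in the source data.
#' The media layer dominates arterial wall mechanics, so these percentages
#' parameterize the material uncertainty of the whole-wall HGO model.
#'
#' The `epsilon` column belongs to the source's own constitutive model and
#' has no HGO counterpart; its printed percentage (48.89) is inconsistent
#' with its printed mean/std (0.05/0.02) but is reproduced verbatim, and it
#' enters the printed row average (39) exactly as printed. Use
#' [std_pct_from_layer_stats()] to recompute percentages from mean/std.
#'
#' @return A data frame with columns `parameter`, `mean`, `std`,
#'   `percentage` (the printed value).
#' @seealso [std_pct_from_layer_stats()], [default_gamma_specs()]
#' @export
media_layer_stats <- function() {
  data.frame(
    parameter = c("c", "k1", "k2", "gamma", "kappa", "epsilon"),
    mean = c(1.27, 21.6, 8.21, 20.61, 0.25, 0.05),
    std = c(0.63, 7.12, 3.27, 5.5, 0.09, 0.02),
    percentage = c(49.61, 32.96, 39.83, 26.69, 36, 48.89),
    stringsAsFactors = FALSE
  )
}

#' Transannular patch material conditions
#'
#' The four patch stiffness conditions: an isotropic elastic patch with
#' Young's modulus 1.1e3 kPa scaled 2x, 4x and 8x, Poisson ratio 0.495 and
#' density 1.41e-6 kg/mm^3.
#'
#' @return A data frame with columns `condition`, `E_kPa`, `nu`, `rho`.
#' @export
patch_conditions <- function() {
  data.frame(
    condition = paste0("stiffness_", 1:4),
    E_kPa = 1.1e3 * c(1, 2, 4, 8),
    nu = 0.495,
    rho = 1.41e-6,
    stringsAsFactors = FALSE
  )
}
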