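#' Model parameters for the coarse-grained binding model
#'
#' Collects every energy-function, thermostat and integrator constant in one
#' validated object. Defaults follow the conventions of residue-level
#' structure-based (Go-type) models: each amino acid is one bead at the
#' C-alpha position, ligands are small rigid bead clusters, and the
#' protein can switch between a closed and an open reference conformation
#' through a double-basin interface potential.
#'
#' @param eps_nat Depth (kcal/mol) of the 12-10 protein--ligand native-contact
#'   well. Default 0.15.
#' @param eps_nnat Depth (kcal/mol) of the Gaussian non-native protein--ligand
#'   well; controls the ruggedness of the binding landscape. Default 0 (smooth).
#' @param sigma_nnat Width (Angstrom) of the non-native Gaussian well.
#'   Default 6.0.
#' @param eps_pp Depth (kcal/mol) of protein--protein native contacts.
#'   Default 1.2 (roughly 2 kBT at 300 K, enough to hold a small fold together).
#' @param eps_exv Excluded-volume prefactor (kcal/mol) for ligand-related
#'   pairs. Default 1.0.
#' @param sigma_exv_protein_ligand Excluded-volume diameter (Angstrom) for
#'   protein--ligand pairs without a native contact. Default 5.0.
#' @param sigma_exv_ligand_ligand Excluded-volume diameter (Angstrom) between
#'   beads of different ligands. Default 3.5.
#' @param eps_exv_pp,sigma_exv_pp Excluded-volume prefactor and diameter for
#'   non-contact protein pairs. Defaults 0.2 kcal/mol and 4.0 Angstrom.
#' @param deltaV Per-interface energy offset added to the open basin
#'   (kcal/mol); recalibrated per system (see [calibrate_basin_offset()]).
#' @param coupling_delta Per-interface double-basin coupling Delta (kcal/mol).
#' @param k_bond,k_angle,k_dihedral Bonded force constants
#'   (kcal/mol/A^2, kcal/mol/rad^2, kcal/mol).
#' @param k_enm,enm_cutoff,enm_cutoff_core Intra-domain elastic-network
#'   constant (kcal/mol/A^2) and pair cutoffs (Angstrom; the CORE domain
#'   uses the longer `enm_cutoff_core`). The network keeps each domain near
#'   its reference geometry (domains move as quasi-rigid bodies about the
#'   hinge) while leaving the interface energetics to the double-basin
#'   contact terms. Defaults 0.5, 10.5 and 16.
#' @param k_ligand_bond Stiff constant (kcal/mol/A^2) of the harmonic
#'   distance network restraining each ligand's internal geometry (bond
#'   lengths, bends and torsions via first-, second- and third-neighbour
#'   distances) to its reference values -- the rigid-ligand approximation.
#' @param temperature Kelvin. Default 300.
#' @param gamma Langevin friction, 1/tau. Default 0.25.
#' @param dt Integration step, tau. Default 0.1.
#' @param q_lambda Formed-contact cutoff ratio for the fraction of native
#'   contacts Q (a contact counts as formed when r < q_lambda * r0).
#'   Default 1.2.
#'
#' @return An object of class `cg_params` (a validated list).
#' @export
cg_params <- function(eps_nat = 0.15, eps_nnat = 0, sigma_nnat = 6.0,
                      eps_pp = 1.2, eps_exv = 1.0,
                      sigma_exv_protein_ligand = 5.0,
                      sigma_exv_ligand_ligand = 3.5,
                      eps_exv_pp = 0.2, sigma_exv_pp = 4.0,
                      deltaV = numeric(), coupling_delta = numeric(),
                      k_bond = 10, k_angle = 5, k_dihedral = 1,
                      k_enm = 0.5, enm_cutoff = 10.5, enm_cutoff_core = 16,
                      k_ligand_bond = 25,
                      temperature = 300, gamma = 0.25, dt = 0.1,
                      q_lambda = 1.2) {
  p <- list(eps_nat = eps_nat, eps_nnat = eps_nnat, sigma_nnat = sigma_nnat,
            eps_pp = eps_pp, eps_exv = eps_exv,
            sigma_exv_protein_ligand = sigma_exv_protein_ligand,
            sigma_exv_ligand_ligand = sigma_exv_ligand_ligand,
            eps_exv_pp = eps_exv_pp, sigma_exv_pp = sigma_exv_pp,
            deltaV = deltaV, coupling_delta = coupling_delta,
            k_bond = k_bond, k_angle = k_angle, k_dihedral = k_dihedral,
            k_enm = k_enm, enm_cutoff = enm_cutoff,
            enm_cutoff_core = enm_cutoff_core,
            k_ligand_bond = k_ligand_bond,
            temperature = temperature, gamma = gamma, dt = dt,
            q_lambda = q_lambda)
  validate_cg_params(p)
  class(p) <- "cg_params"
  p
}

validate_cg_params <- function(p) {
  eps <- c(p$eps_nat, p$eps_nnat, p$eps_pp, p$eps_exv, p$eps_exv_pp)
  if (any(eps < 0)) stop("all epsilon parameters must be >= 0")
  sig <- c(p$sigma_nnat, p$sigma_exv_protein_ligand,
           p$sigma_exv_ligand_ligand, p$sigma_exv_pp)
  if (any(sig <= 0)) stop("all sigma parameters must be > 0")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$gamma < 0) stop("gamma must be >= 0")
  if (p$temperature <= 0) stop("temperature must be > 0")
  if (any(p$coupling_delta < 0)) stop("coupling_delta must be >= 0")
  if (length(p$deltaV) != length(p$coupling_delta))
    stop("deltaV and coupling_delta must have equal length")
  invisible(p)
}

#' Thermal energy kB*T in kcal/mol
#' @param temperature Kelvin.
#' @return kB*T in kcal/mol.
#' @export
kBT <- function(temperature = 300) 0.0019872041 * temperature

#' Modify parameters of an existing `cg_params` object
#' @param params A `cg_params` object.
#' @param ... Named fields to replace.
#' @return The updated `cg_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cg_params"))
  mod <- list(...)
  bad <- setdiff(names(mod), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(mod)] <- mod
  validate_cg_params(params)
  class(params) <- "cg_params"
  params
}

#' @export
print.cg_params <- function(x, ...) {
  cat("<cg_params>\n")
  cat(sprintf("  eps_nat %.3g  eps_nnat %.3g  sigma_nnat %.3g A\n",
              x$eps_nat, x$eps_nnat, x$sigma_nnat))
  cat(sprintf("  T %g K (kBT = %.4f kcal/mol)  gamma %g/tau  dt %g tau\n",
              x$temperature, kBT(x$temperature), x$gamma, x$dt))
  if (length(x$deltaV))
    cat("  deltaV:", paste(signif(x$deltaV, 4), collapse = ", "),
        " Delta:", paste(signif(x$coupling_delta, 4), collapse = ", "), "\n")
  invisible(x)
}
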