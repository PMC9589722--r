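#' Total coarse-grained energy and forces
#'
#' Evaluates the full model energy: closed-referenced bonded terms, shared
#' single-basin 12-10 contacts, per-interface double-basin mixed contact
#' components, non-native Gaussian wells, excluded volume, and any
#' restraints. Forces are the exact analytic negative gradient.
#'
#' @param coords N x 3 coordinates (Angstrom).
#' @param topology A `cg_topology`.
#' @param params Optional `cg_params` overriding `topology$params`.
#' @param restraints List of restraint specifications (see
#'   [flat_bottom_restraint_spec()] and friends); default none.
#' @param mode `"mixed"` (double-basin, default), `"closed"` or `"open"`
#'   (single-basin limits).
#' @return List with per-component energies (kcal/mol), `total`, and
#'   `forces` (N x 3, kcal/mol/Angstrom).
#' @export
total_energy <- function(coords, topology, params = NULL, restraints = list(),
                         mode = c("mixed", "closed", "open")) {
  mode <- match.arg(mode)
  p <- if (is.null(params)) topology$params else params
  m <- c(mixed = 0L, closed = 1L, open = 2L)[[mode]]
  cg_energy_cpp(as.matrix(coords), topology$core,
                p$eps_nnat, p$sigma_nnat,
                as.numeric(p$deltaV), as.numeric(p$coupling_delta),
                restraints, m)
}

#' Single-basin structure-based energy
#'
#' The energy with every interface component pinned to one basin: bonded
#' terms, that basin's 12-10 native contacts (plus the shared intra-domain
#' and protein--ligand contacts), and excluded volume.
#'
#' @inheritParams total_energy
#' @param basin_reference `"closed"` or `"open"`.
#' @return As [total_energy()].
#' @export
single_basin_energy <- function(coords, topology, basin_reference = c("closed", "open"),
                                params = NULL) {
  basin_reference <- match.arg(basin_reference)
  total_energy(coords, topology, params = params, mode = basin_reference)
}

#' Apo (ligand-free) energy of a topology
#'
#' Convenience wrapper: evaluates [total_energy()] with all ligand-involving
#' terms absent. Requires `coords` for the protein beads only, or full
#' coordinates from which the protein beads are taken.
#' @inheritParams total_energy
#' @return As [total_energy()].
#' @export
apo_energy <- function(coords, topology, params = NULL,
                       mode = c("mixed", "closed", "open")) {
  mode <- match.arg(mode)
  X <- as.matrix(coords)
  if (nrow(X) == length(topology$protein_idx) && topology$n > nrow(X)) {
    # place ligands far away so every ligand term is beyond truncation
    full <- topology$closed
    full[topology$protein_idx, ] <- X
    lig <- setdiff(seq_len(topology$n), topology$protein_idx)
    full[lig, ] <- full[lig, , drop = FALSE] + 1e4
    X <- full
  }
  total_energy(X, topology, params = params, mode = mode)
}

#' Double-basin mixing of two basin energies
#'
#' The standard two-state secular-determinant form
#' `V_MB = ((V1 + V2) - sqrt((V1 - V2)^2 + 4 Delta^2)) / 2`,
#' with `V1` the closed-basin energy and `V2` the open-basin energy plus the
#' offset `deltaV`. `V_MB <= min(V1, V2)` always, with equality iff
#' `Delta = 0`.
#'
#' @param V_closed,V_open Basin energies (kcal/mol).
#' @param deltaV Offset added to the open basin (kcal/mol).
#' @param coupling Coupling Delta >= 0 (kcal/mol).
#' @return List with `energy`, and the chain-rule weights `w_closed`,
#'   `w_open` (partial derivatives of `V_MB` w.r.t. `V1` and `V2`).
#' @export
multi_basin_mix <- function(V_closed, V_open, deltaV = 0, coupling = 0) {
  if (coupling < 0) stop("coupling must be >= 0")
  V1 <- V_closed
  V2 <- V_open + deltaV
  s <- sqrt((V1 - V2)^2 + 4 * coupling^2)
  e <- (V1 + V2 - s) / 2
  if (s < 1e-12) {
    w1 <- 0.5; w2 <- 0.5
  } else {
    w1 <- 0.5 * (1 - (V1 - V2) / s)
    w2 <- 0.5 * (1 + (V1 - V2) / s)
  }
  list(energy = e, w_closed = w1, w_open = w2)
}

#' 12-10 native-contact pair potential
#'
#' `eps * (5 (r0/r)^12 - 6 (r0/r)^10)`: minimum `-eps` at `r = r0`,
#' repulsive core, vanishing at large separation. The simulation core
#' truncates this term at `2.5 r0` with an energy shift; this reference
#' implementation returns the untruncated value.
#'
#' @param r Distance (Angstrom), > 0.
#' @param r0 Reference distance (Angstrom).
#' @param eps Well depth (kcal/mol).
#' @return Energy in kcal/mol.
#' @export
ligand_native_term <- function(r, r0, eps) {
  if (any(r <= 0)) stop("r must be > 0")
  q <- r0 / r
  eps * (5 * q^12 - 6 * q^10)
}

#' Gaussian non-native pair potential
#'
#' `-eps_nnat * exp(-r^2 / (2 sigma^2))`: a bounded attractive well whose
#' depth sets the ruggedness of the binding landscape; identically zero when
#' `eps_nnat = 0` (smooth-landscape limit).
#'
#' @param r Distance (Angstrom), >= 0.
#' @param eps_nnat Well depth (kcal/mol).
#' @param sigma_nnat Width (Angstrom).
#' @return Energy in kcal/mol, in `[-eps_nnat, 0]`.
#' @export
ligand_nonnative_term <- function(r, eps_nnat, sigma_nnat = 6.0) {
  if (any(r < 0)) stop("r must be >= 0")
  -eps_nnat * exp(-r^2 / (2 * sigma_nnat^2))
}

#' Excluded-volume pair potential
#'
#' `eps * (sigma / r)^12`: positive and monotonically decreasing in r.
#' @param r Distance (Angstrom), > 0.
#' @param sigma Diameter (Angstrom).
#' @param eps Prefactor (kcal/mol).
#' @return Energy in kcal/mol.
#' @export
excluded_volume_term <- function(r, sigma, eps = 1.0) {
  if (any(r <= 0)) stop("r must be > 0")
  eps * (sigma / r)^12
}

#' Numerical force check by central finite differences
#'
#' @param coords N x 3 coordinates.
#' @param topology A `cg_topology`.
#' @param params,restraints,mode Passed to [total_energy()].
#' @param h Step (Angstrom); default 1e-5.
#' @param idx Bead indices to check (default: all).
#' @return Maximum relative deviation between analytic and numerical force
#'   components (relative to the largest force magnitude).
#' @export
force_check <- function(coords, topology, params = NULL, restraints = list(),
                        mode = "mixed", h = 1e-5, idx = NULL) {
  X <- as.matrix(coords)
  E <- total_energy(X, topology, params, restraints, mode)
  Fa <- E$forces
  if (is.null(idx)) idx <- seq_len(nrow(X))
  fscale <- max(abs(Fa), 1)
  maxrel <- 0
  for (i in idx) {
    for (d in 1:3) {
      Xp <- X; Xp[i, d] <- Xp[i, d] + h
      Xm <- X; Xm[i, d] <- Xm[i, d] - h
      fn <- -(total_energy(Xp, topology, params, restraints, mode)$total -
              total_energy(Xm, topology, params, restraints, mode)$total) / (2 * h)
      maxrel <- max(maxrel, abs(fn - Fa[i, d]) / fscale)
    }
  }
  maxrel
}
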