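#' Simulation state
#'
#' Coordinates, velocities, global step index and RNG seed. The integrator's
#' noise stream is counter-based on (seed, global step, degree of freedom),
#' so a run continued from a serialized state is bit-identical to an
#' uninterrupted run with the same seed.
#'
#' @param coords N x 3 coordinates (Angstrom).
#' @param velocities N x 3 velocities (reduced units); default zero.
#' @param step_index Global step counter; default 0.
#' @param seed Integer RNG seed.
#' @return A `simulation_state`.
#' @export
simulation_state <- function(coords, velocities = NULL, step_index = 0,
                             seed = 1) {
  coords <- as.matrix(coords)
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3)
  if (!all(is.finite(coords)) || !all(is.finite(velocities)))
    stop("state must be finite")
  structure(list(coords = coords, velocities = as.matrix(velocities),
                 step_index = as.double(step_index), seed = as.double(seed)),
            class = "simulation_state")
}

#' Draw Maxwell-Boltzmann velocities for a state
#'
#' Deterministic given the state's seed and step index, so runs that
#' re-thermalize are still bit-reproducible.
#' @param state A `simulation_state`.
#' @param temperature Kelvin.
#' @return The state with thermal velocities.
#' @export
thermalize <- function(state, temperature = 300) {
  n <- nrow(state$coords)
  state$velocities <- with_seed(
    (round(abs(state$seed)) * 131L + round(state$step_index) %% 1009L) %%
      .Machine$integer.max,
    matrix(stats::rnorm(3 * n, sd = sqrt(kBT(temperature))), n, 3))
  state
}

#' Restraint specifications
#'
#' Constructors for the restraint types understood by the integrator and by
#' [total_energy()]. All are energy terms added to the potential:
#' \describe{
#'   \item{flat-bottom}{`(K/2) (d - r0)^2 H(d - r0)` on the centroid
#'     distance `d` between two bead groups; zero inside `r0`, C1 at the
#'     boundary. Used to keep a substrate inside the binding area.}
#'   \item{rmsd}{`(k/2) RMSD^2` toward a reference after best-fit
#'     superposition (targeted-MD style conformational restraint).}
#'   \item{tether}{independent harmonic distance restraints
#'     `(k/2)(d_ij - r0_ij)^2`; used to hold a ligand pose relative to the
#'     protein frame.}
#'   \item{posfix}{harmonic positional fix `(k/2)|x - x_ref|^2`.}
#'   \item{xi bias}{umbrella potential `(k/2)(xi - center)^2` on the
#'     conformational coordinate xi.}
#' }
#'
#' @param idxA,idxB Bead index vectors (1-based).
#' @param K,k Force constants (kcal/mol/A^2; for the xi bias kcal/mol).
#' @param r0 Flat-bottom radius (Angstrom).
#' @return A restraint specification list.
#' @export
flat_bottom_restraint_spec <- function(idxA, idxB, K, r0) {
  stopifnot(K >= 0)
  list(type = "flat_bottom", idxA = as.integer(idxA), idxB = as.integer(idxB),
       k = K, r0 = r0)
}

#' @rdname flat_bottom_restraint_spec
#' @param idx Bead indices the restraint acts on.
#' @param ref Reference coordinates (length(idx) x 3).
#' @export
rmsd_restraint_spec <- function(idx, ref, k) {
  list(type = "rmsd", idx = as.integer(idx), ref = as.matrix(ref), k = k)
}

#' @rdname flat_bottom_restraint_spec
#' @param i,j Paired bead indices.
#' @param r0_pairs Per-pair target distances (Angstrom).
#' @export
tether_restraint_spec <- function(i, j, r0_pairs, k) {
  m <- length(i)
  list(type = "tether", i = as.integer(i), j = as.integer(j),
       r0 = as.numeric(r0_pairs), k = rep_len(as.numeric(k), m))
}

#' @rdname flat_bottom_restraint_spec
#' @export
posfix_restraint_spec <- function(idx, ref, k) {
  list(type = "posfix", idx = as.integer(idx), ref = as.matrix(ref), k = k)
}

#' @rdname flat_bottom_restraint_spec
#' @param topology A `cg_topology` (for the reference structures).
#' @param center Umbrella centre on xi.
#' @param subset Optional protein-bead subset defining the coordinate
#'   (e.g. one mobile domain plus CORE); default all protein beads.
#' @export
xi_bias_spec <- function(topology, center, k, subset = NULL) {
  p <- if (is.null(subset)) topology$protein_idx else as.integer(subset)
  open_full <- topology$closed
  open_full[topology$protein_idx, ] <- topology$open
  ref_c <- topology$closed[p, , drop = FALSE]
  ref_o <- open_full[p, , drop = FALSE]
  list(type = "xi_bias", idx = as.integer(p),
       ref_closed = ref_c, ref_open = ref_o,
       k = k, center = center, rmsd_co = kabsch_rmsd(ref_c, ref_o))
}

#' Flat-bottom half-harmonic restraint energy
#'
#' `(K/2) (r - r0)^2 H(r - r0)` with `H` the Heaviside step function:
#' zero inside the flat bottom, harmonic outside, continuous first
#' derivative at `r = r0`. Distances are in nm here, mirroring the usual
#' reporting convention for this restraint; the simulation core applies the
#' same form in Angstrom.
#'
#' @param r Distance (nm).
#' @param K Force constant (kcal/mol/nm^2).
#' @param r0 Flat-bottom radius (nm).
#' @return Energy in kcal/mol.
#' @export
flat_bottom_restraint <- function(r, K = 23.9, r0 = 0.2) {
  if (K < 0) stop("K must be >= 0")
  ifelse(r > r0, 0.5 * K * (r - r0)^2, 0)
}

#' RMSD restraint energy and forces
#'
#' `(k/2) RMSD^2` toward a reference after best-fit superposition; the
#' gradient is taken through the superposition (rotation and translation
#' derivatives vanish at the optimum).
#' @param coords N x 3 coordinates.
#' @param reference N x 3 reference coordinates.
#' @param k Force constant (kcal/mol/A^2).
#' @param idx Optional subset of beads.
#' @return List with `energy`, `rmsd` and `forces` (N x 3).
#' @export
rmsd_restraint <- function(coords, reference, k, idx = NULL) {
  X <- as.matrix(coords)
  if (is.null(idx)) idx <- seq_len(nrow(X))
  fit <- kabsch_fit(X[idx, , drop = FALSE], as.matrix(reference))
  rmsd <- fit$rmsd
  Fm <- matrix(0, nrow(X), 3)
  diff <- sweep(X[idx, , drop = FALSE], 2, colMeans(X[idx, , drop = FALSE])) -
    sweep(fit$Y_aligned, 2, colMeans(fit$Y_aligned))
  Fm[idx, ] <- -k * diff / length(idx)
  list(energy = 0.5 * k * rmsd^2, rmsd = rmsd, forces = Fm)
}

#' One Langevin (BAOAB) step
#'
#' Single step of the BAOAB splitting of Langevin dynamics with unit bead
#' masses; with `gamma = 0` the scheme reduces to velocity Verlet.
#' @param state A `simulation_state`.
#' @param topology A `cg_topology`.
#' @param params Optional `cg_params` override.
#' @param restraints Restraint list.
#' @return The advanced `simulation_state`.
#' @export
langevin_step <- function(state, topology, params = NULL, restraints = list()) {
  run_trajectory(state, topology, n_steps = 1L, stride = 1L,
                 params = params, restraints = restraints)$final_state
}

#' Run a Langevin trajectory
#'
#' Propagates the system with the BAOAB integrator, storing coordinate
#' frames every `stride` steps together with kinetic and potential energy.
#' All randomness derives from `state$seed` and the global step index, so
#' identical inputs give bit-identical trajectories and a run may be split
#' and resumed without changing the result.
#'
#' @param state A `simulation_state`.
#' @param topology A `cg_topology`.
#' @param n_steps Number of steps (>= 0).
#' @param stride Frame recording interval; a run stores
#'   `floor(n_steps / stride) + 1` frames including the initial one.
#' @param params Optional `cg_params` override.
#' @param restraints Restraint list (see [flat_bottom_restraint_spec()]).
#' @param mode `"mixed"`, `"closed"` or `"open"` basin mode.
#' @return A `cg_trajectory`: frames (n_frames x 3N), energies, the final
#'   `simulation_state`, and full metadata (seed, parameters, restraints).
#' @export
run_trajectory <- function(state, topology, n_steps, stride = 10L,
                           params = NULL, restraints = list(),
                           mode = c("mixed", "closed", "open")) {
  mode <- match.arg(mode)
  p <- if (is.null(params)) topology$params else params
  m <- c(mixed = 0L, closed = 1L, open = 2L)[[mode]]
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (p$dt * p$gamma >= 1) stop("dt * gamma must be < 1")
  if (n_steps == 0L) {
    res <- list(frames = matrix(as.vector(t(state$coords)), 1),
                ekin = 0.5 * sum(state$velocities^2),
                epot = total_energy(state$coords, topology, p,
                                    restraints, mode)$total,
                coords = state$coords, vels = state$velocities)
    frame_steps <- 0
  } else {
    res <- run_cg_cpp(state$coords, state$velocities, topology$core,
                      p$eps_nnat, p$sigma_nnat,
                      as.numeric(p$deltaV), as.numeric(p$coupling_delta),
                      restraints, m, kBT(p$temperature), p$gamma, p$dt,
                      as.integer(n_steps), as.integer(stride),
                      state$seed, state$step_index)
    frame_steps <- seq(0, n_steps - n_steps %% stride, by = stride)
  }
  final <- simulation_state(res$coords, res$vels,
                            step_index = state$step_index + n_steps,
                            seed = state$seed)
  structure(list(frames = res$frames, ekin = res$ekin, epot = res$epot,
                 frame_steps = state$step_index + frame_steps,
                 dt = p$dt, stride = stride, seed = state$seed,
                 params = p, mode = mode, restraints = restraints,
                 final_state = final),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames, stride %d, dt %g tau, seed %d\n",
              nrow(x$frames), x$stride, x$dt, x$seed))
  invisible(x)
}

#' Extract one frame of a trajectory as an N x 3 matrix
#' @param traj A `cg_trajectory`.
#' @param frame Frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  matrix(traj$frames[frame, ], ncol = 3, byrow = TRUE)
}

#' Write trajectory observables to a TSV file
#' @param traj A `cg_trajectory`.
#' @param topology Matching topology.
#' @param file Output path.
#' @param ... Passed to [trajectory_observables()].
#' @return `file`, invisibly.
#' @export
write_observables_tsv <- function(traj, topology, file, ...) {
  obs <- trajectory_observables(traj, topology, ...)
  utils::write.table(obs, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
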