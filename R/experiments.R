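# End-to-end drivers for the three computational studies on the toy enzyme:
# substrate-binding MFPT vs landscape ruggedness (free vs closed-locked
# enzyme), domain-opening MFPT vs bound pose, and free-energy profiles.

#' Study-condition parameters for the toy enzyme
#'
#' The fixed conditions of the toy-enzyme studies: softened protein-contact
#' strength, basin offsets calibrated so the apo enzyme spends roughly 30%
#' of its time fully closed (see [calibrate_basin_offset()] and the methods
#' vignette), coupling Delta chosen so both domains switch on accessible
#' timescales, and the production time step.
#'
#' @param eps_nnat Non-native interaction strength (the study variable).
#' @return A `cg_params`.
#' @export
toy_study_params <- function(eps_nnat = 0) {
  # deltaV order follows the alphabetical interface components
  # (CORE-LID, CORE-NMP); values calibrated on the standard system so the
  # apo enzyme is genuinely bistable with a joint closed population near
  # 0.3; Delta = 4 keeps both domains switching on accessible timescales
  cg_params(eps_pp = 1.0, eps_nnat = eps_nnat, dt = 0.05,
            deltaV = c(-6.0, -7.1), coupling_delta = c(4, 4))
}

#' Build the standard toy-enzyme study system
#'
#' @param seed Generator seed.
#' @param eps_nnat Non-native strength.
#' @return List with `topology`, `system` (generator output) and derived
#'   helper indices (ligand beads, pocket floors, thresholds).
#' @export
toy_study_system <- function(seed = 1, eps_nnat = 0) {
  sys <- make_toy_enzyme(seed = seed)
  topo <- build_topology(sys$closed, sys$open,
                         params = toy_study_params(eps_nnat))
  lig <- list(AMP = which(topo$role == "ligand:AMP"),
              ATP = which(topo$role == "ligand:ATP"))
  # binding-area anchors: the CORE beads nearest each pocket centre
  anchors <- lapply(names(lig), function(kind) {
    ctr <- colMeans(topo$closed[lig[[kind]], , drop = FALSE])
    core <- which(topo$domain == "CORE" & topo$role == "protein")
    d <- sqrt(colSums((t(topo$closed[core, , drop = FALSE]) - ctr)^2))
    core[order(d)[1:10]]
  })
  names(anchors) <- names(lig)
  list(topology = topo, system = sys, ligand_idx = lig, anchors = anchors,
       thresholds = list(NMP = domain_thresholds(topo, "NMP"),
                         LID = domain_thresholds(topo, "LID")))
}

#' Binding-area restraints for both substrates
#'
#' Flat-bottom restraints on the centroid distance between each ligand and
#' the CORE beads lining its pocket, mirroring the weak restraint used to
#' keep substrates near the binding site during binding simulations.
#' @param sys Output of [toy_study_system()].
#' @param K Force constant (kcal/mol/A^2). Default 0.239
#'   (= 23.9 kcal/mol/nm^2).
#' @param r0 Flat-bottom radius (Angstrom). Default 8.
#' @return List of restraint specs.
#' @export
binding_area_restraints <- function(sys, K = 0.239, r0 = 6) {
  lapply(names(sys$ligand_idx), function(kind) {
    flat_bottom_restraint_spec(sys$ligand_idx[[kind]], sys$anchors[[kind]],
                               K = K, r0 = r0)
  })
}

# randomized encounter-pose start: open conformer with each ligand placed
# near its groove in a fully random orientation (random rotation plus a
# bounded translation, optionally lifted toward the pocket mouth) --
# an encounter complex inside the binding-area restraint
encounter_start <- function(sys, seed, lift = 0, magnitude = 2.5) {
  topo <- sys$topology
  X <- topo$closed
  X[topo$protein_idx, ] <- topo$open
  for (kind in names(sys$ligand_idx)) {
    lk <- sys$ligand_idx[[kind]]
    native <- topo$closed[lk, , drop = FALSE]
    lifted <- sweep(native, 2, c(0, 0, lift), "+")
    X[lk, ] <- perturb_pose(lifted, "random", magnitude = magnitude,
                            seed = seed + match(kind, names(sys$ligand_idx)),
                            open_coords = topo$open)
  }
  simulation_state(X, seed = seed)
}

# chunked propagation with binding detection. With `lock = TRUE` the
# enzyme is held at the closed conformation by an RMSD restraint for the
# whole run (the C variant). The first frame at which the protein reaches
# the closed structure (RMSD < 2 A) is recorded and its state returned, so
# the free run's first closing event can seed a closed-restrained run.
run_binding_trajectory <- function(sys, state, n_steps, lock = FALSE,
                                   chunk = 20000, stride = 100,
                                   q_threshold = 0.7, lock_k = 2,
                                   params = NULL, keep_frames = FALSE) {
  topo <- sys$topology
  p <- if (is.null(params)) topo$params else params
  res <- binding_area_restraints(sys)
  if (lock)
    res <- c(res, list(rmsd_restraint_spec(topo$protein_idx,
                                           topo$closed[topo$protein_idx, ,
                                                       drop = FALSE],
                                           lock_k)))
  t_done <- NA_real_
  obs_all <- NULL
  frames_all <- NULL
  first_closed_state <- NULL
  t_first_closed <- NA_real_
  steps_done <- 0
  while (steps_done < n_steps) {
    nn <- min(chunk, n_steps - steps_done)
    tr <- run_trajectory(state, topo, n_steps = nn, stride = stride,
                         params = p, restraints = res)
    state <- tr$final_state
    obs <- trajectory_observables(tr, topo, which = c("xi", "Q", "domains"))
    first <- if (is.null(obs_all)) 1L else 2L   # drop duplicated frame
    obs_all <- rbind(obs_all, obs[first:nrow(obs), , drop = FALSE])
    if (keep_frames)
      frames_all <- rbind(frames_all,
                          tr$frames[first:nrow(tr$frames), , drop = FALSE])
    steps_done <- steps_done + nn
    if (is.null(first_closed_state)) {
      hit <- which(obs$rmsd_closed < 2.0)[1]
      if (!is.na(hit)) {
        first_closed_state <- simulation_state(
          frame_coords(tr, hit), seed = state$seed,
          step_index = tr$frame_steps[hit])
        t_first_closed <- obs$time[hit]
      }
    }
    bs <- binding_success(obs_all, criteria = "Q", q_threshold = q_threshold)
    if (bs$success) { t_done <- bs$time; break }
  }
  list(obs = obs_all, frames = frames_all, success = !is.na(t_done),
       t_success = t_done, state = state,
       first_closed_state = first_closed_state,
       t_first_closed = t_first_closed)
}

# is every ligand centroid inside its binding area in this configuration?
ligands_in_binding_area <- function(sys, coords, radius = 10) {
  topo <- sys$topology
  all(vapply(names(sys$ligand_idx), function(kind) {
    ctr <- colMeans(coords[sys$ligand_idx[[kind]], , drop = FALSE])
    anch <- colMeans(coords[sys$anchors[[kind]], , drop = FALSE])
    sqrt(sum((ctr - anch)^2)) <= radius
  }, logical(1)))
}

#' Substrate-binding MFPT study (free vs closed-locked enzyme)
#'
#' For each non-native strength on the grid, runs independent binding
#' simulations of the free enzyme (`WT`) from randomized encounter poses at
#' the open conformation and detects native binding with the Q criterion
#' (both ligands simultaneously at Q >= 0.7). The closed-locked control
#' (`C`) continues each free run from its first closing event (the first
#' frame within 2 A RMSD of the closed structure) with the enzyme held
#' closed by an RMSD restraint; snapshots whose substrates lie outside the
#' binding area are excluded, mirroring the published protocol. Reports the
#' censored-MLE MFPT with bootstrap confidence intervals plus the number of
#' domain opening/closing cycles needed before binding in the free runs.
#'
#' @param eps_grid Non-native strengths (kcal/mol).
#' @param n_traj Independent trajectories per condition.
#' @param n_steps Maximum steps per trajectory (censoring horizon).
#' @param seed Base seed.
#' @param variants Model variants to run.
#' @param sys_seed Seed of the toy system build.
#' @param stride Observable stride (steps).
#' @return List with `mfpt` (tidy data frame: eps_nnat, variant, mfpt, ci,
#'   events) and `cycles` (per-domain mean cycles before binding, WT).
#' @export
experiment_binding_mfpt <- function(eps_grid = c(0.1, 0.5), n_traj = 12,
                                    n_steps = 150000, seed = 1,
                                    variants = c("WT", "C"), sys_seed = 1,
                                    stride = 100) {
  if (n_traj < 1) stop("n_traj must be >= 1")
  rows <- list(); cyc_rows <- list()
  for (eps in eps_grid) {
    sys <- toy_study_system(seed = sys_seed, eps_nnat = eps)
    th <- sys$thresholds
    wt_recs <- list(); c_recs <- list(); c_excluded <- 0L
    for (q in seq_len(n_traj)) {
      st <- encounter_start(sys, seed = seed + 811L * q + round(1e4 * eps))
      st <- thermalize(st, sys$topology$params$temperature)
      run <- run_binding_trajectory(sys, st, n_steps, lock = FALSE,
                                    stride = stride)
      dur <- if (run$success) run$t_success else run$obs$time[nrow(run$obs)]
      wt_recs[[length(wt_recs) + 1L]] <-
        list(duration = max(dur, stride * sys$topology$params$dt),
             event = run$success)
      tstop <- if (run$success) run$t_success else Inf
      for (d in c("NMP", "LID")) {
        cc <- count_conformation_cycles(
          run$obs[[paste0("R_", d, "_CORE")]], run$obs$time,
          close_at = th[[d]][["close_at"]], open_at = th[[d]][["open_at"]],
          t_stop = tstop)
        cyc_rows[[length(cyc_rows) + 1L]] <-
          data.frame(eps_nnat = eps, domain = d, traj = q,
                     success = run$success, cycles = cc$cycles,
                     openings = cc$n_openings)
      }
      # C variant: continue from the free run's first closing event with
      # the enzyme held closed; snapshots whose substrates sit outside the
      # binding area are excluded (they could never bind while closed),
      # and parents that never reach the closed structure contribute
      # right-censored records (no closure, hence no binding without
      # reopening)
      if ("C" %in% variants && is.null(run$first_closed_state)) {
        c_recs[[length(c_recs) + 1L]] <-
          list(duration = run$obs$time[nrow(run$obs)], event = FALSE)
      }
      if ("C" %in% variants && !is.null(run$first_closed_state)) {
        snap <- run$first_closed_state
        if (!ligands_in_binding_area(sys, snap$coords)) {
          c_excluded <- c_excluded + 1L
          next
        }
        snap <- thermalize(snap, sys$topology$params$temperature)
        snap$seed <- snap$seed + 5000L
        snap$step_index <- 0
        crun <- run_binding_trajectory(sys, snap, n_steps, lock = TRUE,
                                       stride = stride)
        cdur <- if (crun$success) crun$t_success else
          crun$obs$time[nrow(crun$obs)]
        # the C clock runs from the shared encounter start: time to the
        # first closing event plus the time under the closed lock
        c_recs[[length(c_recs) + 1L]] <-
          list(duration = run$t_first_closed +
                 max(cdur, stride * sys$topology$params$dt),
               event = crun$success)
      }
    }
    ests <- list(WT = if ("WT" %in% variants) wt_recs else NULL,
                 C = if ("C" %in% variants) c_recs else NULL)
    for (variant in variants) {
      recs <- ests[[variant]]
      if (!length(recs)) next
      est <- tryCatch(mfpt_mle(recs), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(est)) {
        # no events: the exponential-model 95% lower bound on the MFPT is
        # the total observation time divided by 3 (zero Poisson counts)
        data.frame(eps_nnat = eps, variant = variant, mfpt = Inf,
                   ci_lo = sum(vapply(recs, `[[`, numeric(1), "duration")) / 3,
                   ci_hi = Inf, n_events = 0L, n_traj = length(recs))
      } else {
        data.frame(eps_nnat = eps, variant = variant, mfpt = est$mfpt,
                   ci_lo = est$ci[1], ci_hi = est$ci[2],
                   n_events = est$n_events, n_traj = length(recs))
      }
    }
  }
  list(mfpt = do.call(rbind, rows),
       cycles = if (length(cyc_rows)) do.call(rbind, cyc_rows) else NULL)
}

# closed-state start with a chosen ligand pose, relaxed under a closed lock
prepared_closed_start <- function(sys, pose = c("apo", "native", "nonnative"),
                                  seed = 1, relax_steps = 20000,
                                  lock_k = 2) {
  pose <- match.arg(pose)
  topo <- sys$topology
  X <- topo$closed
  if (pose == "apo") {
    for (lk in sys$ligand_idx) X[lk, ] <- X[lk, ] + 500
  } else if (pose == "nonnative") {
    for (lk in sys$ligand_idx)
      X[lk, ] <- perturb_pose(topo$closed[lk, , drop = FALSE], "flip180")
  }
  st <- thermalize(simulation_state(X, seed = seed), topo$params$temperature)
  res <- list(rmsd_restraint_spec(topo$protein_idx,
                                  topo$closed[topo$protein_idx, , drop = FALSE],
                                  lock_k))
  if (pose != "apo") res <- c(res, binding_area_restraints(sys))
  tr <- run_trajectory(st, topo, n_steps = relax_steps, stride = relax_steps,
                       restraints = res)
  tr$final_state
}

#' Domain-opening MFPT study
#'
#' Measures the first-passage time from the closed state to domain opening
#' (interdomain distance exceeding the open hysteresis threshold) for the
#' apo enzyme and for substrates pre-bound in native or non-native
#' (flipped) poses. Start structures are relaxed at the closed state under
#' a conformational lock before release.
#'
#' @param eps_nnat Non-native strength during the opening runs.
#' @param poses Conditions to run.
#' @param n_traj Trajectories per condition.
#' @param n_steps Censoring horizon (steps).
#' @param relax_steps Closed-state relaxation length.
#' @param seed,sys_seed Seeds.
#' @param stride Observable stride.
#' @return Tidy data frame: pose, domain, mfpt, ci, events.
#' @export
experiment_opening_mfpt <- function(eps_nnat = 0.3,
                                    poses = c("apo", "native", "nonnative"),
                                    n_traj = 12, n_steps = 150000,
                                    relax_steps = 20000, seed = 1,
                                    sys_seed = 1, stride = 100) {
  sys <- toy_study_system(seed = sys_seed, eps_nnat = eps_nnat)
  topo <- sys$topology
  th <- sys$thresholds
  rows <- list()
  for (pose in poses) {
    recs <- list(NMP = list(), LID = list())
    for (q in seq_len(n_traj)) {
      st <- prepared_closed_start(sys, pose,
                                  seed = seed + 389L * q +
                                    1000L * match(pose, poses),
                                  relax_steps = relax_steps)
      res <- if (pose == "apo") list() else binding_area_restraints(sys)
      tr <- run_trajectory(st, topo, n_steps = n_steps, stride = stride,
                           restraints = res)
      obs <- trajectory_observables(tr, topo, which = "domains")
      for (d in c("NMP", "LID")) {
        col <- paste0("R_", d, "_CORE")
        recs[[d]][[q]] <- first_passage(obs, function(o)
          o[[col]] > th[[d]][["open_at"]])
      }
    }
    for (d in c("NMP", "LID")) {
      est <- try(mfpt_mle(recs[[d]]), silent = TRUE)
      if (inherits(est, "try-error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(pose = pose, domain = d, mfpt = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_, n_events = 0L,
                     n_traj = n_traj)
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(pose = pose, domain = d, mfpt = est$mfpt,
                     ci_lo = est$ci[1], ci_hi = est$ci[2],
                     n_events = est$n_events, n_traj = n_traj)
      }
    }
  }
  do.call(rbind, rows)
}

# stiff pose tethers holding a ligand pose relative to its pocket
pose_tether_restraints <- function(sys, poses, k = 5) {
  topo <- sys$topology
  out <- list()
  for (kind in names(sys$ligand_idx)) {
    lk <- sys$ligand_idx[[kind]]
    anch <- sys$anchors[[kind]]
    Xl <- poses[[kind]]
    ii <- integer(); jj <- integer(); rr <- numeric()
    for (a in seq_along(lk)) {
      for (b in seq_along(anch)) {
        ii <- c(ii, lk[a]); jj <- c(jj, anch[b])
        rr <- c(rr, sqrt(sum((Xl[a, ] - topo$closed[anch[b], ])^2)))
      }
    }
    out[[kind]] <- tether_restraint_spec(ii, jj, rr, k)
  }
  out
}

#' Free-energy profiles of domain opening for native vs non-native poses
#'
#' Umbrella sampling along the conformational coordinate xi of one
#' substrate-binding domain (its cap plus the CORE), with the substrates
#' tethered in place: the profiled substrate either in its native pose or
#' flipped into a non-native one (the other substrate stays native,
#' mirroring the published setup). MBAR reweighting yields the two
#' profiles and their closed-to-open barriers.
#'
#' @param eps_nnat Non-native strength. Default 0.3 (moderate ruggedness,
#'   where the steric destabilisation by the mis-bound pose dominates the
#'   non-native attraction).
#' @param domain Profiled domain (`"NMP"` profiles AMP binding). Default
#'   `"NMP"`.
#' @param centers Umbrella centres.
#' @param k Umbrella force constant (kcal/mol). Default 836.
#' @param steps_per_window Steps per window.
#' @param seed,sys_seed Seeds.
#' @param n_boot Bootstrap replicates for the profile uncertainties.
#' @return List with `profiles` (named list of `free_energy_profile`s) and
#'   `barriers` (closed-to-open barrier per pose, kBT).
#' @export
experiment_fes <- function(eps_nnat = 0.3, domain = "NMP",
                           centers = umbrella_centers(),
                           k = 836, steps_per_window = 8000, seed = 1,
                           sys_seed = 1, n_boot = 20) {
  sys <- toy_study_system(seed = sys_seed, eps_nnat = eps_nnat)
  topo <- sys$topology
  kind <- if (domain == "NMP") "AMP" else "ATP"
  subset <- which(topo$role == "protein" &
                    topo$domain %in% c("CORE", domain))
  profiles <- list(); barriers <- c()
  for (pose in c("native", "nonnative")) {
    poses <- lapply(names(sys$ligand_idx), function(kd) {
      lk <- sys$ligand_idx[[kd]]
      if (pose == "nonnative" && kd == kind)
        perturb_pose(topo$closed[lk, , drop = FALSE], "flip180")
      else topo$closed[lk, , drop = FALSE]
    })
    names(poses) <- names(sys$ligand_idx)
    tethers <- pose_tether_restraints(sys, poses)
    # directional sweeps start from the pose-consistent closed/open
    # structures and walk the window ladder
    Xc <- topo$closed
    Xo <- topo$closed
    Xo[topo$protein_idx, ] <- topo$open
    for (kd in names(poses)) {
      Xc[sys$ligand_idx[[kd]], ] <- poses[[kd]]
      Xo[sys$ligand_idx[[kd]], ] <- poses[[kd]]
    }
    wins <- run_umbrella(topo, centers = centers, k = k,
                         steps_per_window = steps_per_window,
                         subset = subset, seeding = "sweep",
                         sweep_starts = list(closed = Xc, open = Xo),
                         restraints = unname(tethers),
                         seed = seed + ifelse(pose == "native", 0L, 5000L))
    prof <- reweight_pmf(wins, temperature = topo$params$temperature,
                         n_boot = n_boot)
    profiles[[pose]] <- prof
    barriers[pose] <- barrier_height(prof, basinA = c(-1.2, -0.4),
                                     basinB = c(0.4, 1.2))
  }
  list(profiles = profiles, barriers = barriers)
}

#' Write an experiment report to disk
#'
#' Flat TSV tables plus a JSON manifest (seeds, parameters, package
#' version) sufficient to rerun the experiment bit-identically.
#' @param result Experiment output (list of data frames / vectors).
#' @param dir Output directory (created if needed).
#' @param name Experiment name.
#' @param config Named list of the call's configuration to record.
#' @return The directory, invisibly.
#' @export
write_experiment_report <- function(result, dir, name, config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (is.data.frame(obj)) {
      utils::write.table(obj, file.path(dir, paste0(name, "_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  manifest <- list(name = name, config = config,
                   package_version = as.character(utils::packageVersion("cgbind")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
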