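#' One cycle of parallel cascade selection (PaCS)
#'
#' Runs `n_replicas` short unbiased trajectories from the seed states, pools
#' every sampled snapshot together with the seeds themselves (incumbent
#' retention, so the best RMSD is non-increasing over cycles), ranks the
#' pool by best-fit RMSD of the protein beads to the target reference, and
#' returns the top `n_replicas` snapshots as the next seeds. The potential
#' is never modified: every snapshot is a valid unbiased-dynamics state.
#'
#' @param seeds List of `simulation_state`s (recycled to `n_replicas`).
#' @param topology A `cg_topology`.
#' @param target_ref Protein-bead reference coordinates (n_prot x 3).
#' @param n_replicas Replicas per cycle. Default 10.
#' @param steps_per_replica Steps per short trajectory. Default 2000.
#' @param stride Snapshot stride. Default 100.
#' @param params,restraints Passed to [run_trajectory()].
#' @param seed Integer; seeds the replica RNG streams.
#' @return List with `seeds` (new seed states), `best_rmsd`, and
#'   `pool_rmsd` (all ranked RMSDs).
#' @export
pacs_cycle <- function(seeds, topology, target_ref, n_replicas = 10,
                       steps_per_replica = 2000, stride = 100,
                       params = NULL, restraints = list(), seed = 1) {
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  p <- if (is.null(params)) topology$params else params
  pidx <- topology$protein_idx
  pool_states <- list()
  pool_rmsd <- numeric()
  # incumbents compete with the new snapshots
  for (s in seeds) {
    pool_states[[length(pool_states) + 1L]] <- s
    pool_rmsd <- c(pool_rmsd,
                   kabsch_rmsd(s$coords[pidx, , drop = FALSE], target_ref))
  }
  for (r in seq_len(n_replicas)) {
    st <- seeds[[(r - 1L) %% length(seeds) + 1L]]
    st <- thermalize(st, p$temperature)
    st$seed <- seed * 1000 + r
    st$step_index <- 0
    tr <- run_trajectory(st, topology, n_steps = steps_per_replica,
                         stride = stride, params = p,
                         restraints = restraints)
    rm <- rmsd_frames_cpp(tr$frames, target_ref, pidx)
    for (f in seq_along(rm)[-1]) {
      pool_states[[length(pool_states) + 1L]] <-
        simulation_state(frame_coords(tr, f), seed = st$seed,
                         step_index = tr$frame_steps[f])
      pool_rmsd <- c(pool_rmsd, rm[f])
    }
  }
  ord <- order(pool_rmsd)
  sel <- ord[seq_len(min(n_replicas, length(ord)))]
  list(seeds = pool_states[sel], best_rmsd = pool_rmsd[sel[1]],
       pool_rmsd = pool_rmsd[ord])
}

#' Run a full PaCS simulation toward a target structure
#'
#' Repeats [pacs_cycle()] up to `n_cycles`, recording the best snapshot per
#' cycle. If a cycle fails to improve on the incumbent best RMSD (a stall),
#' the seeds are relaxed by a segment of conventional dynamics before the
#' next cycle. Stops early when `rmsd_stop` is reached.
#'
#' @inheritParams pacs_cycle
#' @param start A `simulation_state`.
#' @param n_cycles Maximum cycles.
#' @param rmsd_stop Convergence threshold (Angstrom); default 1.5.
#' @param relax_steps Relaxation-segment length on stall. Default
#'   `steps_per_replica`.
#' @return List with `best_states` (best state per cycle), `best_rmsd`
#'   (non-increasing series), `n_cycles_run`, `converged`, `stalls`.
#' @export
pacs_run <- function(start, topology, target_ref, n_cycles = 50,
                     n_replicas = 10, steps_per_replica = 2000, stride = 100,
                     rmsd_stop = 1.5, relax_steps = NULL, params = NULL,
                     restraints = list(), seed = 1) {
  p <- if (is.null(params)) topology$params else params
  if (is.null(relax_steps)) relax_steps <- steps_per_replica
  seeds <- list(start)
  best <- Inf
  best_series <- numeric()
  best_states <- list()
  stalls <- 0L
  for (cy in seq_len(n_cycles)) {
    res <- pacs_cycle(seeds, topology, target_ref, n_replicas,
                      steps_per_replica, stride, params = p,
                      restraints = restraints, seed = seed + 7919L * cy)
    if (res$best_rmsd >= best - 1e-9 && is.finite(best)) {
      stalls <- stalls + 1L
      # relax: conventional dynamics from the current seeds
      seeds <- lapply(seq_along(res$seeds), function(q) {
        st <- thermalize(res$seeds[[q]], p$temperature)
        st$seed <- seed + 104729L * cy + q
        st$step_index <- 0
        run_trajectory(st, topology, n_steps = relax_steps, stride = relax_steps,
                       params = p, restraints = restraints)$final_state
      })
    } else {
      seeds <- res$seeds
    }
    best <- min(best, res$best_rmsd)
    best_series <- c(best_series, best)
    best_states[[cy]] <- res$seeds[[1]]
    if (best <= rmsd_stop) break
  }
  list(best_states = best_states, best_rmsd = best_series,
       n_cycles_run = length(best_series), converged = best <= rmsd_stop,
       stalls = stalls)
}

#' Targeted MD: dynamics under an RMSD restraint toward a reference
#'
#' @param start A `simulation_state`.
#' @param topology A `cg_topology`.
#' @param reference Protein-bead reference coordinates.
#' @param k Restraint constant (kcal/mol/A^2); with `k = 0` the run is
#'   identical to unbiased dynamics with the same seed.
#' @param n_steps,stride,params,restraints As [run_trajectory()].
#' @return A `cg_trajectory`.
#' @export
targeted_md <- function(start, topology, reference, k, n_steps,
                        stride = 100, params = NULL, restraints = list()) {
  res <- restraints
  if (k > 0)
    res <- c(res, list(rmsd_restraint_spec(topology$protein_idx, reference, k)))
  run_trajectory(start, topology, n_steps = n_steps, stride = stride,
                 params = params, restraints = res)
}

#' Umbrella-sampling window grid
#' @param from,to,by Window centres (default -1 to 1 by 0.05: 41 windows).
#' @return Numeric vector of centres.
#' @export
umbrella_centers <- function(from = -1, to = 1, by = 0.05) {
  seq(from, to, by = by)
}

#' Run umbrella sampling along the conformational coordinate xi
#'
#' Applies the harmonic bias `(k/2)(xi - center)^2` per window and samples
#' xi; the first `discard_fraction` of each window is dropped. Initial
#' structures per window may be supplied (e.g. frames of a PaCS run nearest
#' each centre, from both transition directions for the central windows);
#' by default each window starts from the closed or open reference
#' according to the sign of its centre.
#'
#' @param topology A `cg_topology`.
#' @param centers Window centres (see [umbrella_centers()]).
#' @param k Bias force constant (kcal/mol). Default 836.
#' @param steps_per_window Sampling steps per window.
#' @param discard_fraction Leading fraction discarded. Default 0.25.
#' @param starts Optional list of `simulation_state`s, one per window
#'   (overrides `seeding`).
#' @param subset Optional protein-bead subset defining the coordinate
#'   (e.g. one mobile domain plus CORE).
#' @param sweep_starts Optional list with `closed` and `open` full-system
#'   coordinate matrices used as sweep endpoints (e.g. with non-native
#'   ligand poses injected).
#' @param seeding `"sweep"` (default): two sequential sweeps, one walking
#'   the windows closed-to-open starting from the closed structure and one
#'   open-to-closed from the open structure, each window seeded by the
#'   previous window's final state; both sweeps' samples are pooled per
#'   window, so the two transition directions both contribute (their
#'   disagreement shows up in the bootstrap uncertainty). `"reference"`:
#'   every window starts from the nearest reference structure.
#' @param params,restraints,stride,seed As [run_trajectory()].
#' @return List of `umbrella_window` objects: `center`, `k`, `samples`
#'   (retained xi series), `all_samples`, `discard_fraction`.
#' @export
run_umbrella <- function(topology, centers = umbrella_centers(), k = 836,
                         steps_per_window = 20000, discard_fraction = 0.25,
                         starts = NULL, subset = NULL,
                         seeding = c("sweep", "reference"),
                         sweep_starts = NULL, params = NULL,
                         restraints = list(), stride = 20, seed = 1) {
  if (is.unsorted(centers, strictly = TRUE)) stop("centers must be strictly increasing")
  seeding <- match.arg(seeding)
  p <- if (is.null(params)) topology$params else params
  pidx <- topology$protein_idx
  closed_full <- topology$closed
  open_full <- topology$closed
  open_full[pidx, ] <- topology$open
  if (!is.null(sweep_starts)) {
    closed_full <- sweep_starts$closed
    open_full <- sweep_starts$open
  }
  bias0 <- xi_bias_spec(topology, center = 0, k = k, subset = subset)

  one_window <- function(st, cen, wseed) {
    st$seed <- wseed
    st <- thermalize(st, p$temperature)
    bias <- bias0
    bias$center <- cen
    tr <- run_trajectory(st, topology, n_steps = steps_per_window,
                         stride = stride, params = p,
                         restraints = c(restraints, list(bias)))
    rc <- rmsd_frames_cpp(tr$frames, bias$ref_closed, bias$idx)
    ro <- rmsd_frames_cpp(tr$frames, bias$ref_open, bias$idx)
    xs <- (rc - ro) / bias$rmsd_co
    keep <- seq_along(xs) > discard_fraction * length(xs)
    list(samples = xs[keep], all = xs, state = tr$final_state)
  }

  nw <- length(centers)
  samples <- vector("list", nw)
  all_samples <- vector("list", nw)
  if (!is.null(starts)) {
    for (w in seq_len(nw)) {
      r <- one_window(starts[[w]], centers[w], seed + w)
      samples[[w]] <- r$samples; all_samples[[w]] <- r$all
    }
  } else if (seeding == "reference") {
    for (w in seq_len(nw)) {
      st <- simulation_state(if (centers[w] <= 0) closed_full else open_full,
                             seed = seed + w)
      r <- one_window(st, centers[w], seed + w)
      samples[[w]] <- r$samples; all_samples[[w]] <- r$all
    }
  } else {
    sweeps <- list(list(order = seq_len(nw), X0 = closed_full, off = 0L),
                   list(order = rev(seq_len(nw)), X0 = open_full,
                        off = 1000L))
    for (sw in sweeps) {
      st <- simulation_state(sw$X0, seed = seed)
      for (w in sw$order) {
        r <- one_window(st, centers[w], seed + sw$off + w)
        samples[[w]] <- c(samples[[w]], r$samples)
        all_samples[[w]] <- c(all_samples[[w]], r$all)
        st <- r$state
      }
    }
  }
  lapply(seq_len(nw), function(w) {
    structure(list(center = centers[w], k = k, samples = samples[[w]],
                   all_samples = all_samples[[w]],
                   discard_fraction = discard_fraction),
              class = "umbrella_window")
  })
}

#' Multistate (MBAR) reweighting of umbrella windows to a free-energy profile
#'
#' Solves the self-consistent multistate reweighting equations for the
#' window free energies to relative tolerance `tol`, then histograms the
#' unbiased weights into a profile along the sampled coordinate. Bin
#' uncertainties come from a block bootstrap over each window's trajectory.
#'
#' @param windows List of `umbrella_window`s (>= 2 with overlap, or a
#'   single window for direct inversion).
#' @param temperature Kelvin.
#' @param bins Number of histogram bins (default 50) or a vector of breaks.
#' @param tol Self-consistency tolerance on the reduced free energies.
#' @param n_boot Bootstrap replicates for the uncertainty band. Default 20.
#' @param n_blocks Blocks per window for the bootstrap. Default 10.
#' @return A `free_energy_profile`: data frame with `x` (bin centres),
#'   `F` (kBT, minimum shifted to zero), `err` (bootstrap standard
#'   deviation), plus attributes `f_k` (window free energies) and
#'   `overlap` (sample counts per window).
#' @export
reweight_pmf <- function(windows, temperature = 300, bins = 50, tol = 1e-7,
                         n_boot = 20, n_blocks = 10) {
  kT <- kBT(temperature)
  xs <- unlist(lapply(windows, `[[`, "samples"))
  if (length(bins) == 1L) {
    breaks <- seq(min(xs), max(xs), length.out = bins + 1L)
  } else breaks <- bins
  solve_once <- function(win_samples) {
    x <- unlist(win_samples)
    N_k <- lengths(win_samples)
    K <- length(win_samples)
    # reduced bias energies of every sample in every window
    U <- vapply(seq_len(K), function(kk) {
      0.5 * windows[[kk]]$k * (x - windows[[kk]]$center)^2 / kT
    }, numeric(length(x)))
    # window free energies minimise the convex multistate objective
    # F(f) = sum_n log sum_k N_k exp(f_k - u_nk) - sum_k N_k f_k
    # (f_1 pinned to 0); BFGS with the analytic gradient converges far
    # faster than the textbook fixed-point iteration when overlap is thin
    logden_of <- function(f) {
      A <- sweep(-U, 2, f + log(N_k), "+")
      amax <- apply(A, 1, max)
      list(A = A, amax = amax,
           logden = amax + log(rowSums(exp(A - amax))))
    }
    obj <- function(fr) {
      f <- c(0, fr)
      ld <- logden_of(f)
      sum(ld$logden) - sum(N_k * f)
    }
    grad <- function(fr) {
      f <- c(0, fr)
      ld <- logden_of(f)
      W <- exp(ld$A - ld$logden)      # n x K membership weights
      (colSums(W) - N_k)[-1]
    }
    fr <- if (K > 1) stats::optim(numeric(K - 1), obj, grad, method = "BFGS",
                                  control = list(maxit = 500,
                                                 reltol = 1e-14))$par
          else numeric(0)
    f <- c(0, fr)
    # polish with self-consistent sweeps to the requested tolerance
    for (it in 1:50) {
      ld <- logden_of(f)
      fnew <- vapply(seq_len(K), function(kk) {
        v <- -U[, kk] - ld$logden
        m <- max(v)
        -(m + log(sum(exp(v - m))))
      }, numeric(1))
      fnew <- fnew - fnew[1]
      delta <- max(abs(fnew - f))
      f <- fnew
      if (delta < tol) break
    }
    ld <- logden_of(f)
    logw <- -ld$logden                 # unbiased log-weights
    bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
    Fb <- rep(NA_real_, length(breaks) - 1L)
    for (b in unique(bin[!is.na(bin)])) {
      v <- logw[which(bin == b)]
      m <- max(v)
      Fb[b] <- -(m + log(sum(exp(v - m))))
    }
    list(F = Fb - min(Fb, na.rm = TRUE), f = f)
  }
  overlap_check(windows)
  samples <- lapply(windows, `[[`, "samples")
  full <- solve_once(samples)
  F0 <- full$F
  boot <- replicate(n_boot, {
    res <- lapply(samples, function(s) {
      nb <- min(n_blocks, length(s))
      blocks <- split(s, cut(seq_along(s), nb, labels = FALSE))
      unlist(blocks[sample.int(nb, replace = TRUE)], use.names = FALSE)
    })
    solve_once(res)$F
  })
  err <- apply(boot, 1, stats::sd, na.rm = TRUE)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(data.frame(x = mid, F = F0, err = err),
            class = c("free_energy_profile", "data.frame"),
            f_k = full$f, n_samples = lengths(samples))
}

overlap_check <- function(windows) {
  if (length(windows) < 2L) return(invisible(TRUE))
  rngs <- lapply(windows, function(w) range(w$samples))
  for (q in seq_len(length(windows) - 1L)) {
    if (rngs[[q]][2] < rngs[[q + 1]][1]) {
      warning(sprintf("windows %d and %d do not overlap (ranges %.3f-%.3f vs %.3f-%.3f)",
                      q, q + 1, rngs[[q]][1], rngs[[q]][2],
                      rngs[[q + 1]][1], rngs[[q + 1]][2]))
    }
  }
  invisible(TRUE)
}

#' Two-dimensional free-energy landscape from unbiased sampling
#'
#' `F = -kBT ln(normalised 2D histogram)`, shifted so the minimum is zero;
#' empty bins are `NA`.
#'
#' @param a,b Coordinate samples (equal length).
#' @param bins Bins per axis (default 30) or list of two break vectors.
#' @param temperature Kelvin (profile is reported in kBT units).
#' @return List with `x`, `y` (bin centres) and `F` (matrix, kBT).
#' @export
pmf_2d <- function(a, b, bins = 30, temperature = 300) {
  if (length(a) != length(b)) stop("coordinate series differ in length")
  if (is.list(bins)) { bx <- bins[[1]]; by <- bins[[2]] }
  else {
    bx <- seq(min(a), max(a), length.out = bins + 1L)
    by <- seq(min(b), max(b), length.out = bins + 1L)
  }
  ia <- cut(a, bx, include.lowest = TRUE, labels = FALSE)
  ib <- cut(b, by, include.lowest = TRUE, labels = FALSE)
  H <- matrix(0, length(bx) - 1L, length(by) - 1L)
  for (q in seq_along(ia)) if (!is.na(ia[q]) && !is.na(ib[q]))
    H[ia[q], ib[q]] <- H[ia[q], ib[q]] + 1
  F <- -log(H / sum(H))
  F[!is.finite(F)] <- NA
  F <- F - min(F, na.rm = TRUE)
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2, F = F)
}

#' Barrier height between two basins of a free-energy profile
#'
#' 1D: the maximum of the profile between the two basin minima, minus the
#' starting-basin minimum (zero or negative-free profiles give a barrier of
#' 0 -- a downhill process). 2D: the minimax path value on the bin
#' adjacency graph (4-connected), i.e. the lowest possible highest point of
#' any path connecting the basins, minus the starting minimum.
#'
#' @param profile A `free_energy_profile` data frame (1D) or the list
#'   returned by [pmf_2d()] (2D).
#' @param basinA,basinB 1D: ranges `c(lo, hi)` on `x`. 2D: lists
#'   `list(x = c(lo, hi), y = c(lo, hi))`.
#' @return Barrier in kBT (>= 0), measured from basin A's minimum.
#' @export
barrier_height <- function(profile, basinA, basinB) {
  if (is.data.frame(profile)) {
    x <- profile$x; F <- profile$F
    selA <- which(x >= basinA[1] & x <= basinA[2] & !is.na(F))
    selB <- which(x >= basinB[1] & x <= basinB[2] & !is.na(F))
    if (!length(selA) || !length(selB)) stop("basin outside profile support")
    iA <- selA[which.min(F[selA])]
    iB <- selB[which.min(F[selB])]
    seg <- F[min(iA, iB):max(iA, iB)]
    max(0, max(seg, na.rm = TRUE) - F[iA])
  } else {
    Fm <- profile$F
    nx <- nrow(Fm); ny <- ncol(Fm)
    inA <- outer(profile$x >= basinA$x[1] & profile$x <= basinA$x[2],
                 profile$y >= basinA$y[1] & profile$y <= basinA$y[2], "&")
    inB <- outer(profile$x >= basinB$x[1] & profile$x <= basinB$x[2],
                 profile$y >= basinB$y[1] & profile$y <= basinB$y[2], "&")
    inA[is.na(Fm)] <- FALSE; inB[is.na(Fm)] <- FALSE
    if (!any(inA) || !any(inB)) stop("basin outside landscape support")
    FA <- min(Fm[inA]);
    # bottleneck (minimax) value via threshold search over sorted levels
    lv <- sort(unique(Fm[!is.na(Fm)]))
    lo <- 1L; hi <- length(lv)
    reach <- function(thr) {
      ok <- !is.na(Fm) & Fm <= thr
      if (!any(inA & ok)) return(FALSE)
      visited <- inA & ok
      repeat {
        grown <- visited
        grown[-1, ] <- grown[-1, ] | visited[-nx, ]
        grown[-nx, ] <- grown[-nx, ] | visited[-1, ]
        grown[, -1] <- grown[, -1] | visited[, -ny]
        grown[, -ny] <- grown[, -ny] | visited[, -1]
        grown <- grown & ok
        if (all(grown == visited)) break
        visited <- grown
      }
      any(visited & inB)
    }
    if (!reach(lv[hi])) stop("basins are not connected on the sampled support")
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (reach(lv[mid])) hi <- mid else lo <- mid + 1L
    }
    max(0, lv[lo] - FA)
  }
}

#' Write a free-energy profile as TSV
#' @param profile A `free_energy_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  utils::write.table(profile, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
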