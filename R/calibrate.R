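#' Measure apo conformational populations
#'
#' Runs unbiased apo Langevin trajectories (ligands removed) and reports the
#' fraction of frames each mobile domain spends closed (interdomain distance
#' below the closed/open midpoint) plus the joint closed population.
#'
#' @param topology A `cg_topology`.
#' @param params Optional `cg_params` override.
#' @param n_steps Steps per replicate. Default 4e5.
#' @param n_rep Replicates (different seeds). Default 2.
#' @param seed Base seed.
#' @param discard Leading fraction of each run discarded. Default 0.2.
#' @return List with `per_domain` (named closed fractions), `joint`,
#'   `transitions` (per domain) and the threshold midpoints used.
#' @export
apo_populations <- function(topology, params = NULL, n_steps = 4e5,
                            n_rep = 2, seed = 1, discard = 0.2) {
  p <- if (is.null(params)) topology$params else params
  lk <- which(startsWith(topology$role, "ligand"))
  Xapo <- topology$closed
  if (length(lk)) Xapo[lk, ] <- Xapo[lk, ] + 500
  doms <- setdiff(unique(stats::na.omit(topology$domain)), "CORE")
  Xo <- topology$closed
  Xo[topology$protein_idx, ] <- topology$open
  mids <- vapply(doms, function(d) {
    (interdomain_distance(topology$closed, topology, d, "CORE") +
       interdomain_distance(Xo, topology, d, "CORE")) / 2
  }, numeric(1))
  closed_frac <- matrix(0, n_rep, length(doms), dimnames = list(NULL, doms))
  joint <- numeric(n_rep)
  trans <- stats::setNames(numeric(length(doms)), doms)
  for (r in seq_len(n_rep)) {
    st <- thermalize(simulation_state(Xapo, seed = seed + 17L * r),
                     p$temperature)
    tr <- run_trajectory(st, topology, n_steps = n_steps, stride = 1000,
                         params = p)
    obs <- trajectory_observables(tr, topology, which = "domains")
    keep <- seq_len(nrow(obs)) > discard * nrow(obs)
    cl <- vapply(doms, function(d) {
      obs[[paste0("R_", d, "_CORE")]][keep] < mids[[d]]
    }, logical(sum(keep)))
    closed_frac[r, ] <- colMeans(cl)
    joint[r] <- mean(rowSums(cl) == length(doms))
    trans <- trans + vapply(doms, function(d) {
      sum(diff(cl[, d]) != 0)
    }, numeric(1))
  }
  list(per_domain = colMeans(closed_frac), joint = mean(joint),
       transitions = trans, midpoints = mids)
}

#' Calibrate the double-basin energy offsets
#'
#' Bisections each interface's open-basin offset `deltaV` until the apo
#' closed population of its mobile domain matches `target_per_domain`
#' (default `sqrt(0.3)` per domain so that the joint closed population of a
#' two-domain enzyme is about 0.3, the experimentally known apo value). The
#' coupling `Delta` is held fixed; it sets the switching barrier and hence
#' the transition rate, not the equilibrium.
#'
#' @param topology A `cg_topology`.
#' @param target_per_domain Closed fraction per mobile domain.
#' @param lower,upper Bracketing deltaV values (open basin offsets,
#'   kcal/mol; more negative favours open).
#' @param coupling Delta per interface. Default 2.
#' @param n_iter Bisection iterations. Default 4.
#' @param n_steps,n_rep,seed Passed to [apo_populations()].
#' @return A `cg_params` with calibrated `deltaV` (and the measurement
#'   history as attribute `"history"`).
#' @export
calibrate_basin_offset <- function(topology, target_per_domain = sqrt(0.3),
                                   lower = -8, upper = 0, coupling = 2,
                                   n_iter = 4, n_steps = 4e5, n_rep = 2,
                                   seed = 1) {
  ncomp <- length(topology$components)
  doms <- vapply(strsplit(topology$components, "-"), function(s) {
    setdiff(s, "CORE")[1]
  }, character(1))
  lo <- rep(lower, ncomp); hi <- rep(upper, ncomp)
  p <- update_params(topology$params, deltaV = (lo + hi) / 2,
                     coupling_delta = rep(coupling, ncomp))
  hist <- list()
  for (it in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    p <- update_params(p, deltaV = mid)
    pop <- apo_populations(topology, p, n_steps = n_steps, n_rep = n_rep,
                           seed = seed + 100L * it)
    hist[[it]] <- list(deltaV = mid, pop = pop)
    for (c in seq_len(ncomp)) {
      f <- pop$per_domain[[doms[c]]]
      # more negative deltaV opens the domain more
      if (f > target_per_domain) hi[c] <- mid[c] else lo[c] <- mid[c]
    }
  }
  p <- update_params(p, deltaV = (lo + hi) / 2)
  attr(p, "history") <- hist
  p
}
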