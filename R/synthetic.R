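# Synthetic two-conformation test systems.
#
# The generated protein is a "clamshell": a rigid CORE (pocket floor, inner
# ridge, outer wall, end walls, optional sub-floor) and a mobile two-row cap
# that closes over a ligand groove. The open conformer is the closed one with
# the cap rigidly rotated about a hinge axis running along the outer-wall bead
# row, so domain opening genuinely uncovers the groove: a three-sided cleft
# (floor, ridge, cap) whose top side is removed by the hinge motion.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rotate points about an axis through `origin` with unit direction `dir`
rotate_about_axis <- function(X, origin, dir, angle) {
  dir <- dir / sqrt(sum(dir^2))
  K <- matrix(c(0, -dir[3], dir[2], dir[3], 0, -dir[1], -dir[2], dir[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(sweep(X, 2, origin) %*% t(R), 2, origin, "+")
}

clamshell_layout <- function(ny, n_subfloor, x0 = 0, mirror = 1,
                             include_ends = TRUE) {
  ys <- seq(-3 * (ny - 1) / 2, 3 * (ny - 1) / 2, length.out = ny)
  ymax <- max(ys)
  # chain order: subfloor -> ridge -> end wall A -> floor (serpentine) ->
  # end wall B -> outer wall -> cap; consecutive sections adjoin in space
  # geometry notes: CORE-side clearances keep every protein-ligand distance
  # near or above the excluded-volume diameter (5 A); the cap carries two
  # "lip" rows that seal the wall-side and ridge-side channels of the
  # closed pocket (so a mis-bound ligand cannot slip out sideways while
  # closed) and swing away with the cap on opening. Lip positions are
  # chosen so their distance to every fixed bead grows monotonically during
  # the hinge swing (no mid-swing steric squeeze).
  sub <- if (n_subfloor > 0) {
    yy <- seq(-ymax, ymax, length.out = n_subfloor)
    cbind(2 * rep_len(c(-1, 1), n_subfloor), yy, -4)
  } else NULL
  ridge <- cbind(6.5, rev(ys), 5.2)
  end_a <- rbind(c(0.25, -(ymax + 5), 3.2), c(-0.25, -(ymax + 5), 7.0))
  floor_ <- rbind(cbind(4, ys, -0.5), cbind(0, rev(ys), -0.5),
                  cbind(-4, ys, -0.5))
  end_b <- rbind(c(0.25, ymax + 5, 3.2), c(-0.25, ymax + 5, 7.0))
  wall <- cbind(-6, rev(ys), 4.5)
  # cap roof at 10.5 so a mis-registered ligand still fits underneath with
  # only mild strain (a closable high-energy intermediate); the lips keep
  # sealing the side channels
  cap <- rbind(cbind(-5.4, ys, 7.5),    # wall-side lip
               cbind(-2.5, rev(ys), 10.5),
               cbind(2.5, ys, 10.5),
               cbind(5.4, rev(ys), 7.9))  # ridge-side lip
  if (!include_ends) end_a <- end_b <- NULL
  sections <- list(subfloor = sub, ridge = ridge, enda = end_a,
                   floor = floor_, endb = end_b, wall = wall, cap = cap)
  X <- do.call(rbind, sections)
  X[, 1] <- mirror * X[, 1] + x0
  n_cap <- nrow(cap)
  list(coords = X, n = nrow(X), cap_idx = (nrow(X) - n_cap + 1):nrow(X),
       wall_idx = (nrow(X) - n_cap - ny + 1):(nrow(X) - n_cap),
       hinge_origin = c(mirror * -6 + x0, 0, 4.5),
       hinge_dir = c(0, 1, 0), mirror = mirror,
       pocket_center = c(x0, 0, 5), pocket_axis = c(0, 1, 0),
       ymax = ymax)
}

# smallest distance between beads more than one chain position apart
min_nonbonded_dist <- function(X) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(X)
  d[cbind(seq_len(n), seq_len(n))] <- Inf
  d[cbind(seq_len(n - 1), 2:n)] <- Inf
  d[cbind(2:n, seq_len(n - 1))] <- Inf
  min(d)
}

#' Generate a synthetic two-conformation protein
#'
#' Builds a compact, self-avoiding two-domain chain whose closed conformer
#' encloses a ligand groove and whose open conformer is the closed one with
#' the distal (cap) domain rigidly rotated by `hinge_angle` about the hinge
#' axis. Deterministic for a given seed.
#'
#' @param n_beads Number of protein beads (>= 20). Default 60.
#' @param hinge_residues Index of the last rigid-domain bead; beads beyond it
#'   form the mobile domain. Default: the built-in cap boundary.
#' @param hinge_angle Opening rotation in degrees. Default 60.
#' @param seed Integer seed.
#' @param jitter Gaussian positional noise (Angstrom) applied to the ideal
#'   closed geometry. Default 0.25.
#' @return List with `closed` and `open` `cg_structure`s (domains CORE and
#'   LID assigned) and the hinge/pocket geometry as attributes.
#' @export
make_two_state_protein <- function(n_beads = 60, hinge_residues = NULL,
                                   hinge_angle = 60, seed = 1,
                                   jitter = 0.25) {
  if (n_beads < 20) stop("n_beads must be >= 20")
  include_ends <- n_beads >= 22
  n_ends <- if (include_ends) 4L else 0L
  ny <- max(2, min(7, (n_beads - n_ends) %/% 9))
  n_subfloor <- n_beads - (9 * ny + n_ends)
  if (n_subfloor < 0) { ny <- ny - 1; n_subfloor <- n_beads - (9 * ny + n_ends) }
  lay <- clamshell_layout(ny, n_subfloor, include_ends = include_ends)
  if (lay$n != n_beads) stop("internal layout error")
  cap_start <- min(lay$cap_idx)
  if (is.null(hinge_residues)) hinge_residues <- cap_start - 1L
  if (hinge_residues <= 1L || hinge_residues >= n_beads)
    stop("hinge must be interior to the chain")
  mobile <- (hinge_residues + 1L):n_beads

  for (attempt in 1:20) {
    X <- with_seed(seed + 1000L * (attempt - 1L), {
      lay$coords + matrix(stats::rnorm(3 * n_beads, sd = jitter), n_beads, 3)
    })
    Xo <- X
    Xo[mobile, ] <- rotate_about_axis(X[mobile, , drop = FALSE],
                                      lay$hinge_origin, lay$hinge_dir,
                                      -lay$mirror * hinge_angle * pi / 180)
    dmin_c <- min_nonbonded_dist(X)
    dmin_o <- min_nonbonded_dist(Xo)
    if (dmin_c > 2.4 && dmin_o > 2.4) {
      dom <- rep("CORE", n_beads)
      dom[mobile] <- "LID"
      closed <- cg_structure(X, rep("protein", n_beads), conformer = "closed",
                             domain = dom)
      open <- cg_structure(Xo, rep("protein", n_beads), conformer = "open",
                           domain = dom)
      out <- list(closed = closed, open = open)
      attr(out, "hinge") <- list(origin = lay$hinge_origin,
                                 dir = lay$hinge_dir,
                                 angle_deg = hinge_angle,
                                 mobile = mobile)
      attr(out, "pocket") <- list(center = lay$pocket_center,
                                  axis = lay$pocket_axis, ymax = lay$ymax,
                                  mirror = lay$mirror)
      return(out)
    }
  }
  stop("could not generate a clash-free conformer pair after 20 attempts")
}

ligand_template <- function(n_beads, pocket) {
  # zigzag groove ligand, deliberately shorter than the groove so the
  # closed pocket tolerates shifted or flipped poses as strained but
  # closable intermediates; the phosphate end curls upward so non-native
  # orientations press against the cap (mild closed-state destabilisation)
  # long enough that a head-to-tail reversal displaces the end beads well
  # beyond the formed-contact cutoff (reversed poses must not score as
  # bound), short enough that the closed groove tolerates registry shifts
  ymax <- pocket$ymax
  half <- max(ymax - 1.5, 2.5)
  ys <- seq(-half, half, length.out = n_beads)
  xs <- 0.8 * rep_len(c(-1, 1), n_beads) * pocket$mirror
  n_curl <- if (n_beads >= 7) 3L else 2L
  zs <- c(rep(5.0, n_beads - n_curl),
          if (n_curl == 3L) c(5.3, 5.6, 5.9) else c(5.3, 5.8))
  cbind(xs + pocket$center[1], ys, zs)
}

#' Place a toy ligand in the closed-cleft native pose
#'
#' Positions an `n_beads`-bead rigid zigzag ligand along the pocket groove of
#' the closed conformer. The native pose forms at least 8 protein--ligand
#' native contacts at the 6.5-Angstrom coarse-grained criterion and has
#' Q = 1 by construction (the pose defines the reference distances).
#'
#' @param closed Closed `cg_structure` from [make_two_state_protein()] (or
#'   the list returned by it).
#' @param n_beads Ligand beads: 5 (AMP-like) or 7 (ATP-like). Default 5.
#' @param pocket Pocket geometry; default taken from the generator attributes.
#' @param seed Seed for the (small) placement jitter.
#' @param kind Ligand kind tag; default `"AMP"` for 5 beads, `"ATP"` for 7.
#' @return A `cg_structure` for the combined closed complex (protein +
#'   ligand), conformer `"closed"`.
#' @export
make_toy_ligand <- function(closed, n_beads = 5, pocket = NULL, seed = 1,
                            kind = NULL) {
  if (is.list(closed) && !inherits(closed, "cg_structure")) {
    pocket <- if (is.null(pocket)) attr(closed, "pocket") else pocket
    closed <- closed$closed
  }
  if (is.null(pocket)) stop("pocket geometry required")
  if (is.null(kind)) kind <- if (n_beads == 7) "ATP" else "AMP"
  lig <- with_seed(seed + 7L, {
    ligand_template(n_beads, pocket) +
      matrix(stats::rnorm(3 * n_beads, sd = 0.1), n_beads, 3)
  })
  np <- n_beads(closed)
  cg_structure(rbind(closed$coords, lig),
               c(closed$role, rep(paste0("ligand:", kind), n_beads)),
               c(closed$residue_index, seq_len(n_beads)),
               c(closed$domain, rep(NA_character_, n_beads)),
               conformer = "closed", heavy = closed$heavy)
}

#' Perturb a ligand pose into a non-native one
#'
#' `flip180` rotates the ligand 180 degrees about an axis through its
#' centroid perpendicular to the base-to-terminal-phosphate vector (so the
#' pose vector reverses exactly: theta becomes pi); applying it twice
#' recovers the input. `random` applies a uniformly random rotation plus a
#' bounded random translation. Either way the returned pose is checked to be
#' clash-free against the open conformer (beads no closer than 3 Angstrom).
#'
#' @param pose n x 3 ligand bead coordinates (native pose).
#' @param mode `"flip180"` or `"random"`.
#' @param magnitude Translation bound (Angstrom) for random mode. Default 3.
#' @param seed Seed for random mode.
#' @param open_coords Optional protein coordinates for the clash check.
#' @return Perturbed n x 3 pose.
#' @export
perturb_pose <- function(pose, mode = c("flip180", "random"), magnitude = 3,
                         seed = 1, open_coords = NULL) {
  mode <- match.arg(mode)
  pose <- as.matrix(pose)
  n <- nrow(pose)
  ctr <- colMeans(pose)
  if (mode == "flip180") {
    v <- pose[n, ] - colMeans(pose[1:min(2, n), , drop = FALSE])
    v <- v / sqrt(sum(v^2))
    ax <- c(1, 0, 0) - sum(c(1, 0, 0) * v) * v
    if (sqrt(sum(ax^2)) < 1e-6) ax <- c(0, 0, 1) - sum(c(0, 0, 1) * v) * v
    out <- rotate_about_axis(pose, ctr, ax, pi)
  } else {
    if (magnitude == 0) return(pose)
    out <- with_seed(seed + 13L, {
      for (attempt in 1:50) {
        q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
        R <- matrix(c(
          1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
          2 * (q[2] * q[4] + q[1] * q[3]),
          2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
          2 * (q[3] * q[4] - q[1] * q[2]),
          2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
          1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
        tr <- stats::runif(3, -1, 1) * magnitude
        cand <- sweep(sweep(pose, 2, ctr) %*% t(R), 2, ctr + tr, "+")
        ok <- TRUE
        if (!is.null(open_coords)) {
          d2 <- outer(rowSums(cand^2), rowSums(open_coords^2), "+") -
            2 * cand %*% t(open_coords)
          ok <- min(d2) > 9
        }
        if (ok) break
      }
      if (!ok) stop("could not place a clash-free perturbed pose")
      cand
    })
    return(out)
  }
  if (!is.null(open_coords)) {
    d2 <- outer(rowSums(out^2), rowSums(open_coords^2), "+") -
      2 * out %*% t(open_coords)
    if (min(d2) <= 9) warning("flipped pose clashes with the open conformer")
  }
  out
}

#' Generate the two-pocket toy enzyme
#'
#' Two mirrored clamshell units share a common CORE (joined by a short
#' linker): the left cap is the NMP domain closing over a 5-bead AMP-like
#' ligand, the right cap is the LID domain closing over a 7-bead ATP-like
#' ligand. This is the standard system for the binding/opening studies.
#'
#' @param seed Integer seed.
#' @param hinge_angle Opening rotation per cap, degrees. Default 60.
#' @param ny Bead rows per unit (sets system size). Default 5
#'   (74 protein beads).
#' @param jitter Positional noise (Angstrom). Default 0.2.
#' @return List with `closed` (protein + both ligands), `open` (protein
#'   only), `pockets` (per-ligand pocket geometry) and `hinges`.
#' @export
make_toy_enzyme <- function(seed = 1, hinge_angle = 60, ny = 5, jitter = 0.2) {
  offs <- 13
  layA <- clamshell_layout(ny, 0, x0 = -offs, mirror = 1)   # NMP unit
  layB <- clamshell_layout(ny, 0, x0 = offs, mirror = -1)   # LID unit
  # unit A is threaded in reverse so both caps are chain termini and every
  # CORE--CORE junction (including the linker) is hinge-invariant
  nA <- layA$n
  XA <- layA$coords[nA:1, , drop = FALSE]
  linker <- cbind(seq(-4.5, 4.5, length.out = 4), 0, -1.5)
  X <- rbind(XA, linker, layB$coords)
  n <- nrow(X)
  capA <- seq_len(length(layA$cap_idx))
  capB <- layB$cap_idx + nA + 4L
  dom <- rep("CORE", n)
  dom[capA] <- "NMP"
  dom[capB] <- "LID"

  for (attempt in 1:20) {
    Xj <- with_seed(seed + 1000L * (attempt - 1L), {
      X + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    })
    Xo <- Xj
    Xo[capA, ] <- rotate_about_axis(Xj[capA, , drop = FALSE], layA$hinge_origin,
                                    layA$hinge_dir,
                                    -layA$mirror * hinge_angle * pi / 180)
    Xo[capB, ] <- rotate_about_axis(Xj[capB, , drop = FALSE], layB$hinge_origin,
                                    layB$hinge_dir,
                                    -layB$mirror * hinge_angle * pi / 180)
    if (min_nonbonded_dist(Xj) > 2.4 && min_nonbonded_dist(Xo) > 2.4) break
    if (attempt == 20) stop("could not generate a clash-free enzyme")
  }

  closed_prot <- cg_structure(Xj, rep("protein", n), conformer = "closed",
                              domain = dom)
  open_prot <- cg_structure(Xo, rep("protein", n), conformer = "open",
                            domain = dom)
  pocketA <- list(center = layA$pocket_center, axis = layA$pocket_axis,
                  ymax = layA$ymax, mirror = layA$mirror)
  pocketB <- list(center = layB$pocket_center, axis = layB$pocket_axis,
                  ymax = layB$ymax, mirror = layB$mirror)
  withA <- make_toy_ligand(closed_prot, 5, pocketA, seed = seed, kind = "AMP")
  closed <- make_toy_ligand(withA, 7, pocketB, seed = seed + 1L, kind = "ATP")
  list(closed = closed, open = open_prot,
       pockets = list(AMP = pocketA, ATP = pocketB),
       hinges = list(NMP = list(origin = layA$hinge_origin,
                                dir = layA$hinge_dir, idx = capA),
                     LID = list(origin = layB$hinge_origin,
                                dir = layB$hinge_dir, idx = capB)))
}

#' Closed-form oracle systems
#'
#' Small fixtures with known analytic answers, used to validate the
#' thermostat, the reweighting machinery and the first-passage estimator:
#' \describe{
#'   \item{harmonic1d}{`V = (k/2) x^2`; Boltzmann position variance `kT/k`.}
#'   \item{doublewell1d}{`V = b (x^2 - 1)^2`; barrier height exactly `b`
#'     between minima at -1 and +1.}
#'   \item{telegraph}{Alternating two-state dwell series with exponential
#'     dwell times of known rates; returns the state series and the exact
#'     switch times.}
#' }
#'
#' @param kind `"harmonic1d"`, `"doublewell1d"` or `"telegraph"`.
#' @param params Named list: `k` (harmonic), `b` (double well),
#'   `rate01`/`rate10` and `t_end` (telegraph).
#' @param seed Seed (telegraph only).
#' @return For the potentials: list with `coeffs` (polynomial coefficients,
#'   constant first), and the analytic quantities. For telegraph: list with
#'   `times`, `state`, `switch_times`.
#' @export
make_oracle_system <- function(kind = c("harmonic1d", "doublewell1d",
                                        "telegraph"),
                               params = list(), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "harmonic1d") {
    k <- params$k %||% 1
    list(kind = kind, coeffs = c(0, 0, k / 2), k = k,
         variance = function(kT) kT / k)
  } else if (kind == "doublewell1d") {
    b <- params$b %||% 2
    list(kind = kind, coeffs = c(b, 0, -2 * b, 0, b), b = b,
         barrier = b, minima = c(-1, 1))
  } else {
    r01 <- params$rate01 %||% 1
    r10 <- params$rate10 %||% 1
    t_end <- params$t_end %||% 100
    with_seed(seed + 29L, {
      t <- 0; s <- 0L
      times <- numeric(); states <- integer(); switches <- numeric()
      while (t < t_end) {
        rate <- if (s == 0L) r01 else r10
        dwell <- stats::rexp(1, rate)
        times <- c(times, t); states <- c(states, s)
        t <- t + dwell
        if (t < t_end) switches <- c(switches, t)
        s <- 1L - s
      }
      list(kind = kind, times = times, state = states,
           switch_times = switches, rate01 = r01, rate10 = r10,
           t_end = t_end)
    })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
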