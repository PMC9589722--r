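#' Best-fit (Kabsch) RMSD between two coordinate sets
#'
#' Minimum root-mean-square deviation over all rigid rotations and
#' translations, computed with the Kabsch singular-value-decomposition
#' algorithm (proper rotations only).
#'
#' @param X,Y n x 3 coordinate matrices.
#' @param subset Optional index vector of rows to superpose and measure
#'   (at least 3 non-collinear points).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y, subset = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(subset)) { X <- X[subset, , drop = FALSE]; Y <- Y[subset, , drop = FALSE] }
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in size")
  if (nrow(X) < 3) stop("need at least 3 points")
  fit <- kabsch_fit(X, Y)
  if (fit$degenerate) stop("degenerate (collinear) subset")
  fit$rmsd
}

# rotation R and translation aligning Y onto X; returns rmsd and aligned Y
kabsch_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  C <- t(Yc) %*% Xc
  sv <- svd(C)
  degenerate <- sv$d[2] < 1e-9 * max(sv$d[1], 1e-30)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Yal <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xc - Yal)^2)))
  list(rmsd = rmsd, R = R, Y_aligned = sweep(Yal, 2, cx, "+"),
       degenerate = degenerate)
}

#' Conformational progress coordinate xi
#'
#' `xi = (RMSD_C - RMSD_O) / RMSD_CO`, where the RMSDs are best-fit
#' deviations of the instantaneous protein beads from the closed and open
#' references and `RMSD_CO` is the deviation between the two references.
#' By construction xi is -1 at the closed reference and +1 at the open one.
#'
#' @param coords Instantaneous coordinates: either an N x 3 matrix over all
#'   beads of the topology's system or a matrix over the protein beads only.
#' @param closed_ref,open_ref Protein-bead reference coordinate matrices.
#' @return Dimensionless xi.
#' @export
xi <- function(coords, closed_ref, open_ref) {
  closed_ref <- as.matrix(closed_ref); open_ref <- as.matrix(open_ref)
  rmsd_co <- kabsch_rmsd(closed_ref, open_ref)
  if (rmsd_co < 1e-9) stop("closed and open references coincide (RMSD_CO = 0)")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(closed_ref))
    coords <- coords[seq_len(nrow(closed_ref)), , drop = FALSE]
  (kabsch_rmsd(coords, closed_ref) - kabsch_rmsd(coords, open_ref)) / rmsd_co
}

#' xi evaluated on a topology
#' @param coords Full-system N x 3 coordinates.
#' @param topology A `cg_topology`.
#' @return Dimensionless xi.
#' @export
xi_topology <- function(coords, topology) {
  p <- topology$protein_idx
  xi(as.matrix(coords)[p, , drop = FALSE],
     topology$closed[p, , drop = FALSE], topology$open)
}

#' Fraction of formed native contacts Q
#'
#' A contact counts as formed when its instantaneous distance is below
#' `lam * r0`. `Q` is the formed fraction over the supplied contact list.
#'
#' @param coords N x 3 coordinates.
#' @param contacts Data frame with columns `i, j, r0` (e.g. from
#'   [ligand_contacts()]).
#' @param lam Cutoff ratio; default 1.2.
#' @return Q in `[0, 1]`.
#' @export
fraction_native_contacts <- function(coords, contacts, lam = 1.2) {
  if (nrow(contacts) == 0L) stop("Q is undefined for an empty contact list")
  X <- as.matrix(coords)
  d <- sqrt(rowSums((X[contacts$i, , drop = FALSE] -
                     X[contacts$j, , drop = FALSE])^2))
  mean(d < lam * contacts$r0)
}

#' Smooth variant of the fraction of native contacts
#'
#' Uses the switching function 1 / (1 + exp(beta * (r - lam * r0))) instead
#' of a sharp cutoff; provided behind the same interface for analyses that
#' need a differentiable Q.
#' @inheritParams fraction_native_contacts
#' @param beta Switching steepness (1/Angstrom); default 5.
#' @return Smooth Q in `(0, 1)`.
#' @export
fraction_native_contacts_smooth <- function(coords, contacts, lam = 1.2,
                                            beta = 5) {
  if (nrow(contacts) == 0L) stop("Q is undefined for an empty contact list")
  X <- as.matrix(coords)
  d <- sqrt(rowSums((X[contacts$i, , drop = FALSE] -
                     X[contacts$j, , drop = FALSE])^2))
  mean(1 / (1 + exp(beta * (d - lam * contacts$r0))))
}

#' Ligand pose coordinates R and theta
#'
#' The CORE-domain beads of the instantaneous structure are superposed onto
#' the closed reference; `R` is then the displacement of the ligand's
#' terminal-phosphate bead from its reference position and `theta` is the
#' angle between the instantaneous and reference base-to-terminal-phosphate
#' vectors. Both are 0 when the ligand sits exactly in its native pose.
#'
#' @param coords Full-system N x 3 coordinates.
#' @param topology A `cg_topology` whose closed reference holds the native
#'   ligand pose.
#' @param kind `"ATP"` or `"AMP"`.
#' @return List with `R` (Angstrom) and `theta` (radians, in `[0, pi]`).
#' @export
pose_coordinates <- function(coords, topology, kind) {
  X <- as.matrix(coords)
  lk <- which(topology$role == paste0("ligand:", kind))
  if (!length(lk)) stop("no ligand of kind ", kind, " in topology")
  core <- which(topology$domain == "CORE" & topology$role == "protein")
  if (length(core) < 3) stop("CORE domain beads missing")
  fit <- kabsch_fit(topology$closed[core, , drop = FALSE],
                    X[core, , drop = FALSE])
  # map instantaneous coordinates into the reference frame
  cx <- colMeans(X[core, , drop = FALSE])
  cref <- colMeans(topology$closed[core, , drop = FALSE])
  to_ref <- function(v) as.numeric((v - cx) %*% t(fit$R)) + cref
  # base = first two beads (purine rings); terminal phosphate = last bead
  base_inst <- colMeans(X[lk[1:2], , drop = FALSE])
  tp_inst <- X[lk[length(lk)], ]
  base_ref <- colMeans(topology$closed[lk[1:2], , drop = FALSE])
  tp_ref <- topology$closed[lk[length(lk)], ]
  bi <- to_ref(base_inst); ti <- to_ref(tp_inst)
  Rv <- sqrt(sum((ti - tp_ref)^2))
  v1 <- ti - bi; v2 <- tp_ref - base_ref
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("degenerate base-to-phosphate vector")
  theta <- acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2))))
  list(R = Rv, theta = theta)
}

#' Distance between domain centres of mass
#'
#' Euclidean distance between the unweighted bead centroids of two domains
#' (unit bead masses).
#' @param coords N x 3 coordinates.
#' @param topology A `cg_topology`.
#' @param domainA,domainB Domain labels.
#' @return Distance in Angstrom.
#' @export
interdomain_distance <- function(coords, topology, domainA, domainB) {
  X <- as.matrix(coords)
  ia <- which(topology$domain == domainA & topology$role == "protein")
  ib <- which(topology$domain == domainB & topology$role == "protein")
  if (!length(ia) || !length(ib)) stop("empty domain selection")
  sqrt(sum((colMeans(X[ia, , drop = FALSE]) -
            colMeans(X[ib, , drop = FALSE]))^2))
}

# ---- per-frame observable series over a trajectory --------------------------

#' Observable time series from a trajectory
#'
#' Computes named reaction-coordinate series over the stored frames of a
#' trajectory: `xi`, per-ligand `Q` and pose coordinates, and interdomain
#' distances for every mobile domain against CORE.
#'
#' @param traj A `cg_trajectory` from [run_trajectory()].
#' @param topology The matching `cg_topology`.
#' @param which Character vector choosing observables: any of `"xi"`,
#'   `"Q"`, `"pose"`, `"domains"`. Default all.
#' @return Data frame with one row per frame, first column `time` (tau).
#' @export
trajectory_observables <- function(traj, topology,
                                   which = c("xi", "Q", "pose", "domains")) {
  fr <- traj$frames
  p <- topology$protein_idx
  dt <- traj$dt
  out <- data.frame(time = traj$frame_steps * dt)
  if ("xi" %in% which) {
    rc <- rmsd_frames_cpp(fr, topology$closed[p, , drop = FALSE], p)
    ro <- rmsd_frames_cpp(fr, topology$open, p)
    out$rmsd_closed <- rc
    out$rmsd_open <- ro
    out$xi <- (rc - ro) / topology$rmsd_co
  }
  kinds <- unique(sub("^ligand:", "", topology$role[grepl("^ligand", topology$role)]))
  if ("Q" %in% which) {
    for (k in kinds) {
      ct <- ligand_contacts(topology, k)
      out[[paste0("Q_", k)]] <-
        q_frames_cpp(fr, as.matrix(ct[, c("i", "j")]), ct$r0,
                     topology$params$q_lambda)
    }
  }
  if ("pose" %in% which) {
    for (k in kinds) {
      pc <- t(vapply(seq_len(nrow(fr)), function(f) {
        X <- matrix(fr[f, ], ncol = 3, byrow = TRUE)
        unlist(pose_coordinates(X, topology, k))
      }, numeric(2)))
      out[[paste0("R_", k)]] <- pc[, 1]
      out[[paste0("theta_", k)]] <- pc[, 2]
    }
  }
  if ("domains" %in% which) {
    doms <- setdiff(unique(stats::na.omit(topology$domain)), "CORE")
    core <- which(topology$domain == "CORE" & topology$role == "protein")
    for (d in doms) {
      idm <- which(topology$domain == d & topology$role == "protein")
      out[[paste0("R_", d, "_CORE")]] <-
        centroid_dist_frames_cpp(fr, idm, core)
    }
  }
  out
}
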