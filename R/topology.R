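#' Build the full simulation topology from a reference pair
#'
#' Combines the closed and open reference structures into the complete
#' interaction list used by the energy model: bonded terms referenced to the
#' closed conformation (terms whose reference value differs between the two
#' conformers -- i.e. hinge-spanning angles and dihedrals -- are dropped so
#' both references remain strain-free minima), shared single-basin 12-10
#' contacts (intra-domain protein--protein and protein--ligand native),
#' per-interface closed/open contact lists mixed by the double-basin
#' potential, non-native Gaussian pairs, and excluded-volume pairs.
#'
#' @param closed Closed reference `cg_structure`, including ligands in their
#'   native pose, with domains assigned.
#' @param open Open reference `cg_structure` (protein beads only, same
#'   residue ordering), domains assigned.
#' @param params A `cg_params` object. If `deltaV` / `coupling_delta` are
#'   empty they are initialised to zeros, one per interface component.
#' @param contact_threshold Native-contact threshold in Angstrom.
#' @param hinge_tol Reference-value tolerance (rad) beyond which a bonded
#'   term is considered hinge-spanning and dropped.
#' @return A `cg_topology` object.
#' @export
build_topology <- function(closed, open, params = cg_params(),
                           contact_threshold = 6.5, hinge_tol = 0.15) {
  pidx <- protein_idx(closed)
  if (length(protein_idx(open)) != length(pidx))
    stop("closed and open references have different protein lengths")
  if (any(is.na(closed$domain[pidx]))) stop("closed reference lacks domain labels")
  n <- n_beads(closed)
  Xc <- closed$coords
  Xo_prot <- open$coords[protein_idx(open), , drop = FALSE]

  cmap_c <- build_native_contacts(closed, threshold = contact_threshold)
  cmap_c <- build_nonnative_pairs(cmap_c, closed)
  open_lab <- open
  open_lab$domain <- closed$domain[pidx]
  cmap_o <- build_native_contacts(open_lab, threshold = contact_threshold)

  nat_c <- cmap_c$native
  nat_o <- cmap_o$native
  # map open-structure bead indices onto full-system indices
  nat_o$i <- pidx[nat_o$i]; nat_o$j <- pidx[nat_o$j]

  # ---- bonded terms (closed-referenced; hinge-spanning terms pruned) ----
  dist_ref <- function(X, i, j) sqrt(sum((X[i, ] - X[j, ]) ^ 2))
  ang_ref <- function(X, i, j, k) {
    a <- X[i, ] - X[j, ]; b <- X[k, ] - X[j, ]
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  }
  # dihedrals are undefined (and their forces unbounded) near collinear
  # geometries; terms whose reference bends are not safely bent are dropped
  # (the tertiary structure is maintained by the contact network)
  dih_ok <- function(X, i, j, k, l) {
    s1 <- sin(ang_ref(X, i, j, k)); s2 <- sin(ang_ref(X, j, k, l))
    min(s1, s2) > 0.6
  }
  dih_ref <- function(X, i, j, k, l) {
    b1 <- X[j, ] - X[i, ]; b2 <- X[k, ] - X[j, ]; b3 <- X[l, ] - X[k, ]
    n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
    n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
    m <- c(n1[2]*n2[3]-n1[3]*n2[2], n1[3]*n2[1]-n1[1]*n2[3], n1[1]*n2[2]-n1[2]*n2[1])
    atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }
  prot_open_pos <- function(i) Xo_prot[match(i, pidx), , drop = TRUE]

  b_ij <- NULL; b_r0 <- numeric(); b_k <- numeric()
  a_ijk <- NULL; a_t0 <- numeric(); a_k <- numeric()
  d_ijkl <- NULL; d_p0 <- numeric(); d_k <- numeric()

  # protein chain
  np <- length(pidx)
  for (q in seq_len(np - 1)) {
    i <- pidx[q]; j <- pidx[q + 1]
    r0c <- dist_ref(Xc, i, j)
    r0o <- dist_ref(rbind(prot_open_pos(i), prot_open_pos(j)), 1, 2)
    if (abs(r0c - r0o) < 0.05) {
      b_ij <- rbind(b_ij, c(i, j)); b_r0 <- c(b_r0, r0c); b_k <- c(b_k, params$k_bond)
    } else {  # hinge-spanning bond: keep chain connectivity, soften
      b_ij <- rbind(b_ij, c(i, j)); b_r0 <- c(b_r0, (r0c + r0o) / 2)
      b_k <- c(b_k, params$k_bond / 10)
    }
  }
  if (np >= 3) for (q in seq_len(np - 2)) {
    i <- pidx[q]; j <- pidx[q + 1]; k <- pidx[q + 2]
    t0c <- ang_ref(Xc, i, j, k)
    Xo3 <- rbind(prot_open_pos(i), prot_open_pos(j), prot_open_pos(k))
    t0o <- ang_ref(Xo3, 1, 2, 3)
    if (abs(t0c - t0o) < hinge_tol) {
      a_ijk <- rbind(a_ijk, c(i, j, k)); a_t0 <- c(a_t0, t0c)
      a_k <- c(a_k, params$k_angle)
    }
  }
  if (np >= 4) for (q in seq_len(np - 3)) {
    i <- pidx[q]; j <- pidx[q + 1]; k <- pidx[q + 2]; l <- pidx[q + 3]
    if (!dih_ok(Xc, i, j, k, l)) next
    p0c <- dih_ref(Xc, i, j, k, l)
    Xo4 <- rbind(prot_open_pos(i), prot_open_pos(j), prot_open_pos(k),
                 prot_open_pos(l))
    p0o <- dih_ref(Xo4, 1, 2, 3, 4)
    dphi <- abs(atan2(sin(p0c - p0o), cos(p0c - p0o)))
    if (dphi < hinge_tol) {
      d_ijkl <- rbind(d_ijkl, c(i, j, k, l)); d_p0 <- c(d_p0, p0c)
      d_k <- c(d_k, params$k_dihedral)
    }
  }

  # intra-domain elastic network: quasi-rigid domains, hinge-invariant
  # because domains map onto themselves between the two references
  if (params$k_enm > 0) {
    dom <- closed$domain
    for (a in seq_len(np - 1)) {
      for (b in seq((a + 1), np) ) {
        i <- pidx[a]; j <- pidx[b]
        if (b - a < 2) next
        if (is.na(dom[i]) || is.na(dom[j]) || dom[i] != dom[j]) next
        r0c <- dist_ref(Xc, i, j)
        cut <- if (dom[i] == "CORE") params$enm_cutoff_core else params$enm_cutoff
        if (r0c > cut) next
        b_ij <- rbind(b_ij, c(i, j)); b_r0 <- c(b_r0, r0c)
        b_k <- c(b_k, params$k_enm)
      }
    }
  }

  # rigid-like ligands: the internal geometry (bonds, bends, torsions) is
  # restrained to the reference by a harmonic distance network over first,
  # second and third neighbours -- equivalent in effect to stiff
  # bond/angle/dihedral restraints but with everywhere-bounded forces
  for (kind in unique(closed$role[ligand_idx(closed)])) {
    lk <- which(closed$role == kind)
    m <- length(lk)
    for (gap in 1:3) {
      if (m > gap) for (q in seq_len(m - gap)) {
        b_ij <- rbind(b_ij, c(lk[q], lk[q + gap]))
        b_r0 <- c(b_r0, dist_ref(Xc, lk[q], lk[q + gap]))
        b_k <- c(b_k, if (gap == 1) params$k_ligand_bond
                      else params$k_ligand_bond / 2)
      }
    }
  }

  # ---- contact lists ----
  intra_c <- nat_c[nat_c$class == "intra", , drop = FALSE]
  plig <- nat_c[nat_c$class == "protein-ligand", , drop = FALSE]
  iface_names <- sort(unique(c(nat_c$class, nat_o$class)))
  iface_names <- setdiff(iface_names, c("intra", "protein-ligand"))
  shared <- list(
    ij = rbind(as.matrix(intra_c[, c("i", "j")]),
               as.matrix(plig[, c("i", "j")])),
    a = c(intra_c$r0, plig$r0),
    b = c(rep(params$eps_pp, nrow(intra_c)), rep(params$eps_nat, nrow(plig)))
  )
  if (is.null(shared$ij)) shared$ij <- matrix(integer(), 0, 2)

  comp_closed <- list(); comp_open <- list()
  for (cn in iface_names) {
    cc <- nat_c[nat_c$class == cn, , drop = FALSE]
    co <- nat_o[nat_o$class == cn, , drop = FALSE]
    comp_closed[[cn]] <- list(ij = matrix(as.matrix(cc[, c("i", "j")]),
                                          ncol = 2),
                              a = cc$r0, b = rep(params$eps_pp, nrow(cc)))
    comp_open[[cn]] <- list(ij = matrix(as.matrix(co[, c("i", "j")]),
                                        ncol = 2),
                            a = co$r0, b = rep(params$eps_pp, nrow(co)))
  }

  # ---- non-native pairs ----
  nn <- cmap_c$nonnative
  nonnative <- list(ij = matrix(as.matrix(nn), ncol = 2))

  # ---- excluded volume ----
  nat_any_key <- unique(c(paste(nat_c$i, nat_c$j), paste(nat_o$i, nat_o$j)))
  exv_ij <- NULL; exv_sig <- numeric(); exv_eps <- numeric()
  role <- closed$role
  resi <- closed$residue_index
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pi <- role[i] == "protein"; pj <- role[j] == "protein"
      if (pi && pj) {
        if (abs(resi[i] - resi[j]) < 3) next
        if (paste(i, j) %in% nat_any_key) next
        # pairs far apart in both references cannot reach the repulsive
        # range (domains are quasi-rigid); drop them from the pair list
        dc <- dist_ref(Xc, i, j)
        do_ <- sqrt(sum((prot_open_pos(i) - prot_open_pos(j))^2))
        if (min(dc, do_) > 14) next
        exv_ij <- rbind(exv_ij, c(i, j))
        exv_sig <- c(exv_sig, params$sigma_exv_pp)
        exv_eps <- c(exv_eps, params$eps_exv_pp)
      } else if (xor(pi, pj)) {
        if (paste(i, j) %in% nat_any_key) next
        exv_ij <- rbind(exv_ij, c(i, j))
        exv_sig <- c(exv_sig, params$sigma_exv_protein_ligand)
        exv_eps <- c(exv_eps, params$eps_exv)
      } else if (role[i] != role[j]) {   # different ligands
        exv_ij <- rbind(exv_ij, c(i, j))
        exv_sig <- c(exv_sig, params$sigma_exv_ligand_ligand)
        exv_eps <- c(exv_eps, params$eps_exv)
      }
    }
  }
  if (is.null(exv_ij)) exv_ij <- matrix(integer(), 0, 2)

  ncomp <- length(iface_names)
  if (!length(params$deltaV)) {
    params$deltaV <- rep(0, ncomp)
    params$coupling_delta <- rep(0, ncomp)
  }
  if (length(params$deltaV) != ncomp)
    stop(sprintf("params$deltaV has length %d but topology has %d interface components (%s)",
                 length(params$deltaV), ncomp, paste(iface_names, collapse = ", ")))

  contacts_df <- rbind(
    data.frame(nat_c, basin = "closed"),
    data.frame(nat_o, basin = "open")
  )

  topo <- list(
    n = n,
    role = role,
    domain = closed$domain,
    residue_index = resi,
    closed = Xc,
    open = Xo_prot,
    protein_idx = pidx,
    components = iface_names,
    contacts = contacts_df,
    contact_map = cmap_c,
    params = params,
    rmsd_co = NA_real_,
    core = list(
      n = n,
      bonds = list(ij = b_ij, r0 = b_r0, k = b_k),
      angles = list(ijk = if (is.null(a_ijk)) matrix(integer(), 0, 3) else a_ijk,
                    theta0 = a_t0, k = a_k),
      dihedrals = list(ijkl = if (is.null(d_ijkl)) matrix(integer(), 0, 4) else d_ijkl,
                       phi0 = d_p0, k = d_k),
      shared_contacts = shared,
      comp_closed = unname(comp_closed),
      comp_open = unname(comp_open),
      nonnative = nonnative,
      exv = list(ij = exv_ij, a = exv_sig, b = exv_eps)
    )
  )
  class(topo) <- "cg_topology"
  topo$rmsd_co <- kabsch_rmsd(Xc[pidx, , drop = FALSE], Xo_prot)
  topo
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d beads, %d interface component(s): %s\n",
              x$n, length(x$components), paste(x$components, collapse = ", ")))
  cat(sprintf("  shared contacts %d, non-native pairs %d, exv pairs %d\n",
              nrow(x$core$shared_contacts$ij), nrow(x$core$nonnative$ij),
              nrow(x$core$exv$ij)))
  cat(sprintf("  closed/open protein RMSD %.2f A\n", x$rmsd_co))
  invisible(x)
}

#' Native protein--ligand contact pairs for one ligand
#' @param topology A `cg_topology`.
#' @param kind `"ATP"` or `"AMP"`.
#' @return Data frame with columns `i, j, r0`.
#' @export
ligand_contacts <- function(topology, kind) {
  lk <- which(topology$role == paste0("ligand:", kind))
  cc <- topology$contacts
  cc <- cc[cc$class == "protein-ligand" & cc$basin == "closed" &
             cc$j %in% lk, , drop = FALSE]
  cc[, c("i", "j", "r0")]
}
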