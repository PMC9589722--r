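#' Coarse-grained structure objects
#'
#' A `cg_structure` holds one bead per protein residue (placed at the
#' C-alpha position when built from an atomic structure) plus optional
#' multi-bead ligands, together with per-bead role, residue index, domain
#' label and the conformer tag of the reference it represents.
#'
#' @param coords N x 3 numeric matrix of bead positions (Angstrom).
#' @param role Character vector: `"protein"`, `"ligand:ATP"` or `"ligand:AMP"`.
#' @param residue_index Integer per bead (protein: residue number; ligand:
#'   bead number within the ligand).
#' @param domain Character per protein bead (`"CORE"`, `"LID"`, `"NMP"` or
#'   `NA` before assignment); ligand beads carry `NA`.
#' @param conformer `"closed"`, `"open"` or `"instantaneous"`.
#' @param heavy Optional list of per-bead heavy-atom coordinate matrices
#'   (used for atomic-distance contact detection; absent for synthetic beads).
#' @return A `cg_structure` object.
#' @export
cg_structure <- function(coords, role, residue_index = seq_len(nrow(coords)),
                         domain = rep(NA_character_, nrow(coords)),
                         conformer = "instantaneous", heavy = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 1L) stop("structure must contain at least one bead")
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (length(role) != n) stop("role must have one entry per bead")
  ok <- role %in% c("protein", "ligand:ATP", "ligand:AMP")
  if (!all(ok)) stop("invalid role(s): ", paste(unique(role[!ok]), collapse = ", "))
  n_atp <- sum(role == "ligand:ATP")
  n_amp <- sum(role == "ligand:AMP")
  if (n_atp > 0L && n_atp != 7L) stop("ligand ATP must have exactly 7 beads")
  if (n_amp > 0L && n_amp != 5L) stop("ligand AMP must have exactly 5 beads")
  if (!conformer %in% c("closed", "open", "instantaneous"))
    stop("conformer must be closed, open or instantaneous")
  structure(list(coords = coords, role = role,
                 residue_index = as.integer(residue_index),
                 domain = domain, conformer = conformer, heavy = heavy),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("<cg_structure> %d beads (%d protein), conformer = %s\n",
              nrow(x$coords), sum(x$role == "protein"), x$conformer))
  if (!all(is.na(x$domain))) {
    tb <- table(x$domain[x$role == "protein"])
    cat("  domains:", paste(names(tb), tb, sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

n_beads <- function(x) nrow(x$coords)
protein_idx <- function(x) which(x$role == "protein")
ligand_idx <- function(x, kind = NULL) {
  if (is.null(kind)) which(startsWith(x$role, "ligand"))
  else which(x$role == paste0("ligand:", kind))
}

#' Load a closed/open reference pair from PDB files
#'
#' Reads two PDB structures, keeps one bead per residue at the C-alpha
#' position, and retains the heavy atoms of each residue (and of any bound
#' ligands) for atomic-distance contact detection. The two files must
#' describe the same chain: equal residue count and matching residue
#' numbering after sorting.
#'
#' @param closed_file,open_file Paths to PDB files of the closed and open
#'   reference conformations.
#' @param chain Optional chain identifier; default takes the first chain.
#' @param ligands Named list mapping ligand residue names in the closed file
#'   to `"ATP"` or `"AMP"` (e.g. `list(AP5A_ATP = "ATP")`); ligand atoms are
#'   coarse-grained with [map_ligand_beads()].
#' @return A list with elements `closed` and `open`, both `cg_structure`s.
#' @export
load_reference_pair <- function(closed_file, open_file, chain = NULL,
                                ligands = NULL) {
  parse_one <- function(file, conformer, with_ligands) {
    pdb <- bio3d::read.pdb(file)
    at <- pdb$atom
    # altloc: keep blank or 'A'
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
    prot <- at[at$type == "ATOM", , drop = FALSE]
    if (is.null(chain)) ch <- sort(unique(prot$chain))[1] else ch <- chain
    prot <- prot[prot$chain %in% ch, , drop = FALSE]
    resnos <- sort(unique(prot$resno))
    coords <- matrix(NA_real_, length(resnos), 3)
    heavy <- vector("list", length(resnos))
    for (q in seq_along(resnos)) {
      res <- prot[prot$resno == resnos[q], , drop = FALSE]
      ca <- res[res$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0L)
        stop(sprintf("residue %d has no CA atom in %s", resnos[q], file))
      coords[q, ] <- as.numeric(ca[1, c("x", "y", "z")])
      hv <- res[!grepl("^H", res$elety), , drop = FALSE]
      heavy[[q]] <- as.matrix(hv[, c("x", "y", "z")])
    }
    role <- rep("protein", length(resnos))
    residue_index <- resnos
    lig_coords <- NULL; lig_role <- character(); lig_heavy <- list()
    if (with_ligands && !is.null(ligands)) {
      het <- at[at$type == "HETATM", , drop = FALSE]
      for (resid in names(ligands)) {
        kind <- ligands[[resid]]
        sel <- het[het$resid == resid, , drop = FALSE]
        if (nrow(sel) == 0L)
          stop(sprintf("ligand residue %s not found in %s", resid, file))
        atoms <- data.frame(elety = sel$elety,
                            x = sel$x, y = sel$y, z = sel$z)
        lb <- map_ligand_beads(atoms, kind)
        lig_coords <- rbind(lig_coords, lb$coords)
        lig_role <- c(lig_role, rep(paste0("ligand:", kind), nrow(lb$coords)))
        lig_heavy <- c(lig_heavy, lb$heavy)
      }
    }
    all_coords <- rbind(coords, lig_coords)
    all_role <- c(role, lig_role)
    all_ri <- c(residue_index,
                if (length(lig_role)) seq_len(length(lig_role)) else integer())
    cg_structure(all_coords, all_role, all_ri, conformer = conformer,
                 heavy = c(heavy, lig_heavy))
  }
  closed <- parse_one(closed_file, "closed", with_ligands = TRUE)
  open <- parse_one(open_file, "open", with_ligands = FALSE)
  nc <- sum(closed$role == "protein"); no <- sum(open$role == "protein")
  if (nc != no)
    stop(sprintf("residue-count mismatch: %d (closed) vs %d (open)", nc, no))
  if (!all(closed$residue_index[closed$role == "protein"] ==
           open$residue_index[open$role == "protein"]))
    stop("residue numbering differs between closed and open structures")
  list(closed = closed, open = open)
}

#' Map ligand heavy atoms to coarse-grained beads
#'
#' AMP is represented by five beads and ATP by seven. Atoms are grouped by
#' chemical moiety -- adenine purine five-ring, adenine six-ring, ribose,
#' and one bead per phosphate-centred group (alpha phosphate plus terminal
#' oxygens for AMP; beta and gamma phosphates added for ATP) -- and each
#' bead is placed at the centre of geometry of its group. The grouping is
#' deterministic: the same atom table always yields the same beads.
#'
#' @param heavy_atoms Data frame with columns `elety`, `x`, `y`, `z`
#'   (PDB-style atom names, e.g. `"N9"`, `"C1'"`, `"PA"`, `"O1A"`).
#' @param ligand_kind `"ATP"` or `"AMP"`.
#' @return List with `coords` (beads x 3), `heavy` (per-bead atom matrices)
#'   and `groups` (atom-name assignment).
#' @export
map_ligand_beads <- function(heavy_atoms, ligand_kind = c("AMP", "ATP")) {
  ligand_kind <- match.arg(ligand_kind)
  nm <- gsub("\\*", "'", heavy_atoms$elety)  # old-style primes
  groups <- list(
    purine5 = c("N9", "C8", "N7", "C5", "C4"),
    purine6 = c("C6", "N6", "N1", "C2", "N3"),
    ribose  = c("C1'", "C2'", "O2'", "C3'", "O3'", "C4'", "O4'", "C5'", "O5'"),
    alphaP  = c("PA", "P"),
    alphaO  = c("O1A", "O2A", "O3A", "O1P", "O2P", "O3P")
  )
  if (ligand_kind == "ATP") {
    groups$betaP  <- c("PB", "O1B", "O2B", "O3B")
    groups$gammaP <- c("PG", "O1G", "O2G", "O3G")
  }
  coords <- matrix(NA_real_, length(groups), 3)
  heavy <- vector("list", length(groups))
  for (q in seq_along(groups)) {
    sel <- which(nm %in% groups[[q]])
    if (length(sel) == 0L)
      stop(sprintf("missing atoms for ligand group '%s'", names(groups)[q]))
    m <- as.matrix(heavy_atoms[sel, c("x", "y", "z")])
    storage.mode(m) <- "double"
    coords[q, ] <- colMeans(m)
    heavy[[q]] <- m
  }
  rownames(coords) <- names(groups)
  list(coords = coords, heavy = heavy, groups = groups)
}

#' Assign domain labels to protein beads
#'
#' @param structure A `cg_structure`.
#' @param ranges Named list of integer vectors of residue indices, e.g.
#'   `list(CORE = c(1:29, 68:117, 161:214), NMP = 30:67, LID = 118:160)`.
#'   The ranges must partition the protein residues: no overlap, no gap.
#' @return The structure with `domain` filled in.
#' @export
assign_domains <- function(structure, ranges) {
  pidx <- protein_idx(structure)
  res <- structure$residue_index[pidx]
  all_assigned <- unlist(ranges, use.names = FALSE)
  if (anyDuplicated(all_assigned))
    stop("domain ranges overlap: residue(s) ",
         paste(unique(all_assigned[duplicated(all_assigned)]), collapse = ", "))
  missing <- setdiff(res, all_assigned)
  if (length(missing))
    stop("domain ranges leave residue(s) uncovered: ",
         paste(utils::head(missing, 5), collapse = ", "))
  dom <- rep(NA_character_, length(res))
  for (nmv in names(ranges)) dom[res %in% ranges[[nmv]]] <- nmv
  structure$domain[pidx] <- dom
  structure
}

#' Default adenylate-kinase domain ranges
#'
#' Residue intervals for the CORE, NMP (AMP-binding) and LID (ATP-binding)
#' domains of E. coli adenylate kinase. Conventions in the literature vary
#' by a few residues; these defaults are configurable wherever used.
#' @return Named list of residue-index vectors.
#' @export
adk_domain_ranges <- function() {
  list(CORE = c(1:29, 68:117, 161:214), NMP = 30:67, LID = 118:160)
}

#' Write a coarse-grained structure as a PDB file
#'
#' Protein beads are written as CA pseudo-atoms, ligand beads as HETATM
#' records, so synthetic systems and crystal-derived systems share one
#' on-disk format.
#' @param structure A `cg_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cg_pdb <- function(structure, file) {
  n <- n_beads(structure)
  is_prot <- structure$role == "protein"
  resid <- ifelse(is_prot, "ALA",
                  ifelse(structure$role == "ligand:ATP", "ATP", "AMP"))
  chain <- ifelse(is_prot, "A", "L")
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(structure$coords)),
                   type = ifelse(is_prot, "ATOM", "HETATM"),
                   resno = structure$residue_index,
                   resid = resid, chain = chain,
                   elety = rep("CA", n))
  invisible(file)
}

#' Serialize a topology to JSON
#'
#' Writes the bead table, contact map and parameters of a built model to a
#' plain-text JSON file; [read_topology_json()] restores it.
#' @param topology A `cg_topology` from [build_topology()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_topology_json <- function(topology, file) {
  ser <- list(
    n = topology$n,
    role = topology$role,
    domain = topology$domain,
    residue_index = topology$residue_index,
    closed = topology$closed,
    open = topology$open,
    contacts = topology$contacts,
    nonnative_ij = topology$core$nonnative$ij,
    params = unclass(topology$params)
  )
  jsonlite::write_json(ser, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Restore a topology written by [write_topology_json()]
#' @param file JSON path.
#' @return A `cg_topology`.
#' @export
read_topology_json <- function(file) {
  ser <- jsonlite::read_json(file, simplifyVector = TRUE)
  params <- do.call(cg_params, ser$params[names(ser$params) %in%
                                            names(formals(cg_params))])
  closed <- cg_structure(ser$closed, ser$role, ser$residue_index,
                         ser$domain, conformer = "closed")
  open_prot <- cg_structure(ser$open,
                            ser$role[seq_len(nrow(ser$open))],
                            ser$residue_index[seq_len(nrow(ser$open))],
                            ser$domain[seq_len(nrow(ser$open))],
                            conformer = "open")
  build_topology(closed, open_prot, params = params)
}
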