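#' Build the native contact map of a reference structure
#'
#' A pair of beads is in native contact when the closest distance between
#' their heavy-atom groups in the reference structure is below `threshold`
#' (default 6.5 Angstrom). For synthetic structures without heavy atoms the
#' bead--bead distance is used with the same threshold. Protein--protein
#' pairs additionally require a sequence separation of at least
#' `min_seq_sep` residues. The stored reference distance `r0` is always the
#' coarse-grained bead--bead distance, and each pair is classified by domain
#' interface (`intra`, `LID-CORE`, ..., or `protein-ligand`).
#'
#' @param reference A `cg_structure` (with domains assigned for interface
#'   classification).
#' @param threshold Contact threshold in Angstrom. Default 6.5.
#' @param min_seq_sep Minimum |i - j| for protein pairs. Default 3.
#' @return A `contact_map`: list with `native` (data frame `i, j, r0, class`),
#'   `nonnative` (empty until [build_nonnative_pairs()]), and the thresholds.
#' @export
build_native_contacts <- function(reference, threshold = 6.5,
                                  min_seq_sep = 3L) {
  X <- reference$coords
  n <- nrow(X)
  pidx <- protein_idx(reference)
  lidx <- ligand_idx(reference)
  heavy <- reference$heavy

  min_heavy_dist <- function(i, j) {
    if (is.null(heavy) || is.null(heavy[[i]]) || is.null(heavy[[j]]))
      return(sqrt(sum((X[i, ] - X[j, ])^2)))
    A <- heavy[[i]]; B <- heavy[[j]]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }

  rows <- list()
  # protein-protein
  for (a in seq_along(pidx)) {
    for (b in seq_along(pidx)) {
      if (b <= a) next
      i <- pidx[a]; j <- pidx[b]
      if (abs(reference$residue_index[i] - reference$residue_index[j]) <
          min_seq_sep) next
      if (min_heavy_dist(i, j) < threshold) {
        di <- reference$domain[i]; dj <- reference$domain[j]
        cls <- if (is.na(di) || is.na(dj) || di == dj) "intra"
               else paste(sort(c(di, dj)), collapse = "-")
        rows[[length(rows) + 1L]] <-
          data.frame(i = i, j = j, r0 = sqrt(sum((X[i, ] - X[j, ])^2)),
                     class = cls)
      }
    }
  }
  # protein-ligand
  for (i in pidx) {
    for (j in lidx) {
      if (min_heavy_dist(i, j) < threshold) {
        rows[[length(rows) + 1L]] <-
          data.frame(i = i, j = j, r0 = sqrt(sum((X[i, ] - X[j, ])^2)),
                     class = "protein-ligand")
      }
    }
  }
  native <- if (length(rows)) do.call(rbind, rows)
            else data.frame(i = integer(), j = integer(), r0 = numeric(),
                            class = character())
  if (any(native$r0 <= 0)) stop("native contact with non-positive r0")
  structure(list(native = native,
                 nonnative = data.frame(i = integer(), j = integer()),
                 threshold = threshold, min_seq_sep = min_seq_sep),
            class = "contact_map")
}

#' Add non-native protein--ligand pairs to a contact map
#'
#' A protein residue i and ligand bead j form a non-native pair when
#' (a) (i, j) is not a native contact, (b) residue i lies within
#' `neighbour_cut` (default 6 Angstrom, bead--bead) of some residue that
#' forms a native contact with the same ligand, and (c) the reference
#' distance between i and j does not exceed `max_ref_dist` (default 10
#' Angstrom), which keeps the attractive non-native wells out of the native
#' well region.
#'
#' @param contacts A `contact_map` with native contacts built.
#' @param closed The closed reference `cg_structure` the map was built from.
#' @param neighbour_cut,max_ref_dist Rule thresholds in Angstrom.
#' @return The updated `contact_map`.
#' @export
build_nonnative_pairs <- function(contacts, closed, neighbour_cut = 6,
                                  max_ref_dist = 10) {
  X <- closed$coords
  nat <- contacts$native
  pl <- nat[nat$class == "protein-ligand", , drop = FALSE]
  lidx <- ligand_idx(closed)
  pidx <- protein_idx(closed)
  rows <- list()
  for (kind in unique(closed$role[lidx])) {
    lk <- which(closed$role == kind)
    natk <- pl[pl$j %in% lk, , drop = FALSE]
    anchor <- unique(natk$i)
    if (!length(anchor)) next
    # residues within neighbour_cut of any native-contact-forming residue
    eligible <- pidx[vapply(pidx, function(i) {
      min(sqrt(colSums((t(X[anchor, , drop = FALSE]) - X[i, ])^2))) <=
        neighbour_cut
    }, logical(1))]
    for (i in eligible) {
      for (j in lk) {
        if (any(natk$i == i & natk$j == j)) next
        d <- sqrt(sum((X[i, ] - X[j, ])^2))
        if (d <= max_ref_dist)
          rows[[length(rows) + 1L]] <- data.frame(i = i, j = j)
      }
    }
  }
  nn <- if (length(rows)) do.call(rbind, rows)
        else data.frame(i = integer(), j = integer())
  # invariant: disjoint from native pairs
  if (nrow(nn)) {
    key_nat <- paste(nat$i, nat$j)
    if (any(paste(nn$i, nn$j) %in% key_nat))
      stop("internal error: non-native pair duplicates a native contact")
  }
  contacts$nonnative <- nn
  contacts$neighbour_cut <- neighbour_cut
  contacts$max_ref_dist <- max_ref_dist
  contacts
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d native (%s), %d non-native pairs\n",
              nrow(x$native),
              paste(names(table(x$native$class)), table(x$native$class),
                    sep = ":", collapse = " "),
              nrow(x$nonnative)))
  invisible(x)
}
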