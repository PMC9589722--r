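test_that("load_reference_pair places one bead per residue at the CA position", {
  set.seed(21)
  coords <- matrix(rnorm(30, sd = 6), 10, 3)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_fake_pdb(f1, coords)
  write_fake_pdb(f2, coords + 1)   # rigid shift, same residues
  pair <- load_reference_pair(f1, f2)
  expect_equal(sum(pair$closed$role == "protein"), 10L)
  expect_equal(sum(pair$open$role == "protein"), 10L)
  expect_equal(pair$closed$coords, coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(pair$closed$conformer, "closed")
  expect_equal(pair$open$conformer, "open")
})

test_that("a residue without a CA atom is a hard error naming the residue", {
  set.seed(22)
  coords <- matrix(rnorm(30, sd = 6), 10, 3)
  f1 <- tempfile(fileext = ".pdb")
  write_fake_pdb(f1, coords, skip_ca = 5L)
  expect_error(load_reference_pair(f1, f1), "residue 5")
})

test_that("a residue-count mismatch between references is a hard error", {
  set.seed(23)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_fake_pdb(f1, matrix(rnorm(30, sd = 6), 10, 3))
  write_fake_pdb(f2, matrix(rnorm(27, sd = 6), 9, 3))
  expect_error(load_reference_pair(f1, f2), "mismatch")
})

test_that("ligand coarse-graining gives 5 beads for AMP and 7 for ATP", {
  amp <- map_ligand_beads(fake_amp_atoms(), "AMP")
  expect_equal(nrow(amp$coords), 5L)
  atp <- map_ligand_beads(fake_atp_atoms(), "ATP")
  expect_equal(nrow(atp$coords), 7L)
  # deterministic
  expect_identical(amp$coords, map_ligand_beads(fake_amp_atoms(), "AMP")$coords)
})

test_that("ligand bead mapping is translation-equivariant", {
  v <- c(3.2, -1.5, 7.9)
  b0 <- map_ligand_beads(fake_amp_atoms(), "AMP")$coords
  b1 <- map_ligand_beads(fake_amp_atoms(shift = v), "AMP")$coords
  expect_equal(b1, sweep(b0, 2, v, "+"), tolerance = 1e-12)
})

test_that("a missing moiety is an error naming the group", {
  at <- fake_amp_atoms()
  at <- at[!at$elety %in% c("P", "O1P", "O2P", "O3P"), ]
  expect_error(map_ligand_beads(at, "AMP"), "alphaP")
})

test_that("contact threshold separates 6.4 from 6.6 Angstrom pairs", {
  mk <- function(d) {
    cg_structure(rbind(c(0, 0, 0), c(d, 0, 0)), rep("protein", 2),
                 residue_index = c(1L, 10L),
                 domain = c("CORE", "CORE"), conformer = "closed")
  }
  expect_equal(nrow(build_native_contacts(mk(6.4))$native), 1L)
  expect_equal(nrow(build_native_contacts(mk(6.6))$native), 0L)
})

test_that("contact map equals the brute-force all-pairs oracle", {
  tc <- toy_complex()
  cm <- build_native_contacts(tc$closed)
  oracle <- oracle_contacts(tc$closed)
  expect_equal(nrow(cm$native), nrow(oracle))
  got <- cm$native[order(cm$native$i, cm$native$j), c("i", "j")]
  want <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(want))
})

test_that("contact detection ignores heavy-atom ordering within a residue", {
  set.seed(31)
  coords <- rbind(c(0, 0, 0), c(8, 0, 0))
  heavy <- list(matrix(rnorm(9, sd = 1), 3, 3),
                matrix(rnorm(9, sd = 1) + c(7, 0, 0), 3, 3))
  mk <- function(perm) {
    cg_structure(coords, rep("protein", 2), residue_index = c(1L, 9L),
                 domain = c("CORE", "CORE"), conformer = "closed",
                 heavy = list(heavy[[1]][perm, ], heavy[[2]]))
  }
  a <- build_native_contacts(mk(1:3))$native
  b <- build_native_contacts(mk(3:1))$native
  expect_equal(a, b)
})

test_that("non-native pairs obey both eligibility rules and avoid native pairs", {
  # bead 1 forms the only native ligand contact (anchor); bead 2 is within
  # 6 A of it and inside 10 A of the ligand (non-native pair); bead 3 is
  # 7 A from the anchor (ineligible); bead 4 is within 6 A of the anchor
  # but more than 10 A from the ligand (excluded by the overlap rule)
  X <- rbind(c(0, 0, 0),       # 1: anchor residue
             c(0, 5.5, 0),     # 2: eligible, ligand distance 8.4
             c(0, -7, 0),      # 3: 7 A from the anchor
             c(-5.9, 0, 0),    # 4: eligible, ligand distance 12.3
             c(6.4, 0, 0),     # ligand bead 1 (6.4 A from anchor: native)
             c(60, 0, 0), c(63, 0, 0), c(66, 0, 0), c(69, 0, 0))
  st <- cg_structure(X, c(rep("protein", 4), rep("ligand:AMP", 5)),
                     residue_index = c(1L, 5L, 9L, 13L, 1:5),
                     domain = c(rep("CORE", 4), rep(NA, 5)),
                     conformer = "closed")
  cm <- build_native_contacts(st)
  expect_true(any(cm$native$i == 1 & cm$native$j == 5))
  cm <- build_nonnative_pairs(cm, st)
  nn <- cm$nonnative
  expect_true(any(nn$i == 2 & nn$j == 5))    # eligible and in range
  expect_false(any(nn$i == 3))               # 7 A from native residue
  expect_false(any(nn$i == 4))               # 12.3 A from ligand (> 10)
  expect_false(any(paste(nn$i, nn$j) %in% paste(cm$native$i, cm$native$j)))
})

test_that("non-native list equals brute-force application of both rules", {
  tc <- toy_complex()
  cm <- build_nonnative_pairs(build_native_contacts(tc$closed), tc$closed)
  X <- tc$closed$coords
  nat <- cm$native[cm$native$class == "protein-ligand", ]
  lidx <- which(startsWith(tc$closed$role, "ligand"))
  pidx <- which(tc$closed$role == "protein")
  anchors <- unique(nat$i)
  brute <- NULL
  for (i in pidx) {
    near <- min(sqrt(colSums((t(X[anchors, , drop = FALSE]) - X[i, ])^2)))
    if (near > 6) next
    for (j in lidx) {
      if (any(nat$i == i & nat$j == j)) next
      if (sqrt(sum((X[i, ] - X[j, ])^2)) <= 10) brute <- rbind(brute, c(i, j))
    }
  }
  got <- as.matrix(cm$nonnative[order(cm$nonnative$i, cm$nonnative$j), ])
  want <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("domain assignment validates coverage and rejects overlaps", {
  st <- cg_structure(matrix(rnorm(180), 60, 3), rep("protein", 60))
  ranges <- list(CORE = c(1:20, 41:60), NMP = 21:30, LID = 31:40)
  st2 <- assign_domains(st, ranges)
  expect_equal(unname(table(st2$domain)[c("CORE", "LID", "NMP")]),
               c(40L, 10L, 10L), ignore_attr = TRUE)
  expect_error(assign_domains(st, list(CORE = 1:30, NMP = 25:60)), "overlap")
  expect_error(assign_domains(st, list(CORE = 1:30, NMP = 31:50)), "uncovered")
})

test_that("default adenylate-kinase ranges give three nonempty domains", {
  st <- cg_structure(matrix(rnorm(3 * 214), 214, 3), rep("protein", 214))
  st <- assign_domains(st, adk_domain_ranges())
  tb <- table(st$domain)
  expect_setequal(names(tb), c("CORE", "LID", "NMP"))
  expect_true(all(tb > 0))
  expect_equal(sum(tb), 214L)
})

test_that("native and non-native pair lists are always disjoint", {
  for (eps in c(0, 0.5)) {
    topo <- study_system(eps)$topology
    nat <- topo$contacts[topo$contacts$basin == "closed", ]
    nn <- as.data.frame(topo$core$nonnative$ij)
    expect_false(any(paste(nn[, 1], nn[, 2]) %in% paste(nat$i, nat$j)))
  }
})

test_that("topology JSON roundtrip preserves the interaction lists", {
  tc <- toy_complex()
  f <- tempfile(fileext = ".json")
  write_topology_json(tc$topology, f)
  back <- read_topology_json(f)
  expect_equal(back$core$shared_contacts$ij, tc$topology$core$shared_contacts$ij)
  expect_equal(back$core$nonnative$ij, tc$topology$core$nonnative$ij)
  expect_equal(back$params$eps_nat, tc$topology$params$eps_nat)
})
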