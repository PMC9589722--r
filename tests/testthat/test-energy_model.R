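test_that("double-basin mixing reproduces its closed-form values", {
  expect_equal(multi_basin_mix(-10, -10, 0, 2)$energy, -12)
  expect_equal(multi_basin_mix(-5, -3, 0, 0)$energy, -5)   # min at Delta = 0
  expect_equal(multi_basin_mix(0, -4, 0, 1)$energy, -2 - sqrt(5))
  expect_error(multi_basin_mix(0, 0, 0, -1), "coupling")
})

test_that("mixed energy never exceeds either basin; equality only at Delta = 0", {
  grid <- expand.grid(V1 = c(-20, -5, 0, 3), V2 = c(-15, -2, 1),
                      dV = c(-3, 0, 2), D = c(0, 0.5, 2))
  for (q in seq_len(nrow(grid))) {
    g <- grid[q, ]
    m <- multi_basin_mix(g$V1, g$V2, g$dV, g$D)$energy
    lo <- min(g$V1, g$V2 + g$dV)
    expect_lte(m, lo + 1e-12)
    if (g$D == 0) expect_equal(m, lo)
    if (g$D > 0) expect_lt(m, lo)
  }
})

test_that("pair potentials match their defining values", {
  expect_equal(ligand_native_term(4.2, 4.2, 0.15), -0.15)
  expect_lt(abs(ligand_native_term(1e4, 4.2, 0.15)), 1e-12)
  opt <- optimize(ligand_native_term, c(2, 12), r0 = 5.3, eps = 0.15,
                  tol = 1e-10)
  expect_equal(opt$minimum, 5.3, tolerance = 1e-6)

  expect_identical(ligand_nonnative_term(c(0, 3, 50), 0), c(0, 0, 0))
  expect_equal(ligand_nonnative_term(0, 0.4), -0.4)
  expect_equal(ligand_nonnative_term(6, 1, 6), -exp(-0.5))
  r <- seq(0.1, 30, by = 0.1)
  expect_true(all(diff(ligand_nonnative_term(r, 0.3)) > 0))  # monotone up

  expect_equal(excluded_volume_term(5, 5, 1), 1)
  expect_equal(excluded_volume_term(10, 5, 1), 1 / 4096)
  expect_lt(excluded_volume_term(1e3, 5), 1e-25)
})

test_that("the closed reference is the shared-contact minimum with zero bonded strain", {
  topo <- toy_complex()$topology
  E <- single_basin_energy(topo$closed, topo, "closed")
  # softened hinge-spanning bonds (mean reference) carry a tiny residual
  expect_lt(E$bond, 0.01)
  expect_lt(E$angle, 1e-9)
  expect_lt(abs(E$dihedral), 1e-9)
  # every 12-10 term sits at its (shift-corrected) minimum
  sc <- topo$core$shared_contacts
  expect_equal(E$contacts_shared, -sum(sc$b), tolerance = 2e-3)
})

test_that("analytic forces agree with central finite differences", {
  topo <- study_system(0.4)$topology
  set.seed(77)
  X <- topo$closed + matrix(rnorm(3 * topo$n, sd = 0.08), topo$n, 3)
  expect_lt(force_check(X, topo, idx = sample(topo$n, 12)), 1e-5)
})

test_that("forces remain exact gradients under restraints", {
  topo <- toy_complex()$topology
  set.seed(78)
  X <- topo$closed + matrix(rnorm(3 * topo$n, sd = 0.05), topo$n, 3)
  res <- list(
    flat_bottom_restraint_spec(61:65, 1:10, K = 3, r0 = 1),
    rmsd_restraint_spec(topo$protein_idx, topo$open, k = 0.5),
    xi_bias_spec(topo, center = -0.4, k = 50))
  expect_lt(force_check(X, topo, restraints = res, idx = c(1, 5, 30, 61, 65)),
            1e-5)
})

test_that("moving a non-interacting distant bead leaves the energy unchanged", {
  topo <- toy_complex()$topology
  X <- topo$closed
  lig <- which(startsWith(topo$role, "ligand"))
  X[lig, ] <- X[lig, ] + 1e4
  e0 <- total_energy(X, topo)$total
  X2 <- X
  X2[lig[1], ] <- X2[lig[1], ] + c(5, -3, 2)
  e1 <- total_energy(X2, topo)$total
  # only the ligand's internal restraints change; protein terms identical
  X2[lig, ] <- X[lig, ] + 50
  expect_equal(total_energy(X2, topo)$total, e0, tolerance = 1e-10)
})

test_that("removing the ligand reduces the total to the apo energy", {
  topo <- toy_complex()$topology
  set.seed(79)
  Xp <- topo$closed[topo$protein_idx, ] +
    matrix(rnorm(3 * length(topo$protein_idx), sd = 0.05),
           length(topo$protein_idx), 3)
  ea <- apo_energy(Xp, topo)
  X <- topo$closed
  X[topo$protein_idx, ] <- Xp
  lig <- which(startsWith(topo$role, "ligand"))
  X[lig, ] <- X[lig, ] + 1e4
  et <- total_energy(X, topo)
  expect_equal(et$bond + et$angle + et$dihedral - ea$bond - ea$angle -
                 ea$dihedral, 0, tolerance = 1e-9)
  expect_equal(ea$contacts_shared,
               et$contacts_shared, tolerance = 1e-9)
})

test_that("doubling eps_nnat exactly doubles the summed non-native energy", {
  sys <- study_system(0.25)
  topo <- sys$topology
  set.seed(80)
  X <- topo$closed + matrix(rnorm(3 * topo$n, sd = 0.3), topo$n, 3)
  e1 <- total_energy(X, topo,
                     update_params(topo$params, eps_nnat = 0.25))$nonnative
  e2 <- total_energy(X, topo,
                     update_params(topo$params, eps_nnat = 0.5))$nonnative
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("total energy is invariant under rigid rotation and translation", {
  topo <- toy_complex()$topology
  set.seed(81)
  X <- topo$closed + matrix(rnorm(3 * topo$n, sd = 0.1), topo$n, 3)
  e0 <- total_energy(X, topo)$total
  th <- 0.83; ax <- c(1, 2, -1) / sqrt(6)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  X2 <- sweep(X %*% t(R), 2, c(12, -7, 3), "+")
  expect_equal(total_energy(X2, topo)$total, e0, tolerance = 1e-8)
})

test_that("energy is continuous along the closed-to-open morph", {
  topo <- toy_complex()$topology
  p <- topo$protein_idx
  lam <- seq(0, 1, length.out = 201)
  e <- vapply(lam, function(l) {
    X <- topo$closed
    X[p, ] <- (1 - l) * topo$closed[p, ] + l * topo$open
    total_energy(X, topo)$total
  }, numeric(1))
  expect_true(all(is.finite(e)))
  # no jump anywhere near the truncation boundaries
  expect_lt(max(abs(diff(e))), max(abs(diff(range(e)))) * 0.08)
})

test_that("interface components reduce to the closed basin when deltaV is large", {
  topo <- toy_complex()$topology
  p_hi <- update_params(topo$params, deltaV = rep(1e4, 1),
                        coupling_delta = rep(0, 1))
  E <- total_energy(topo$closed, topo, p_hi)
  Ec <- single_basin_energy(topo$closed, topo, "closed")
  expect_equal(unlist(E$interface_mixed), unlist(Ec$interface_mixed),
               tolerance = 1e-9)
})
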