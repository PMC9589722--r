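rot_mat <- function(th, ax) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

test_that("kabsch RMSD is zero for identical and rigidly moved sets", {
  set.seed(41)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-10)
  Y <- sweep(X %*% t(rot_mat(1.1, c(1, 1, 0))), 2, c(4, -2, 9), "+")
  expect_equal(kabsch_rmsd(X, Y), 0, tolerance = 1e-9)
  expect_equal(kabsch_rmsd(X, Y), kabsch_rmsd(Y, X), tolerance = 1e-9)
})

test_that("kabsch RMSD matches exhaustive minimisation over rotations", {
  set.seed(42)
  for (rep in 1:2) {
    X <- matrix(rnorm(12, sd = 2), 4, 3)
    Y <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- kabsch_rmsd(X, Y)
    # oracle: numerical minimisation over Euler angles from many starts
    obj <- function(par) {
      R <- rot_mat(par[1], c(1, 0, 0)) %*% rot_mat(par[2], c(0, 1, 0)) %*%
        rot_mat(par[3], c(0, 0, 1))
      Yr <- sweep(Y, 2, colMeans(Y)) %*% t(R)
      sqrt(mean(rowSums((sweep(X, 2, colMeans(X)) - Yr)^2)))
    }
    best <- Inf
    for (s in 1:12) {
      o <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
      best <- min(best, o$value)
    }
    expect_equal(got, best, tolerance = 1e-3)
  }
})

test_that("degenerate collinear subsets are rejected", {
  X <- cbind(1:4, 0, 0)
  expect_error(kabsch_rmsd(X, X + 1), "degenerate|collinear")
})

test_that("xi is -1 at the closed reference and +1 at the open reference", {
  topo <- toy_complex()$topology
  p <- topo$protein_idx
  expect_equal(xi(topo$closed[p, ], topo$closed[p, ], topo$open), -1)
  expect_equal(xi(topo$open, topo$closed[p, ], topo$open), 1)
  expect_error(xi(topo$open, topo$open, topo$open), "RMSD_CO")
})

test_that("xi stays within [-1, 1] along a morph and vanishes at the midpoint", {
  topo <- toy_complex()$topology
  p <- topo$protein_idx
  lam <- seq(0, 1, length.out = 41)
  xs <- vapply(lam, function(l) {
    xi((1 - l) * topo$closed[p, ] + l * topo$open, topo$closed[p, ],
       topo$open)
  }, numeric(1))
  expect_true(all(xs >= -1 - 1e-9 & xs <= 1 + 1e-9))
  expect_equal(xs[21], 0, tolerance = 0.05)
  expect_true(all(diff(xs) > 0))
})

test_that("Q counts formed contacts with the 1.2 r0 cutoff", {
  topo <- toy_complex()$topology
  ct <- ligand_contacts(topo, "AMP")
  expect_equal(fraction_native_contacts(topo$closed, ct), 1.0)
  X <- topo$closed
  lig <- which(startsWith(topo$role, "ligand"))
  X[lig, ] <- X[lig, ] + 1e4
  expect_equal(fraction_native_contacts(X, ct), 0.0)
  expect_error(fraction_native_contacts(X, ct[0, ]), "empty")
})

test_that("a constructed half-stretched configuration gives Q = 0.5", {
  n <- 10
  X <- rbind(cbind(seq_len(n) * 10, 0, 0),          # protein beads, far apart
             cbind(seq_len(n) * 10, 3, 0))          # ligand beads at 3 A
  contacts <- data.frame(i = 1:n, j = n + 1:n, r0 = rep(3, n))
  X2 <- X
  X2[n + 1:(n / 2), 2] <- 9                          # stretch half to 3 r0
  expect_equal(fraction_native_contacts(X2, contacts), 0.5)
  # smooth variant agrees in the well-separated limit
  expect_equal(fraction_native_contacts_smooth(X2, contacts, beta = 50), 0.5,
               tolerance = 1e-3)
})

test_that("Q decreases monotonically as the ligand is pulled out", {
  topo <- toy_complex()$topology
  ct <- ligand_contacts(topo, "AMP")
  lig <- which(startsWith(topo$role, "ligand"))
  qs <- vapply(seq(0, 30, by = 1.5), function(d) {
    X <- topo$closed
    X[lig, 3] <- X[lig, 3] + d      # pull along the pocket normal
    fraction_native_contacts(X, ct)
  }, numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
  expect_equal(qs[1], 1)
  expect_equal(qs[length(qs)], 0)
})

test_that("pose coordinates are (0, 0) at the native pose", {
  topo <- toy_complex()$topology
  pc <- pose_coordinates(topo$closed, topo, "AMP")
  expect_equal(pc$R, 0, tolerance = 1e-9)
  expect_equal(pc$theta, 0, tolerance = 1e-6)
})

test_that("a rigid 5 A translation of the ligand gives R = 5, theta = 0", {
  topo <- toy_complex()$topology
  X <- topo$closed
  lig <- which(startsWith(topo$role, "ligand"))
  X[lig, ] <- X[lig, ] + matrix(c(3, 0, 4), length(lig), 3, byrow = TRUE)
  pc <- pose_coordinates(X, topo, "AMP")
  expect_equal(pc$R, 5, tolerance = 1e-9)
  expect_equal(pc$theta, 0, tolerance = 1e-9)
})

test_that("a 180-degree flip about a perpendicular axis gives theta = pi", {
  topo <- toy_complex()$topology
  X <- topo$closed
  lig <- which(startsWith(topo$role, "ligand"))
  X[lig, ] <- perturb_pose(topo$closed[lig, ], "flip180")
  pc <- pose_coordinates(X, topo, "AMP")
  expect_equal(pc$theta, pi, tolerance = 1e-6)
})

test_that("pose coordinates ignore rigid motion of the whole complex", {
  topo <- toy_complex()$topology
  X <- sweep(topo$closed %*% t(rot_mat(0.7, c(0, 1, 1))), 2, c(5, 5, -8), "+")
  pc <- pose_coordinates(X, topo, "AMP")
  expect_equal(pc$R, 0, tolerance = 1e-8)
  expect_equal(pc$theta, 0, tolerance = 1e-4)
})

test_that("interdomain distance is the centroid distance, translation-invariant", {
  topo <- toy_complex()$topology
  d0 <- interdomain_distance(topo$closed, topo, "LID", "CORE")
  core <- which(topo$domain == "CORE" & topo$role == "protein")
  lid <- which(topo$domain == "LID" & topo$role == "protein")
  hand <- sqrt(sum((colMeans(topo$closed[core, ]) -
                      colMeans(topo$closed[lid, ]))^2))
  expect_equal(d0, hand, tolerance = 1e-10)
  expect_equal(interdomain_distance(topo$closed + 7, topo, "LID", "CORE"), d0,
               tolerance = 1e-10)
  expect_error(interdomain_distance(topo$closed, topo, "LID", "NOPE"), "empty")
})
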