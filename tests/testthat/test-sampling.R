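# 1D umbrella windows on a polynomial potential, as umbrella_window objects
umbrella_1d <- function(coeffs, centers, k, kT = 1, n_steps = 20000,
                        dt = 0.02, seed = 1, discard = 0.25) {
  lapply(seq_along(centers), function(w) {
    r <- run_langevin_1d(coeffs, x0 = centers[w], kT = kT, gamma = 1, dt = dt,
                         n_steps = n_steps, stride = 10, seed = seed + w,
                         bias_k = k, bias_center = centers[w])
    xs <- r$x
    structure(list(center = centers[w], k = k,
                   samples = xs[seq_along(xs) > discard * length(xs)],
                   all_samples = xs, discard_fraction = discard),
              class = "umbrella_window")
  })
}

test_that("the default umbrella grid has 41 windows ending exactly at -1 and 1", {
  cen <- umbrella_centers()
  expect_length(cen, 41L)
  expect_identical(cen[1], -1)
  expect_identical(cen[41], 1)
  expect_equal(unique(round(diff(cen), 10)), 0.05)
})

test_that("MBAR recovers a harmonic free-energy profile within bootstrap error", {
  k_pot <- 1.5; kT <- 1
  wins <- umbrella_1d(c(0, 0, k_pot / 2), centers = seq(-2, 2, by = 0.4),
                      k = 8, kT = kT, n_steps = 15000, seed = 101)
  prof <- reweight_pmf(wins, temperature = 1 / 0.0019872041, bins = 24,
                       n_boot = 15)
  ref <- 0.5 * k_pot * prof$x^2 / kT
  ref <- ref - min(ref)
  keep <- abs(prof$x) < 1.6
  dev <- abs(prof$F - ref)[keep]
  expect_lt(median(dev), 0.25)
  expect_true(mean(dev < 3 * prof$err[keep] + 0.15) > 0.9)
})

test_that("a flat potential reweights to a flat profile", {
  wins <- umbrella_1d(c(0), centers = seq(-1, 1, by = 0.25), k = 10,
                      n_steps = 30000, seed = 55)
  prof <- reweight_pmf(wins, temperature = 1 / 0.0019872041, bins = 16,
                       n_boot = 10)
  keep <- abs(prof$x) < 0.9
  expect_lt(max(prof$F[keep], na.rm = TRUE), 0.5)
})

test_that("a single unbiased window reduces to the log-histogram", {
  r <- run_langevin_1d(c(0, 0, 0.5), kT = 1, gamma = 1, dt = 0.02,
                       n_steps = 40000, stride = 10, seed = 77)
  w <- structure(list(center = 0, k = 0, samples = r$x[-(1:1000)],
                      all_samples = r$x, discard_fraction = 0),
                 class = "umbrella_window")
  prof <- reweight_pmf(list(w), temperature = 1 / 0.0019872041, bins = 20,
                       n_boot = 5)
  h <- hist(w$samples, breaks = seq(min(w$samples), max(w$samples),
                                    length.out = 21), plot = FALSE)
  ref <- -log(h$counts)
  ref <- ref - min(ref[is.finite(ref)])
  ok <- is.finite(ref) & !is.na(prof$F)
  expect_equal(prof$F[ok], ref[ok], tolerance = 1e-6)
})

test_that("the reweighting solver agrees with plain fixed-point iteration", {
  wins <- umbrella_1d(c(0, 0, 0.75), centers = seq(-1.5, 1.5, by = 0.75),
                      k = 6, n_steps = 8000, seed = 31)
  kT <- 1
  prof <- reweight_pmf(wins, temperature = 1 / 0.0019872041, bins = 12,
                       n_boot = 2)
  f_pkg <- attr(prof, "f_k")
  # independent route: the textbook self-consistent iteration, run from
  # scratch until convergence
  x <- unlist(lapply(wins, `[[`, "samples"))
  N_k <- lengths(lapply(wins, `[[`, "samples"))
  U <- vapply(seq_along(wins), function(kk) {
    0.5 * wins[[kk]]$k * (x - wins[[kk]]$center)^2 / kT
  }, numeric(length(x)))
  f <- numeric(length(wins))
  for (it in 1:20000) {
    A <- sweep(-U, 2, f + log(N_k), "+")
    amax <- apply(A, 1, max)
    logden <- amax + log(rowSums(exp(A - amax)))
    fnew <- vapply(seq_along(wins), function(kk) {
      v <- -U[, kk] - logden
      m <- max(v)
      -(m + log(sum(exp(v - m))))
    }, numeric(1))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < 1e-10) { f <- fnew; break }
    f <- fnew
  }
  expect_lt(max(abs(f_pkg - f)), 1e-6)
})

test_that("the profile is stable under removing every second sample", {
  wins <- umbrella_1d(c(0, 0, 1), centers = seq(-1.5, 1.5, by = 0.5), k = 8,
                      n_steps = 12000, seed = 91)
  prof1 <- reweight_pmf(wins, temperature = 1 / 0.0019872041, bins = 15,
                        n_boot = 5)
  wins2 <- lapply(wins, function(w) {
    w$samples <- w$samples[c(TRUE, FALSE)]
    w
  })
  prof2 <- reweight_pmf(wins2, temperature = 1 / 0.0019872041,
                        bins = seq(min(prof1$x) - 0.11, max(prof1$x) + 0.11,
                                   length.out = 16), n_boot = 5)
  ok <- !is.na(prof1$F) & !is.na(prof2$F)
  expect_lt(median(abs(prof1$F - prof2$F)[ok]), 0.3)
})

test_that("window means sit between the bias centre and the unbiased minimum", {
  wins <- umbrella_1d(c(0, 0, 1), centers = c(-1, 1), k = 4,
                      n_steps = 10000, seed = 61)
  for (w in wins) {
    m <- mean(w$samples)
    expect_true(m > min(w$center, 0) - 0.15 && m < max(w$center, 0) + 0.15)
    expect_true(abs(m) < abs(w$center))   # pulled toward the minimum
  }
})

test_that("doubling the bias constant roughly halves the window variance", {
  v <- vapply(c(8, 16), function(k) {
    w <- umbrella_1d(c(0), centers = 0, k = k, n_steps = 30000, seed = 71)
    var(w[[1]]$samples)
  }, numeric(1))
  expect_equal(v[1] / v[2], 2, tolerance = 0.3)
})

test_that("2D histogram landscapes behave for uniform and Gaussian samples", {
  set.seed(201)
  # uniform: flat within noise
  a <- runif(40000); b <- runif(40000)
  flat <- pmf_2d(a, b, bins = 6)
  expect_lt(max(flat$F, na.rm = TRUE), 0.35)
  # independent standard gaussians: quadratic bowl, no cross-term
  a <- rnorm(60000); b <- rnorm(60000)
  pg <- pmf_2d(a, b, bins = list(seq(-2, 2, 0.5), seq(-2, 2, 0.5)))
  xs <- rep(pg$x, times = length(pg$y))
  ys <- rep(pg$y, each = length(pg$x))
  Fv <- as.vector(pg$F)
  fit <- lm(Fv ~ I(xs^2) + I(ys^2) + I(xs * ys))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.1)
  expect_equal(unname(coef(fit)[3]), 0.5, tolerance = 0.1)
  expect_lt(abs(unname(coef(fit)[4])), 0.05)
})

test_that("1D barrier heights match closed forms", {
  x <- seq(-1.6, 1.6, length.out = 161)
  Fq <- 3 * (x^2 - 1)^2
  prof <- structure(data.frame(x = x, F = Fq - min(Fq), err = 0),
                    class = c("free_energy_profile", "data.frame"))
  expect_equal(barrier_height(prof, c(-1.3, -0.7), c(0.7, 1.3)), 3,
               tolerance = 1e-6)
  down <- structure(data.frame(x = x, F = rev(seq_along(x)) * 0.01, err = 0),
                    class = c("free_energy_profile", "data.frame"))
  # monotone downhill toward the second basin: no barrier at all
  expect_equal(barrier_height(down, c(-1.6, -1.2), c(1.2, 1.6)), 0,
               tolerance = 1e-9)
})

test_that("2D minimax barrier matches exhaustive path enumeration", {
  set.seed(202)
  Fm <- matrix(runif(16, 0, 4), 4, 4)
  Fm[1, 1] <- 0; Fm[4, 4] <- 0.2
  prof <- list(x = 1:4, y = 1:4, F = Fm)
  got <- barrier_height(prof, list(x = c(1, 1), y = c(1, 1)),
                        list(x = c(4, 4), y = c(4, 4)))
  # oracle: enumerate all simple paths with DFS, minimise the maximum
  best <- Inf
  dfs <- function(i, j, seen, mx) {
    mx <- max(mx, Fm[i, j])
    if (mx >= best) return()
    if (i == 4 && j == 4) { best <<- mx; return() }
    seen[i, j] <- TRUE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4 && !seen[ii, jj])
        dfs(ii, jj, seen, mx)
    }
  }
  dfs(1, 1, matrix(FALSE, 4, 4), 0)
  expect_equal(got, best - Fm[1, 1], tolerance = 1e-9)
})

test_that("PaCS selection never loses the incumbent and ranks the pool", {
  tc <- toy_complex()
  topo <- tc$topology
  target <- topo$open
  st <- thermalize(simulation_state(topo$closed, seed = 30), 300)
  res <- pacs_cycle(list(st), topo, target, n_replicas = 1,
                    steps_per_replica = 300, stride = 100, seed = 5)
  expect_equal(res$best_rmsd, min(res$pool_rmsd))
  start_rmsd <- kabsch_rmsd(st$coords[topo$protein_idx, ], target)
  expect_lte(res$best_rmsd, start_rmsd + 1e-9)
})

test_that("a PaCS run toward the start converges immediately and best RMSD never rises", {
  tc <- toy_complex()
  topo <- tc$topology
  st <- thermalize(simulation_state(topo$closed, seed = 31), 300)
  self <- pacs_run(st, topo, topo$closed[topo$protein_idx, ], n_cycles = 3,
                   n_replicas = 2, steps_per_replica = 200, rmsd_stop = 0.5,
                   seed = 7)
  expect_true(self$converged)
  expect_equal(self$n_cycles_run, 1L)
  toward_open <- pacs_run(st, topo, topo$open, n_cycles = 6, n_replicas = 3,
                          steps_per_replica = 400, rmsd_stop = 0.1, seed = 8)
  expect_true(all(diff(toward_open$best_rmsd) <= 1e-12))
})

test_that("PaCS reaches the open basin faster than unbiased dynamics", {
  tc <- toy_complex()
  topo <- tc$topology
  target <- topo$open
  n_rep <- 6
  pacs_best <- unb_best <- numeric(n_rep)
  for (q in seq_len(n_rep)) {
    st <- thermalize(simulation_state(topo$closed, seed = 500 + q), 300)
    pr <- pacs_run(st, topo, target, n_cycles = 6, n_replicas = 4,
                   steps_per_replica = 500, stride = 250, rmsd_stop = 0,
                   seed = 900 + q)
    pacs_best[q] <- min(pr$best_rmsd)
    # unbiased control with the same total sampling (6 cycles x 4 x 500)
    tr <- run_trajectory(st, topo, n_steps = 12000, stride = 250)
    unb_best[q] <- min(rmsd_frames_cpp(tr$frames, target, topo$protein_idx))
  }
  expect_lt(mean(pacs_best), mean(unb_best))
})

test_that("targeted MD with k = 0 is identical to unbiased dynamics", {
  topo <- toy_complex()$topology
  st <- thermalize(simulation_state(topo$closed, seed = 33), 300)
  a <- targeted_md(st, topo, topo$open, k = 0, n_steps = 300, stride = 100)
  b <- run_trajectory(st, topo, n_steps = 300, stride = 100)
  expect_identical(a$frames, b$frames)
})

test_that("stiff targeted MD pins the structure near its reference", {
  topo <- toy_complex()$topology
  ref <- topo$closed[topo$protein_idx, ]
  st <- thermalize(simulation_state(topo$closed, seed = 34), 300)
  tr <- targeted_md(st, topo, ref, k = 239, n_steps = 3000, stride = 100)
  rms <- rmsd_frames_cpp(tr$frames, ref, topo$protein_idx)
  expect_lt(max(rms[-1]), 0.4)
  # restraint variance shrinks monotonically over a k grid
  vs <- vapply(c(2, 20, 200), function(k) {
    tr <- targeted_md(st, topo, ref, k = k, n_steps = 2000, stride = 50)
    mean(rmsd_frames_cpp(tr$frames, ref, topo$protein_idx)[-(1:10)]^2)
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
})
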