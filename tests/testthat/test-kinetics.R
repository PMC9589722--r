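mk_obs <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  cbind(data.frame(time = seq_len(n) * 10), as.data.frame(cols))
}

test_that("Q-based binding succeeds at the first frame when both ligands qualify", {
  obs <- mk_obs(Q_ATP = rep(0.8, 20), Q_AMP = rep(0.8, 20))
  bs <- binding_success(obs, "Q")
  expect_true(bs$success)
  expect_equal(bs$time, obs$time[1])
  # one ligand below threshold blocks success
  obs$Q_AMP <- rep(0.6, 20)
  expect_false(binding_success(obs, "Q")$success)
})

test_that("pose-based binding respects the 3 A / 0.4 rad thresholds and dwell", {
  n <- 40
  obs <- mk_obs(R_AMP = rep(3.1, n), theta_AMP = rep(0.2, n))
  expect_false(binding_success(obs, "pose", kinds = "AMP")$success)
  obs$R_AMP <- rep(2, n)
  expect_true(binding_success(obs, "pose", kinds = "AMP")$success)
  # exactly dwell frames of compliance, stamped at the interval start
  r <- rep(5, n); th <- rep(1, n)
  r[11:20] <- 2; th[11:20] <- 0.2
  obs <- mk_obs(R_AMP = r, theta_AMP = th)
  bs <- binding_success(obs, "pose", kinds = "AMP", dwell = 10)
  expect_true(bs$success)
  expect_equal(bs$time, obs$time[11])
  expect_false(binding_success(obs, "pose", kinds = "AMP", dwell = 11)$success)
})

test_that("first passage records the event time or censors at the end", {
  obs <- mk_obs(v = c(0, 0, 0, 1, 1))
  rec <- first_passage(obs, function(o) o$v > 0.5)
  expect_true(rec$event)
  expect_equal(rec$duration, obs$time[4] - obs$time[1])
  rec2 <- first_passage(obs, function(o) o$v > 2)
  expect_false(rec2$event)
  expect_equal(rec2$duration, obs$time[5] - obs$time[1])
  # event at the first frame: charged one stride
  rec3 <- first_passage(obs, function(o) rep(TRUE, nrow(o)))
  expect_true(rec3$event)
  expect_equal(rec3$duration, obs$time[2] - obs$time[1])
})

test_that("first passage reproduces a constructed telegraph switch exactly", {
  tg <- make_oracle_system("telegraph", list(rate01 = 0.5, rate10 = 2,
                                             t_end = 50), seed = 5)
  obs <- data.frame(time = tg$times, state = tg$state)
  rec <- first_passage(obs, function(o) o$state == 1L)
  expect_true(rec$event)
  expect_equal(rec$duration, tg$switch_times[1] - tg$times[1])
})

test_that("censored-exponential MLE matches its closed form", {
  recs <- list(list(duration = 1, event = TRUE),
               list(duration = 2, event = TRUE),
               list(duration = 3, event = TRUE))
  expect_equal(mfpt_mle(recs, n_boot = 10)$mfpt, 2.0)
  recs <- list(list(duration = 1, event = TRUE),
               list(duration = 3, event = TRUE),
               list(duration = 5, event = FALSE))
  expect_equal(mfpt_mle(recs, n_boot = 10)$mfpt, 4.5)
  expect_error(mfpt_mle(list(list(duration = 5, event = FALSE))),
               "no passages")
})

test_that("the estimator recovers a known MFPT from censored exponential data", {
  set.seed(91)
  true_mfpt <- 7
  horizon <- 15
  d <- rexp(1e4, 1 / true_mfpt)
  df <- data.frame(duration = pmin(d, horizon), event = d <= horizon)
  est <- mfpt_mle(df, n_boot = 200)
  se <- (est$ci[2] - est$ci[1]) / (2 * 1.96)
  expect_lt(abs(est$mfpt - true_mfpt), 3 * se)
})

test_that("the MFPT estimator is scale-equivariant and censoring-monotone", {
  set.seed(92)
  df <- data.frame(duration = rexp(200, 1 / 3),
                   event = runif(200) < 0.8)
  base <- mfpt_mle(df, n_boot = 2)$mfpt
  scaled <- df; scaled$duration <- scaled$duration * 4.5
  expect_equal(mfpt_mle(scaled, n_boot = 2)$mfpt, 4.5 * base,
               tolerance = 1e-12)
  more <- rbind(df, data.frame(duration = 2, event = FALSE))
  expect_gte(mfpt_mle(more, n_boot = 2)$mfpt, base)
})

test_that("cycle counting with hysteresis matches constructed inputs", {
  # monotone closing: one closing, no completed round trip from closed side
  r <- seq(25, 10, length.out = 50)
  cc <- count_conformation_cycles(r, close_at = 14, open_at = 20)
  expect_equal(cc$n_closings, 1L)
  expect_equal(cc$n_openings, 0L)
  expect_equal(cc$cycles, 0L)
  # square wave with k = 4 full round trips
  r <- rep(c(rep(10, 5), rep(25, 5)), 5)
  cc <- count_conformation_cycles(r, close_at = 14, open_at = 20)
  expect_equal(cc$cycles, 4L)
  # counting stops at t_stop: by frame 22 two full round trips completed
  cc2 <- count_conformation_cycles(r, time = seq_along(r),
                                   close_at = 14, open_at = 20, t_stop = 22)
  expect_equal(cc2$cycles, 2L)
  cc3 <- count_conformation_cycles(r, time = seq_along(r),
                                   close_at = 14, open_at = 20, t_stop = 12)
  expect_equal(cc3$cycles, 1L)
  expect_error(count_conformation_cycles(r, close_at = 20, open_at = 14),
               "below")
})

test_that("hysteresis suppresses threshold chatter", {
  set.seed(93)
  r <- 17 + rnorm(2000, sd = 2.5)   # noise straddling a single threshold
  narrow <- count_conformation_cycles(r, close_at = 16.999, open_at = 17.001)
  wide <- count_conformation_cycles(r, close_at = 12, open_at = 22)
  expect_gt(narrow$cycles, wide$cycles)
})

test_that("contact formation probabilities match constructed trajectories", {
  sys <- study_system(0)
  topo <- sys$topology
  ct <- ligand_contacts(topo, "AMP")
  th <- domain_thresholds(topo, "NMP")
  # synthetic trajectory: open for 30 frames (cap rotated), then closed with
  # the ligand native -> every contact formed at the end of the closing
  hg <- sys$system$hinges$NMP
  Xopen <- topo$closed
  Xopen[hg$idx, ] <- cgbind:::rotate_about_axis(topo$closed[hg$idx, ],
                                                hg$origin, hg$dir,
                                                -60 * pi / 180)
  fr_open <- as.vector(t(Xopen))
  fr_closed <- as.vector(t(topo$closed))
  frames <- rbind(matrix(fr_open, 30, length(fr_open), byrow = TRUE),
                  matrix(fr_closed, 10, length(fr_closed), byrow = TRUE))
  traj <- list(frames = frames)
  prof <- contact_probability_profile(list(traj, traj), topo, "AMP", "NMP",
                                      selector = "first", n_bins = 4)
  expect_equal(attr(prof, "n_used"), 2)
  # CORE-side contacts are formed throughout (ligand stays in the groove);
  # cap-side contacts only form as the domain closes
  is_cap <- topo$domain[ct$i] == "NMP"
  expect_true(all(prof[, !is_cap] == 1))
  expect_gt(mean(prof[4, is_cap]), mean(prof[1, is_cap]))
  # a trajectory whose ligand sits outside the binding area is excluded
  Xfar <- topo$closed
  lk <- which(topo$role == "ligand:AMP")
  Xfar[lk, ] <- Xfar[lk, ] + 40
  Xfar_open <- Xfar
  Xfar_open[hg$idx, ] <- Xopen[hg$idx, ]
  frames2 <- rbind(matrix(as.vector(t(Xfar_open)), 30, ncol(frames),
                          byrow = TRUE),
                   matrix(as.vector(t(Xfar)), 10, ncol(frames), byrow = TRUE))
  prof2 <- contact_probability_profile(list(traj, list(frames = frames2)),
                                       topo, "AMP", "NMP", n_bins = 4)
  expect_equal(attr(prof2, "n_used"), 1)
})
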