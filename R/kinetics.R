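#' Detect successful substrate binding in an observable series
#'
#' Two criteria are implemented:
#' \describe{
#'   \item{`"pose"`}{`R < 0.3` nm (3 Angstrom) and `theta < 0.4` rad
#'     sustained for at least `dwell` consecutive frames.}
#'   \item{`"Q"`}{the fraction of native contacts of every supplied ligand
#'     simultaneously at or above `q_threshold` (default 0.7).}
#' }
#' The success time is the first frame at which the (sustained) condition
#' starts.
#'
#' @param obs Data frame of observable series (from
#'   [trajectory_observables()]), containing `R_<kind>`/`theta_<kind>` or
#'   `Q_<kind>` columns and a `time` column.
#' @param criteria `"Q"` or `"pose"`.
#' @param kinds Ligand kinds the rule applies to (default: all present).
#' @param q_threshold Q threshold. Default 0.7.
#' @param r_max Pose distance threshold in Angstrom. Default 3 (0.3 nm).
#' @param theta_max Pose angle threshold in radians. Default 0.4.
#' @param dwell Number of consecutive frames the pose rule must hold.
#'   Default 10.
#' @return List with `success` (logical) and `time` (first success time, or
#'   `NA` if never).
#' @export
binding_success <- function(obs, criteria = c("Q", "pose"), kinds = NULL,
                            q_threshold = 0.7, r_max = 3, theta_max = 0.4,
                            dwell = 10L) {
  criteria <- match.arg(criteria)
  if (criteria == "Q") {
    cols <- grep("^Q_", names(obs), value = TRUE)
    if (!is.null(kinds)) cols <- paste0("Q_", kinds)
    if (!length(cols) || !all(cols %in% names(obs)))
      stop("required Q columns not present")
    ok <- rowSums(as.matrix(obs[cols]) >= q_threshold) == length(cols)
    idx <- which(ok)[1]
  } else {
    rcols <- grep("^R_(ATP|AMP)$", names(obs), value = TRUE)
    tcols <- sub("^R_", "theta_", rcols)
    if (!is.null(kinds)) { rcols <- paste0("R_", kinds); tcols <- paste0("theta_", kinds) }
    if (!length(rcols) || !all(c(rcols, tcols) %in% names(obs)))
      stop("required pose columns not present")
    ok <- rowSums(as.matrix(obs[rcols]) < r_max) == length(rcols) &
      rowSums(as.matrix(obs[tcols]) < theta_max) == length(tcols)
    # sustained for >= dwell frames; stamp at interval start
    run <- rle(ok)
    ends <- cumsum(run$lengths)
    w <- which(run$values & run$lengths >= dwell)[1]
    idx <- if (is.na(w)) NA_integer_ else ends[w] - run$lengths[w] + 1L
  }
  if (is.na(idx)) list(success = FALSE, time = NA_real_)
  else list(success = TRUE, time = obs$time[idx])
}

#' First-passage record from a trajectory observable series
#'
#' @param obs Observable data frame with a `time` column.
#' @param predicate Function of the data frame returning a logical vector
#'   (one entry per frame).
#' @return A `first_passage_record`: list with `duration` (tau) and `event`
#'   (TRUE if the predicate fired, FALSE for right-censoring at the end).
#' @export
first_passage <- function(obs, predicate) {
  ok <- predicate(obs)
  if (!is.logical(ok) || length(ok) != nrow(obs))
    stop("predicate must return one logical per frame")
  idx <- which(ok)[1]
  t0 <- obs$time[1]
  if (is.na(idx)) {
    rec <- list(duration = obs$time[nrow(obs)] - t0, event = FALSE)
  } else {
    dur <- obs$time[idx] - t0
    if (dur <= 0) dur <- obs$time[2] - t0   # event in first frame: one stride
    rec <- list(duration = dur, event = TRUE)
  }
  structure(rec, class = "first_passage_record")
}

#' Maximum-likelihood MFPT from censored first-passage records
#'
#' Assumes exponentially distributed first-passage times (two-state barrier
#' crossing); with right-censored observations the maximum-likelihood
#' estimate is the total observation time divided by the number of observed
#' events. Confidence intervals come from percentile bootstrap over records.
#'
#' @param records List of `first_passage_record`s, or a data frame with
#'   columns `duration` and `event`.
#' @param n_boot Bootstrap resamples. Default 1000.
#' @param conf Confidence level. Default 0.95.
#' @param boot_seed Seed for the bootstrap resampling (kept fixed so
#'   estimates are reproducible). Default 1.
#' @return List with `mfpt`, `ci` (length 2), `n_events`, `n_records`.
#' @export
mfpt_mle <- function(records, n_boot = 1000, conf = 0.95, boot_seed = 1) {
  df <- records_to_df(records)
  if (any(df$duration <= 0)) stop("durations must be > 0")
  if (sum(df$event) == 0L) stop("no passages observed")
  est <- function(d) {
    ne <- sum(d$event)
    if (ne == 0L) return(NA_real_)
    sum(d$duration) / ne
  }
  mfpt <- est(df)
  bs <- with_seed(boot_seed, replicate(n_boot, {
    est(df[sample.int(nrow(df), replace = TRUE), , drop = FALSE])
  }))
  a <- (1 - conf) / 2
  ci <- stats::quantile(bs, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(mfpt = mfpt, ci = ci, n_events = sum(df$event), n_records = nrow(df))
}

records_to_df <- function(records) {
  if (is.data.frame(records)) return(records)
  data.frame(duration = vapply(records, `[[`, numeric(1), "duration"),
             event = vapply(records, `[[`, logical(1), "event"))
}

#' Count completed open/close cycles before an event time
#'
#' Segments an interdomain-distance series into open/closed states with a
#' two-threshold (hysteresis) rule -- the state switches to open only above
#' `open_at` and back to closed only below `close_at` -- and counts
#' completed round trips (closed-open-closed or open-closed-open) before
#' `t_stop`.
#'
#' @param r Interdomain-distance series.
#' @param time Matching time vector (default: frame index).
#' @param close_at,open_at Hysteresis thresholds; `close_at < open_at`.
#' @param t_stop Count only cycles completed before this time (default: all).
#' @return List with `cycles` (completed round trips), `n_openings`,
#'   `n_closings`, and the segmented `state` vector.
#' @export
count_conformation_cycles <- function(r, time = seq_along(r), close_at,
                                      open_at, t_stop = Inf) {
  if (close_at >= open_at) stop("close_at must be below open_at")
  keep <- time <= t_stop
  r <- r[keep]
  state <- integer(length(r))   # 0 closed, 1 open
  s <- if (r[1] >= open_at) 1L else 0L
  for (q in seq_along(r)) {
    if (s == 0L && r[q] > open_at) s <- 1L
    else if (s == 1L && r[q] < close_at) s <- 0L
    state[q] <- s
  }
  sw <- diff(state)
  n_open <- sum(sw == 1L)
  n_close <- sum(sw == -1L)
  # a completed round trip needs a return to the starting state
  cycles <- min(n_open, n_close)
  list(cycles = cycles, n_openings = n_open, n_closings = n_close,
       state = state)
}

#' Default hysteresis thresholds for a domain
#'
#' Thresholds at 30% and 70% of the closed-to-open interdomain distance gap.
#' @param topology A `cg_topology`.
#' @param domain Mobile domain label.
#' @return Named vector with `close_at`, `open_at`.
#' @export
domain_thresholds <- function(topology, domain) {
  rc <- interdomain_distance(topology$closed, topology, domain, "CORE")
  Xo <- topology$closed
  Xo[topology$protein_idx, ] <- topology$open
  ro <- interdomain_distance(Xo, topology, domain, "CORE")
  c(close_at = rc + 0.3 * (ro - rc), open_at = rc + 0.7 * (ro - rc))
}

#' Per-contact formation probability along a closing transition
#'
#' For each native protein--ligand contact, the probability (over
#' trajectories) that it is formed, resolved along the progress of a
#' domain-closing event. Each trajectory contributes its first or last
#' closing transition (the segment from the last open-state frame to the
#' subsequent closed-state frame); progress is binned by quantiles of the
#' interdomain distance within the segment (from open to closed).
#' Trajectories whose ligand leaves the binding area during the segment are
#' excluded.
#'
#' @param trajs List of `cg_trajectory` objects ending in native binding.
#' @param topology The shared `cg_topology`.
#' @param kind Ligand kind (`"AMP"` or `"ATP"`).
#' @param domain Closing domain (`"NMP"` or `"LID"`).
#' @param selector `"first"` or `"last"` closing event.
#' @param n_bins Progress bins. Default 5.
#' @param binding_radius Binding-area radius (Angstrom) for the exclusion
#'   rule: ligand centroid must stay within this distance of the pocket
#'   centroid. Default 1.5 x the native-pose maximum bead extent.
#' @return Matrix (n_bins x n_contacts) of formation probabilities, with
#'   attribute `"n_used"` (trajectories contributing).
#' @export
contact_probability_profile <- function(trajs, topology, kind = "AMP",
                                        domain = "NMP",
                                        selector = c("first", "last"),
                                        n_bins = 5, binding_radius = NULL) {
  selector <- match.arg(selector)
  ct <- ligand_contacts(topology, kind)
  if (!nrow(ct)) stop("no native contacts for ligand ", kind)
  lk <- which(topology$role == paste0("ligand:", kind))
  pocket_ref <- topology$closed[lk, , drop = FALSE]
  pocket_ctr <- colMeans(pocket_ref)
  if (is.null(binding_radius))
    binding_radius <- 1.5 * max(sqrt(rowSums(sweep(pocket_ref, 2,
                                                   pocket_ctr)^2)))
  th <- domain_thresholds(topology, domain)
  acc <- array(0, c(n_bins, nrow(ct)))
  cnt <- matrix(0, n_bins, nrow(ct))
  n_used <- 0
  core <- which(topology$domain == "CORE" & topology$role == "protein")
  for (tr in trajs) {
    rdom <- centroid_dist_frames_cpp(tr$frames,
      which(topology$domain == domain & topology$role == "protein"), core)
    seg <- closing_segment(rdom, th["close_at"], th["open_at"], selector)
    if (is.null(seg)) next
    frames <- tr$frames[seg, , drop = FALSE]
    # binding-area exclusion
    lig_ctr_d <- centroid_dist_frames_cpp(frames, lk, core) -
      sqrt(sum((colMeans(topology$closed[core, , drop = FALSE]) -
                  pocket_ctr)^2))
    if (any(abs(lig_ctr_d) > binding_radius)) next
    formed <- contacts_formed_cpp(frames, as.matrix(ct[, c("i", "j")]),
                                  ct$r0, topology$params$q_lambda)
    prog <- seq(0, 1, length.out = length(seg))
    bins <- pmin(n_bins, floor(prog * n_bins) + 1L)
    for (b in seq_len(n_bins)) {
      rows <- bins == b
      if (!any(rows)) next
      acc[b, ] <- acc[b, ] + colMeans(formed[rows, , drop = FALSE])
      cnt[b, ] <- cnt[b, ] + 1
    }
    n_used <- n_used + 1
  }
  out <- acc / pmax(cnt, 1)
  rownames(out) <- paste0("bin", seq_len(n_bins))
  attr(out, "n_used") <- n_used
  out
}

# index range of the first/last open->closed transition in a distance series
closing_segment <- function(rdom, close_at, open_at, selector) {
  st <- count_conformation_cycles(rdom, close_at = close_at,
                                  open_at = open_at)$state
  sw <- diff(st)
  closings <- which(sw == -1L)        # index before the switch to closed
  if (!length(closings)) return(NULL)
  pick <- if (selector == "first") closings[1] else closings[length(closings)]
  # segment: from the last frame the domain was fully open back to closure
  start <- max(1L, pick - 20L)
  seq(start, min(length(rdom), pick + 1L))
}
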