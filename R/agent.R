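#' Parameters of the dead-reckoning agent
#'
#' The simulator is a discrete-time noisy dead-reckoning process: the
#' agent's true position is controlled exactly (as a joystick would), but
#' its internal position estimate accumulates error. At every 200-ms
#' movement step the perceived displacement is the true displacement
#' rotated by Gaussian heading noise and scaled by multiplicative
#' step-length noise; homing therefore drifts with path length. When a
#' spatial cue is visible, the internal estimate is pulled back toward
#' truth once per second by a fraction `kappa` (for the landmark,
#' weighted by proximity to the landmark).
#'
#' @param heading_noise_sd SD of per-step heading noise, degrees.
#' @param step_noise_cv Coefficient of variation of per-step perceived
#'   step length (dimensionless).
#' @param cue_gain_boundary Boundary correction gain per second, \[0, 1\].
#' @param cue_gain_landmark Landmark correction gain per second, \[0, 1\].
#' @param landmark_halfsat Distance (vm) at which the landmark correction
#'   is at half strength; the proximity weight is
#'   `halfsat / (halfsat + distance)`.
#' @param cruise_speed Full movement speed, vm per second.
#' @param turn_speed Rotation speed when turning in place, degrees per
#'   second (joystick navigation: the avatar rotates without
#'   translating, so turn samples have zero movement speed).
#' @param sample_rate Position sampling rate, Hz (the task logs at 5 Hz).
#' @param group_label `"control"` or `"risk"`.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(heading_noise_sd = 10,
                         step_noise_cv = 0.15,
                         cue_gain_boundary = 0.3,
                         cue_gain_landmark = 0.5,
                         landmark_halfsat = 2000,
                         cruise_speed = 1000,
                         turn_speed = 90,
                         sample_rate = 5,
                         group_label = c("control", "risk")) {
  group_label <- match.arg(group_label)
  vals <- c(heading_noise_sd, step_noise_cv, cue_gain_boundary,
            cue_gain_landmark, landmark_halfsat, cruise_speed, turn_speed,
            sample_rate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("agent parameters must be finite and non-negative")
  }
  if (cue_gain_boundary > 1 || cue_gain_landmark > 1) {
    stop("cue gains must lie in [0, 1]")
  }
  structure(
    list(heading_noise_sd = heading_noise_sd,
         step_noise_cv = step_noise_cv,
         cue_gain_boundary = cue_gain_boundary,
         cue_gain_landmark = cue_gain_landmark,
         landmark_halfsat = landmark_halfsat,
         cruise_speed = cruise_speed,
         turn_speed = turn_speed,
         sample_rate = sample_rate,
         group_label = group_label),
    class = "agent_params"
  )
}

# Sample points along a straight leg at constant step length, excluding the
# start point, snapping the final sample to the endpoint.
leg_points <- function(from, to, step_len) {
  d <- sqrt(sum((to - from)^2))
  if (d < 1e-9) return(matrix(numeric(0), ncol = 2))
  n <- max(1L, ceiling(d / step_len))
  f <- seq_len(n) / n
  cbind(from[1] + f * (to[1] - from[1]),
        from[2] + f * (to[2] - from[2]))
}

# Accumulate dead-reckoning error over a sequence of true displacements
# (n x 2). Returns the summed (perceived - true) displacement.
dr_error_increment <- function(disp, params) {
  n <- nrow(disp)
  if (n == 0L) return(c(0, 0))
  th <- rnorm(n, 0, deg2rad(params$heading_noise_sd))
  s <- 1 + params$step_noise_cv * rnorm(n)
  px <- s * (cos(th) * disp[, 1] - sin(th) * disp[, 2])
  py <- s * (sin(th) * disp[, 1] + cos(th) * disp[, 2])
  c(sum(px - disp[, 1]), sum(py - disp[, 2]))
}

#' Simulate one trial of the task
#'
#' Runs the dead-reckoning agent through the start, outgoing, incoming
#' and feedback phases of one trial. During the incoming phase the agent
#' steers toward its internal goal estimate (true goal displaced by the
#' accumulated dead-reckoning error, which keeps accumulating en route);
#' cue correction shrinks the error once per second in the
#' boundary-supported and landmark-supported subtasks. Movement obeys
#' [speed_factor()] and the 200-ms sampling grid.
#'
#' @param trial One row of a [generate_trial_set()] data frame (or any
#'   list with `subtask`, `trial_index`, `goal_x`, `goal_y`, `trees`).
#' @param params An [agent_params()].
#' @param arena An [arena_config()]; cue presence is taken from the
#'   trial's subtask, not from the arena flags.
#' @param seed Integer seed.
#' @param start_xy Where the trial begins (the previous trial's response
#'   location; the arena center for a block's first trial).
#' @param t0_ms Start time of the trial (ms), for contiguous logfiles.
#' @return A list with `trajectory` (logfile-dialect data frame),
#'   `response_xy`, `stars`, and `final_error` (the internal-estimate
#'   error at response time).
#' @export
simulate_trial <- function(trial, params, arena = arena_config(), seed = 1,
                           start_xy = c(0, 0), t0_ms = 0) {
  stopifnot(inherits(params, "agent_params"))
  goal <- c(trial$goal_x, trial$goal_y)
  trees <- if (is.list(trial$trees)) trial$trees[[1]] else trial$trees
  subtask <- as.character(trial$subtask)
  step_len <- params$cruise_speed / params$sample_rate
  dt_ms <- 1000 / params$sample_rate

  turn_step <- params$turn_speed / params$sample_rate

  with_seed(seed, {
    pts <- list()   # position samples (excluding trial start point)
    phase <- character()
    hds <- numeric() # explicit heading per sample
    cur_hd <- NA_real_

    # rotate in place toward `to_hd` (zero-speed samples)
    emit_turn <- function(pos, to_hd, ph) {
      if (is.na(cur_hd)) return(invisible())
      sdiff <- ((to_hd - cur_hd + 180) %% 360) - 180
      if (abs(sdiff) <= turn_step) return(invisible())
      n <- ceiling(abs(sdiff) / turn_step)
      pts[[length(pts) + 1L]] <<- matrix(rep(pos, each = n), ncol = 2)
      phase <<- c(phase, rep(ph, n))
      hds <<- c(hds, wrap360(cur_hd + sdiff * seq_len(n) / n))
    }
    emit_leg <- function(from, to, ph) {
      leg <- leg_points(from, to, step_len)
      if (nrow(leg) == 0L) return(from)
      dir <- rad2deg(atan2(to[2] - from[2], to[1] - from[1]))
      emit_turn(from, dir, ph)
      pts[[length(pts) + 1L]] <<- leg
      phase <<- c(phase, rep(ph, nrow(leg)))
      hds <<- c(hds, rep(wrap360(dir), nrow(leg)))
      cur_hd <<- wrap360(dir)
      leg[nrow(leg), ]
    }

    # start phase: walk to the basket (goal); internal estimate is
    # recalibrated at the basket, so no error is carried out of it
    cur_hd <- NA_real_
    invisible(emit_leg(start_xy, goal, "start"))

    # outgoing phase: goal -> tree1 -> ... -> retrieval (last tree)
    err <- c(0, 0)
    cur <- goal
    for (k in seq_len(nrow(trees))) {
      from <- cur
      cur <- emit_leg(cur, trees[k, ], "outgoing")
      d <- trees[k, ] - from
      dd <- sqrt(sum(d^2))
      if (dd > 1e-9) {
        n_steps <- max(1L, ceiling(dd / step_len))
        disp <- matrix(rep(d / n_steps, each = n_steps), ncol = 2)
        err <- err + dr_error_increment(disp, params)
      }
    }

    # incoming phase: steer toward the internal goal estimate goal + err
    # (the agent believes it is at cur + err and wants to reach the goal,
    # which in true coordinates means walking to goal - (-err)).
    kappa <- switch(subtask,
                    PPI = 0,
                    BPI = params$cue_gain_boundary,
                    LPI = params$cue_gain_landmark)
    max_steps <- 60L * params$sample_rate  # the task's 60-s incoming limit
    inc <- matrix(NA_real_, max_steps, 2)
    inc_hd <- numeric(max_steps)
    steps <- 0L
    inner2 <- arena$speed_zone_inner_radius^2
    h_sd <- deg2rad(params$heading_noise_sd)
    # turn toward the believed goal before setting off
    v0 <- goal + err - cur
    if (sqrt(sum(v0^2)) > 1e-9) {
      emit_turn(cur, rad2deg(atan2(v0[2], v0[1])), "incoming")
    }
    while (steps < max_steps) {
      target <- goal + err
      v <- target - cur
      d <- sqrt(sum(v^2))
      if (d < 1e-9) break
      sf <- if (sum(cur^2) <= inner2) 1 else {
        speed_factor(cur, rad2deg(atan2(v[2], v[1])), arena)
      }
      adv <- min(d, step_len * sf)
      if (adv < 1e-9) break
      nxt <- cur + v / d * adv
      dx <- nxt[1] - cur[1]; dy <- nxt[2] - cur[2]
      th <- rnorm(1, 0, h_sd)
      s <- 1 + params$step_noise_cv * rnorm(1)
      err[1] <- err[1] + s * (cos(th) * dx - sin(th) * dy) - dx
      err[2] <- err[2] + s * (sin(th) * dx + cos(th) * dy) - dy
      cur <- nxt
      steps <- steps + 1L
      inc[steps, ] <- cur
      inc_hd[steps] <- wrap360(rad2deg(atan2(dy, dx)))
      # cue correction once per second of travel
      if (kappa > 0 && steps %% params$sample_rate == 0L) {
        w <- if (subtask == "LPI") {
          dl <- sqrt(sum((cur - arena$landmark_xy)^2))
          params$landmark_halfsat / (params$landmark_halfsat + dl)
        } else 1
        err <- err * (1 - kappa * w)
      }
      if (adv >= d - 1e-9) break  # reached the believed goal
    }
    response <- cur
    if (steps > 0L) {
      pts[[length(pts) + 1L]] <- inc[seq_len(steps), , drop = FALSE]
      phase <- c(phase, rep("incoming", steps))
      hds <- c(hds, inc_hd[seq_len(steps)])
      cur_hd <- inc_hd[steps]
    }

    # feedback phase: stationary for 1 s while stars are shown
    n_fb <- params$sample_rate
    pts[[length(pts) + 1L]] <- matrix(rep(response, each = n_fb), ncol = 2)
    phase <- c(phase, rep("feedback", n_fb))
    hds <- c(hds, rep(if (is.na(cur_hd)) 0 else cur_hd, n_fb))

    xy <- do.call(rbind, pts)
    traj <- list(
      t_ms = t0_ms + dt_ms * seq_len(nrow(xy)),
      x_vm = xy[, 1], y_vm = xy[, 2],
      heading_deg = wrap360(hds),
      phase = phase,
      trial = rep(trial$trial_index, nrow(xy))
    )
    attr(traj, "row.names") <- .set_row_names(nrow(xy))
    class(traj) <- "data.frame"
    list(trajectory = traj,
         response_xy = response,
         stars = assign_star_feedback(sqrt(sum((response - goal)^2))),
         final_error = err)
  })
}

#' Cohort specification for the agent simulator
#'
#' @param n_control,n_risk Group sizes.
#' @param params_control,params_risk [agent_params()] for each group.
#' @param seed Master seed; all subject-level randomness derives from it.
#' @param long_version Logical; long (96-trial) paradigm if `TRUE`.
#' @param subject_sd SD (log scale) of subject-level heterogeneity in the
#'   noise parameters.
#' @param n_sites Number of recruitment sites (subjects assigned
#'   round-robin); sites add mild multiplicative heterogeneity in noise.
#' @param site_sd SD (log scale) of the site effect on heading noise.
#' @param age_mix,age_means,age_sds Bimodal age mixture: probability of
#'   the younger component and the component means/SDs in years.
#' @param prop_male Probability of male sex.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 30, n_risk = 30,
                        params_control = agent_params(group_label = "control"),
                        params_risk = agent_params(
                          heading_noise_sd = 15, group_label = "risk"),
                        seed = 1, long_version = FALSE,
                        subject_sd = 0.2, n_sites = 4, site_sd = 0.1,
                        age_mix = 0.61, age_means = c(24, 59),
                        age_sds = c(5, 8), prop_male = 0.386) {
  stopifnot(n_control >= 0, n_risk >= 0, n_control + n_risk >= 1)
  structure(
    list(n_control = n_control, n_risk = n_risk,
         params_control = params_control, params_risk = params_risk,
         seed = seed, long_version = long_version,
         subject_sd = subject_sd, n_sites = n_sites, site_sd = site_sd,
         age_mix = age_mix, age_means = age_means, age_sds = age_sds,
         prop_male = prop_male),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of navigating agents
#'
#' Simulates every subject through a full (short or long) trial set,
#' producing trajectory logs in the [write_logfile()] dialect, a
#' per-trial response table, and a subject table with synthetic ages
#' drawn from a bimodal mixture (so downstream age-split machinery has
#' realistic input), sex, site and genotype labels.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, one logfile per subject
#'   is written there (`sub-<id>.tsv`).
#' @return An object of class `pi_cohort`: list with `subjects` (id,
#'   group, genotype, age, sex, site), `responses` (one row per trial:
#'   subject, block, subtask, trial, n_trees, goal/retrieval/response
#'   coordinates, stars), and `trajectories` (named list of logfile data
#'   frames).
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_risk
  groups <- rep(c("control", "risk"), c(spec$n_control, spec$n_risk))

  subjects <- with_seed(derive_seed(spec$seed, 0), {
    young <- runif(n) < spec$age_mix
    age <- ifelse(young,
                  rnorm(n, spec$age_means[1], spec$age_sds[1]),
                  rnorm(n, spec$age_means[2], spec$age_sds[2]))
    data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = groups,
      genotype = ifelse(groups == "risk", "e3/e4", "e3/e3"),
      age = round(pmin(pmax(age, 18), 75), 1),
      sex = ifelse(runif(n) < spec$prop_male, "male", "female"),
      site = sprintf("site%d", ((seq_len(n) - 1L) %% spec$n_sites) + 1L)
    )
  })
  site_mult <- with_seed(derive_seed(spec$seed, 1),
                         exp(rnorm(spec$n_sites, 0, spec$site_sd)))

  responses <- vector("list", n)
  trajectories <- vector("list", n)
  trial_sets <- vector("list", n)
  names(trajectories) <- names(trial_sets) <- subjects$subject

  for (i in seq_len(n)) {
    base <- if (groups[i] == "control") spec$params_control else
      spec$params_risk
    sid <- ((i - 1L) %% spec$n_sites) + 1L
    mult <- with_seed(derive_seed(spec$seed, 100 + i),
                      exp(rnorm(1, 0, spec$subject_sd))) * site_mult[sid]
    pars <- base
    pars$heading_noise_sd <- base$heading_noise_sd * mult
    pars$step_noise_cv <- base$step_noise_cv * mult

    trials <- generate_trial_set(derive_seed(spec$seed, 200 + i),
                                 long_version = spec$long_version)
    trial_sets[[i]] <- trials
    cur <- c(0, 0)
    t0 <- 0
    traj <- vector("list", nrow(trials))
    resp <- vector("list", nrow(trials))
    for (j in seq_len(nrow(trials))) {
      tr <- trials[j, ]
      if (tr$trial_index == 1L) cur <- c(0, 0)  # blocks start at the center
      arena <- subtask_arena(as.character(tr$subtask))
      sim <- simulate_trial(tr, pars, arena,
                            seed = derive_seed(spec$seed,
                                               1e4 + i * 200 + j),
                            start_xy = cur, t0_ms = t0)
      sim$trajectory$trial <- j  # globally unique trial id within subject
      traj[[j]] <- sim$trajectory
      t0 <- max(sim$trajectory$t_ms)
      retrieval <- tr$trees[[1]][nrow(tr$trees[[1]]), ]
      resp[[j]] <- data.frame(
        subject = subjects$subject[i],
        block = tr$block, subtask = as.character(tr$subtask),
        trial = j, trial_in_block = tr$trial_index,
        n_trees = tr$n_trees,
        goal_x = tr$goal_x, goal_y = tr$goal_y,
        retrieval_x = retrieval[1], retrieval_y = retrieval[2],
        response_x = sim$response_xy[1], response_y = sim$response_xy[2],
        stars = sim$stars
      )
      cur <- sim$response_xy
    }
    trajectories[[i]] <- do.call(rbind, traj)
    responses[[i]] <- do.call(rbind, resp)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_logfile(trajectories[[i]],
                    file.path(out_dir, paste0("sub-", subjects$subject[i],
                                              ".tsv")))
    }
  }
  structure(
    list(subjects = subjects,
         responses = do.call(rbind, responses),
         trajectories = trajectories,
         trial_sets = trial_sets,
         spec = spec),
    class = "pi_cohort"
  )
}
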