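# Shared fixture builders (everything is generated in code at test time).

# Concatenate simulated trials into one fMRI-style run trajectory.
# Slow cruise speed matches the fMRI task's pacing (a trial lasts tens of
# seconds), giving direction persistence on the TR timescale.
mk_run_trajectory <- function(seed, n_trials = 48, cruise = 250,
                              heading_noise_sd = 10) {
  ts <- generate_trial_set(seed, long_version = TRUE)
  p <- agent_params(heading_noise_sd = heading_noise_sd,
                    cruise_speed = cruise)
  traj <- vector("list", n_trials)
  t0 <- 0
  for (j in seq_len(n_trials)) {
    s <- simulate_trial(ts[j, ], p,
                        subtask_arena(as.character(ts$subtask[j])),
                        seed = seed * 1000 + j, t0_ms = t0)
    s$trajectory$trial <- j
    traj[[j]] <- s$trajectory
    t0 <- max(s$trajectory$t_ms)
  }
  do.call(rbind, traj)
}

# Single-subtask trajectory plus matching trial table for GLM designs.
mk_glm_run <- function(seed, n_trials = 16, subtask = "PPI", cruise = 250) {
  ts <- generate_trial_set(seed)
  ts <- ts[ts$subtask == subtask, ][seq_len(n_trials), ]
  p <- agent_params(heading_noise_sd = 8, cruise_speed = cruise)
  traj <- vector("list", n_trials)
  t0 <- 0
  for (j in seq_len(n_trials)) {
    s <- simulate_trial(ts[j, ], p, subtask_arena(subtask),
                        seed = seed * 100 + j, t0_ms = t0)
    s$trajectory$trial <- j
    traj[[j]] <- s$trajectory
    t0 <- max(s$trajectory$t_ms)
  }
  trials <- ts
  trials$trial <- seq_len(nrow(trials))
  list(trajectory = do.call(rbind, traj), trials = trials)
}
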