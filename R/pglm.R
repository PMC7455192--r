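#' Parametric modulators: integrated path and goal distance
#'
#' For the movement samples of one trial phase, computes the two
#' moment-to-moment quantities used as parametric modulators:
#' *integrated path* (cumulative Euclidean distance traveled within the
#' phase, nondecreasing) and *goal distance* (instantaneous Euclidean
#' distance to the goal). Both are normalized to \[0, 1\] by min-max
#' scaling and then mean-centered; a constant series maps to all zeros
#' with a warning.
#'
#' @param trajectory Logfile-dialect data frame for one trial.
#' @param goal_xy Length-2 goal location (vm).
#' @param phase Phase to extract (`"outgoing"` or `"incoming"`).
#' @return An object of class `modulators`: list with `t_ms`,
#'   `integrated_path`, `goal_distance` (raw series) and
#'   `integrated_path_norm`, `goal_distance_norm` (normalized,
#'   mean-centered).
#' @export
build_modulators <- function(trajectory, goal_xy,
                             phase = c("incoming", "outgoing")) {
  phase <- match.arg(phase)
  idx <- trajectory$phase == phase
  if (!any(idx)) stop("no movement samples in phase '", phase, "'")
  tr <- trajectory[idx, , drop = FALSE]
  xy <- cbind(tr$x_vm, tr$y_vm)
  legs <- vnorm(diff(xy))
  ip <- c(0, cumsum(legs))
  gd <- vnorm(sweep(xy, 2, as.numeric(goal_xy)))
  normalize <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-12) {
      warning("constant modulator series; normalized to zeros")
      return(rep(0, length(x)))
    }
    z <- (x - rng[1]) / diff(rng)
    z - mean(z)
  }
  structure(
    list(t_ms = tr$t_ms, phase = phase,
         integrated_path = ip, goal_distance = gd,
         integrated_path_norm = normalize(ip),
         goal_distance_norm = normalize(gd)),
    class = "modulators"
  )
}

# Build one convolved, TR-resampled design column from 5 Hz stick or
# boxcar values aligned to trajectory samples.
regressor_column <- function(values, n_samples, sample_idx, dt, tr,
                             n_volumes, ...) {
  x <- numeric(n_samples)
  x[sample_idx] <- values
  conv <- convolve_hrf(x, dt = dt, ...)
  col <- resample_tr(conv, dt = dt, tr = tr)
  length(col) <- n_volumes  # pad with NA then zero-fill
  col[is.na(col)] <- 0
  col
}

#' Build a first-level GLM design matrix
#'
#' Constructs the task design matrices used on the (synthetic) BOLD
#' series:
#' * `pi_model`: per subtask, four regressor families -- start phase,
#'   outgoing movement, incoming movement, and no-movement periods
#'   (speed at or below the subject's 1st percentile of movement speed).
#'   Movement regressors are zero-duration onsets at every 200-ms
#'   movement sample; one parametric modulator (`"integrated_path"` or
#'   `"goal_distance"`, normalized and mean-centered per trial phase) is
#'   attached to the outgoing and incoming movement regressors.
#' * `subtask_model`: boxcars for start, outgoing, incoming and feedback
#'   phases per subtask, plus a "PI difficulty" modulator (number of
#'   trees, values 1-5, mean-centered) on the outgoing boxcar.
#' * `combined`: as `pi_model` but with both modulators: goal distance
#'   entered first and integrated path orthogonalized against it (per
#'   phase regressor, after convolution).
#'
#' All regressors are convolved with the canonical [hrf()] and averaged
#' into TR windows. With multiple runs, pass each run's trajectory
#' separately and bind columns blockwise.
#'
#' @param trajectory Logfile-dialect data frame for one run (contiguous
#'   time, multiple trials), with a `subtask` column or a single subtask
#'   given in `subtask`.
#' @param trials The trial table for the run (needs `trial`, `subtask`,
#'   `n_trees`, `goal_x`, `goal_y` per trial id in the trajectory).
#' @param model `"pi_model"`, `"subtask_model"`, or `"combined"`.
#' @param modulator For `pi_model`: `"integrated_path"` or
#'   `"goal_distance"`.
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes; defaults to
#'   `floor(duration / tr)`.
#' @return An object of class `design_matrix`: list with `X` (volumes x
#'   regressors matrix with unique column labels), `tr`, `model`.
#' @export
build_design <- function(trajectory, trials,
                         model = c("pi_model", "subtask_model", "combined"),
                         modulator = c("integrated_path", "goal_distance"),
                         tr = 2.5, n_volumes = NULL) {
  model <- match.arg(model)
  modulator <- match.arg(modulator)
  dt <- diff(trajectory$t_ms[1:2]) / 1000
  n_samples <- nrow(trajectory)
  duration <- n_samples * dt
  n_volumes <- n_volumes %||% floor(duration / tr)

  xy <- cbind(trajectory$x_vm, trajectory$y_vm)
  step <- c(0, vnorm(diff(xy)))
  speed <- step / dt
  moving_speed <- speed[speed > 0]
  no_move_thr <- if (length(moving_speed)) {
    stats::quantile(speed, 0.01)
  } else {
    0
  }
  no_move <- speed <= pmax(no_move_thr, 1e-9)

  trial_of <- trajectory$trial
  sub_of <- as.character(trials$subtask[match(trial_of, trials$trial)])
  subtasks <- unique(as.character(trials$subtask))

  cols <- list()
  add <- function(name, values, sample_idx) {
    if (length(sample_idx) == 0L) return(invisible())
    cols[[name]] <<- regressor_column(values, n_samples, sample_idx,
                                      dt, tr, n_volumes)
  }

  for (st in subtasks) {
    in_st <- sub_of == st
    if (model %in% c("pi_model", "combined")) {
      add(paste0("start_", st),
          rep(1, sum(in_st & trajectory$phase == "start")),
          which(in_st & trajectory$phase == "start"))
      add(paste0("nomove_", st),
          rep(1, sum(in_st & no_move)),
          which(in_st & no_move))
      for (ph in c("outgoing", "incoming")) {
        idx <- which(in_st & trajectory$phase == ph & !no_move)
        add(paste0(ph, "_", st), rep(1, length(idx)), idx)
        # per-trial modulators, concatenated over the subtask's trials
        for (mk in if (model == "combined") {
          c("goal_distance", "integrated_path")
        } else {
          modulator
        }) {
          vals <- numeric(0)
          pos <- integer(0)
          for (trl in unique(trial_of[idx])) {
            ti <- trials[trials$trial == trl, ]
            tt <- trajectory[trajectory$trial == trl, , drop = FALSE]
            mods <- build_modulators(tt, c(ti$goal_x, ti$goal_y), ph)
            sel <- which(trajectory$trial == trl &
                           trajectory$phase == ph)
            keep <- sel %in% idx
            v <- if (mk == "integrated_path") {
              mods$integrated_path_norm
            } else {
              mods$goal_distance_norm
            }
            vals <- c(vals, v[keep])
            pos <- c(pos, sel[keep])
          }
          add(paste0(ph, "_", st, "_x_", mk), vals, pos)
        }
      }
    } else { # subtask_model: boxcars on all four phases
      for (ph in c("start", "outgoing", "incoming", "feedback")) {
        idx <- which(in_st & trajectory$phase == ph)
        add(paste0(ph, "_", st), rep(1, length(idx)), idx)
      }
      idx <- which(in_st & trajectory$phase == "outgoing")
      difficulty <- trials$n_trees[match(trial_of[idx], trials$trial)]
      add(paste0("outgoing_", st, "_x_difficulty"),
          difficulty - mean(difficulty), idx)
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (model == "combined") {
    # orthogonalize integrated path against goal distance per phase column
    for (st in subtasks) {
      for (ph in c("outgoing", "incoming")) {
        gp <- paste0(ph, "_", st, "_x_goal_distance")
        ip <- paste0(ph, "_", st, "_x_integrated_path")
        if (all(c(gp, ip) %in% colnames(X))) {
          g <- X[, gp]
          if (sum(g^2) > 0) {
            X[, ip] <- X[, ip] - g * sum(X[, ip] * g) / sum(g^2)
          }
        }
      }
    }
  }
  structure(list(X = X, tr = tr, model = model, n_volumes = n_volumes),
            class = "design_matrix")
}

#' Combine per-run design matrices into one session design
#'
#' Stacks run designs blockwise in time with run-suffixed column labels
#' (regressors are estimated separately per run, as in a standard
#' first-level model): the two-run PI model has
#' 4 regressor families x 3 subtasks x 2 runs = 24 base regressors.
#'
#' @param designs List of `design_matrix` objects, one per run.
#' @return A `design_matrix` covering all runs.
#' @export
combine_run_designs <- function(designs) {
  stopifnot(length(designs) >= 1)
  nv <- vapply(designs, function(d) d$n_volumes, numeric(1))
  cols <- unlist(lapply(seq_along(designs), function(r) {
    paste0(colnames(designs[[r]]$X), "_run", r)
  }))
  X <- matrix(0, sum(nv), length(cols), dimnames = list(NULL, cols))
  at_row <- 0L
  at_col <- 0L
  for (r in seq_along(designs)) {
    Xr <- designs[[r]]$X
    X[at_row + seq_len(nrow(Xr)), at_col + seq_len(ncol(Xr))] <- Xr
    at_row <- at_row + nrow(Xr)
    at_col <- at_col + ncol(Xr)
  }
  structure(list(X = X, tr = designs[[1]]$tr, model = designs[[1]]$model,
                 n_volumes = sum(nv)),
            class = "design_matrix")
}

#' Fit a GLM to an ROI series and evaluate contrasts
#'
#' Ordinary least squares of the ROI-mean BOLD series (or each voxel) on
#' the design matrix, plus weighted-sum contrasts of the estimated
#' betas (e.g. the boundary-vs-pure and landmark-vs-pure subtask
#' contrasts).
#'
#' @param design A `design_matrix`.
#' @param bold A `bold_series` with at least `design$n_volumes` volumes.
#' @param contrast Optional named numeric vector of contrast weights
#'   (names matching design columns; missing columns get weight 0).
#' @param per_voxel Fit each voxel separately instead of the ROI mean?
#' @return A list with `beta` (named vector, or matrix if per voxel),
#'   `contrast_value` (`NULL` if no contrast given), `residual_sd`, and
#'   `df_residual`.
#' @export
fit_and_contrast <- function(design, bold, contrast = NULL,
                             per_voxel = FALSE) {
  X <- design$X
  n <- nrow(X)
  stopifnot(bold$n_volumes >= n)
  y <- if (per_voxel) bold$data[seq_len(n), , drop = FALSE] else
    rowMeans(bold$data)[seq_len(n)]
  Xi <- cbind(intercept = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  cv <- NULL
  if (!is.null(contrast)) {
    w <- stats::setNames(numeric(ncol(Xi)), colnames(Xi))
    w[names(contrast)] <- contrast
    cv <- if (per_voxel) as.numeric(w %*% beta) else sum(w * beta)
  }
  list(beta = if (per_voxel) beta[-1, , drop = FALSE] else beta[-1],
       intercept = if (per_voxel) beta[1, ] else beta[1],
       contrast_value = cv,
       residual_sd = if (per_voxel) apply(res, 2, stats::sd) else
         stats::sd(res),
       df_residual = n - ncol(Xi))
}

#' Goal proximity vs. integrated path: correlation with surrogate tests
#'
#' Within each subject, Spearman's rho between the goal-proximity and
#' integrated-path series over the entire experiment; each empirical rho
#' is referred to a surrogate distribution obtained by shuffling one
#' series `n_shuffle` times, the resulting one-sided rank p is mapped to
#' a z value via the inverse normal, and the group mean z is tested
#' against `n_shuffle` random sign-flips of the subject z values.
#'
#' Note on sign: the modulator is goal *distance*; goal *proximity* is
#' its negation, so the sign of rho flips with the convention
#' (`proximity = TRUE` negates the first series).
#'
#' @param gp_list List (one element per subject) of goal-distance
#'   series.
#' @param ip_list List of integrated-path series, aligned with
#'   `gp_list`.
#' @param n_shuffle Number of shuffles / sign flips.
#' @param seed Integer seed.
#' @param proximity Negate the goal-distance series (report in proximity
#'   convention)?
#' @return A list with `rho` (per subject), `z` (per subject),
#'   `mean_z`, and `p_group` (two-sided sign-flip p).
#' @export
modulator_correlation_test <- function(gp_list, ip_list, n_shuffle = 10000,
                                       seed = 1, proximity = FALSE) {
  stopifnot(length(gp_list) == length(ip_list))
  n_sub <- length(gp_list)
  rho <- z <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    g <- as.numeric(gp_list[[i]])
    if (proximity) g <- -g
    p <- as.numeric(ip_list[[i]])
    stopifnot(length(g) == length(p), length(g) >= 10)
    if (stats::sd(g) == 0 || stats::sd(p) == 0) {
      stop("constant series: correlation undefined for subject ", i)
    }
    rg <- rank(g)
    rp <- rank(p)
    rho[i] <- stats::cor(rg, rp)
    surr <- with_seed(derive_seed(seed, i), {
      vapply(seq_len(n_shuffle), function(b) {
        stats::cor(rg, rp[sample.int(length(rp))])
      }, numeric(1))
    })
    # one-sided rank p in the direction of the empirical sign -> z
    p_one <- if (rho[i] >= 0) {
      (1 + sum(surr >= rho[i])) / (n_shuffle + 1)
    } else {
      (1 + sum(surr <= rho[i])) / (n_shuffle + 1)
    }
    z[i] <- sign(rho[i]) * stats::qnorm(1 - p_one)
  }
  mean_z <- mean(z)
  flips <- with_seed(derive_seed(seed, 0), {
    vapply(seq_len(n_shuffle), function(b) {
      mean(z * sample(c(-1, 1), n_sub, replace = TRUE))
    }, numeric(1))
  })
  p_group <- (1 + sum(abs(flips) >= abs(mean_z))) / (n_shuffle + 1)
  list(rho = rho, z = z, mean_z = mean_z, p_group = p_group)
}
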