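#' Per-trial behavioral metrics
#'
#' Computes the homing-error and distance measures for one trial:
#' * `drop_error` -- Euclidean distance between goal and response;
#' * `distance_error` -- `|D_correct - D_response|` where `D_correct` is
#'   the retrieval-to-goal distance (the correct incoming path) and
#'   `D_response` the retrieval-to-response distance;
#' * `rotation_error` -- absolute angular difference between the headings
#'   of the correct (`retrieval -> goal`) and chosen
#'   (`retrieval -> response`) incoming paths, wrapped to \[0, 180\];
#' * `outgoing_distance` -- cumulated path distance over the outgoing
#'   legs goal -> tree1 -> ... -> retrieval;
#' * `incoming_distance` -- Euclidean retrieval-to-goal distance;
#' * `goal_to_boundary` -- radial distance from the goal to the boundary
#'   circle; `goal_to_landmark` -- goal-to-landmark distance;
#' * `mean_move_to_boundary` / `mean_move_to_landmark` -- mean Euclidean
#'   distance from the boundary wall / landmark over all samples of the
#'   incoming phase (navigational strategy, not performance).
#'
#' @param trial One row of a [generate_trial_set()] data frame.
#' @param response_xy Length-2 response location (vm).
#' @param incoming_trajectory Data frame of incoming-phase samples with
#'   columns `x_vm`, `y_vm` (may be `NULL`; the two movement-distance
#'   metrics are then `NA`).
#' @param arena An [arena_config()].
#' @return A one-row data frame of metrics. `rotation_error` is `NA` when
#'   the response coincides with the retrieval location (undefined
#'   heading).
#' @examples
#' ts <- generate_trial_set(1)
#' compute_trial_metrics(ts[1, ], c(0, 0))
#' @export
compute_trial_metrics <- function(trial, response_xy,
                                  incoming_trajectory = NULL,
                                  arena = arena_config()) {
  goal <- c(trial$goal_x, trial$goal_y)
  trees <- if (is.list(trial$trees)) trial$trees[[1]] else trial$trees
  retrieval <- trees[nrow(trees), ]
  response <- as.numeric(response_xy)

  drop_error <- sqrt(sum((goal - response)^2))
  d_correct <- sqrt(sum((retrieval - goal)^2))
  d_response <- sqrt(sum((retrieval - response)^2))
  distance_error <- abs(d_correct - d_response)

  rotation_error <- if (d_response < 1e-9 || d_correct < 1e-9) {
    NA_real_
  } else {
    r_correct <- rad2deg(atan2(goal[2] - retrieval[2],
                               goal[1] - retrieval[1]))
    r_response <- rad2deg(atan2(response[2] - retrieval[2],
                                response[1] - retrieval[1]))
    ang_dist(r_correct, r_response)
  }

  legs <- rbind(goal, trees)
  outgoing_distance <- sum(vnorm(diff(legs)))

  mean_b <- mean_l <- NA_real_
  if (!is.null(incoming_trajectory) && nrow(incoming_trajectory) > 0) {
    p <- cbind(incoming_trajectory$x_vm, incoming_trajectory$y_vm)
    mean_b <- mean(arena$boundary_radius - vnorm(p))
    mean_l <- mean(vnorm(sweep(p, 2, arena$landmark_xy)))
  }

  data.frame(
    drop_error = drop_error,
    distance_error = distance_error,
    rotation_error = rotation_error,
    outgoing_distance = outgoing_distance,
    incoming_distance = d_correct,
    goal_to_boundary = arena$boundary_radius - sqrt(sum(goal^2)),
    goal_to_landmark = sqrt(sum((goal - arena$landmark_xy)^2)),
    mean_move_to_boundary = mean_b,
    mean_move_to_landmark = mean_l
  )
}

#' Map errors onto the 0-1000 performance scale
#'
#' Linear, order-reversing transform used for readability:
#' `performance_i = (max(error) - error_i + min(error)) / max(error) * 1000`,
#' where the extrema are taken across all participants and trials of the
#' dataset for the given error type. The minimum error maps to 1000; the
#' transform does not change any statistics.
#'
#' @param errors Numeric vector of per-trial errors.
#' @param cohort_min,cohort_max Normalization extrema; default to the
#'   range of `errors` (NA removed).
#' @return Numeric vector of performance scores.
#' @examples
#' performance_transform(c(2, 4, 10), 2, 10) # 1000, 800, 200
#' @export
performance_transform <- function(errors,
                                  cohort_min = min(errors, na.rm = TRUE),
                                  cohort_max = max(errors, na.rm = TRUE)) {
  if (!is.finite(cohort_max) || cohort_max == 0) {
    stop("degenerate normalization: cohort maximum error is zero")
  }
  stopifnot(cohort_min <= cohort_max)
  (cohort_max - errors + cohort_min) / cohort_max * 1000
}

#' Cohort-level trial metrics table
#'
#' Runs [compute_trial_metrics()] over every trial of a simulated cohort
#' and joins the subject table, producing the analysis-ready long table
#' used by the mixed-model designs. Performance columns are added with
#' [performance_transform()], normalized per error type across the whole
#' cohort.
#'
#' @param cohort A `pi_cohort` from [simulate_cohort()].
#' @return A data frame with one row per trial: subject descriptors
#'   (`subject`, `group`, `apoe` (0 control / 1 risk), `genotype`, `age`,
#'   `sex`, `site`), trial descriptors, all [compute_trial_metrics()]
#'   columns and `performance`, `performance_distance`,
#'   `performance_rotation`.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "pi_cohort"))
  n_rows <- nrow(cohort$responses)
  met <- matrix(NA_real_, n_rows, 9)
  sub_idx <- integer(n_rows)
  k <- 0L
  arenas <- list(PPI = subtask_arena("PPI"), BPI = subtask_arena("BPI"),
                 LPI = subtask_arena("LPI"))
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject[i]
    trials <- cohort$trial_sets[[sid]]
    traj <- cohort$trajectories[[sid]]
    inc_traj <- split(traj[traj$phase == "incoming", , drop = FALSE],
                      traj$trial[traj$phase == "incoming"])
    resp <- cohort$responses[cohort$responses$subject == sid, ]
    for (j in seq_len(nrow(resp))) {
      tr <- trials[resp$trial_in_block[j] == trials$trial_index &
                     trials$block == resp$block[j], ]
      arena <- arenas[[as.character(tr$subtask)]]
      inc <- inc_traj[[as.character(resp$trial[j])]]
      m <- compute_trial_metrics(
        tr, c(resp$response_x[j], resp$response_y[j]), inc, arena)
      k <- k + 1L
      met[k, ] <- as.numeric(m[1, ])
      sub_idx[k] <- i
    }
  }
  colnames(met) <- c("drop_error", "distance_error", "rotation_error",
                     "outgoing_distance", "incoming_distance",
                     "goal_to_boundary", "goal_to_landmark",
                     "mean_move_to_boundary", "mean_move_to_landmark")
  out <- cbind(
    cohort$subjects[sub_idx, c("subject", "group", "genotype", "age",
                               "sex", "site")],
    cohort$responses[, c("block", "subtask", "trial", "n_trees", "stars")],
    as.data.frame(met)
  )
  rownames(out) <- NULL
  out$apoe <- as.integer(out$group == "risk")
  for (v in c("drop_error", "distance_error", "rotation_error")) {
    perf <- paste0("performance",
                   switch(v, drop_error = "",
                          distance_error = "_distance",
                          rotation_error = "_rotation"))
    out[[perf]] <- performance_transform(out[[v]])
  }
  out
}

#' Stack outgoing and incoming distance into one long table
#'
#' Produces the data layout of the combined path-distance model (model
#' "1c"): each trial appears twice, once per distance type, with
#' `path_distance` holding the distance value and `distance_type` coding
#' the type (0 = outgoing, 1 = incoming).
#'
#' @param metrics A [cohort_metrics()] table (or any data frame with
#'   `outgoing_distance` and `incoming_distance` columns).
#' @return The doubled data frame with `path_distance` and
#'   `distance_type` columns.
#' @export
stack_path_distances <- function(metrics) {
  out <- metrics
  out$path_distance <- out$outgoing_distance
  out$distance_type <- 0
  inc <- metrics
  inc$path_distance <- inc$incoming_distance
  inc$distance_type <- 1
  res <- rbind(out, inc)
  rownames(res) <- NULL
  res
}

#' Score the Santa Barbara Sense of Direction questionnaire
#'
#' Computes the overall SBSOD mean and two strategy subscores from the 15
#' Likert items: "mappers" from items 7, 9, 13, 15 and "egocentric
#' navigators" from items 4, 6, 14. Reverse-keyed items (6, 13, 15 among
#' the subscale items) are recoded as `scale_max + 1 - x` before
#' averaging. Strategy flags come from a within-cohort median split of
#' the subscores; respondents exactly at the median count as
#' below-median (flag `FALSE`).
#'
#' @param item_responses An n x 15 matrix or data frame of Likert
#'   responses.
#' @param scale_max Maximum of the response scale (default 7, the
#'   instrument's standard 1-7 scale).
#' @param reverse_items Indices of reverse-keyed items among the scored
#'   items.
#' @return A data frame with `mean_score`, `mapper_score`, `ego_score`,
#'   `mapper_flag`, `ego_flag`.
#' @export
sbsod_score <- function(item_responses, scale_max = 7,
                        reverse_items = c(6, 13, 15)) {
  x <- as.matrix(item_responses)
  if (ncol(x) != 15L) stop("SBSOD has 15 items")
  if (any(is.na(x))) warning("missing SBSOD items propagate to NA scores")
  rec <- x
  rec[, reverse_items] <- scale_max + 1 - x[, reverse_items]
  mapper <- rowMeans(rec[, c(7, 9, 13, 15), drop = FALSE])
  ego <- rowMeans(rec[, c(4, 6, 14), drop = FALSE])
  data.frame(
    mean_score = rowMeans(rec),
    mapper_score = mapper,
    ego_score = ego,
    mapper_flag = mapper > stats::median(mapper, na.rm = TRUE),
    ego_flag = ego > stats::median(ego, na.rm = TRUE)
  )
}
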