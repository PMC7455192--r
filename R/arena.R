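#' Arena configuration for the virtual path-integration task
#'
#' Describes the circular virtual environment used by the "apple game":
#' a navigable disc whose outer part is a speed-reduction zone, an optional
#' circular boundary wall (boundary-supported subtask) and an optional
#' intramaze landmark (landmark-supported subtask), plus the invisible
#' 8 x 8 location grid on which goals and trees are balanced. All lengths
#' are in virtual meters (vm); 310 vm corresponds to ~1.65 real-world
#' meters via the avatar's eye height (see [vm_to_meters()]).
#'
#' @param navigable_radius Radius of the navigable disc (vm).
#' @param speed_zone_inner_radius Radius at which speed attenuation begins
#'   when heading outward (vm).
#' @param boundary_present Logical; is the circular wall visible?
#' @param boundary_radius Radius of the boundary wall (vm).
#' @param boundary_height Height of the boundary wall (vm).
#' @param landmark_present Logical; is the landmark (lighthouse) visible?
#' @param landmark_xy Landmark position, length-2 numeric (vm).
#' @param landmark_height Landmark height (vm).
#' @param eye_height Avatar eye height (vm); anchors the vm-to-meter scale.
#' @param grid_edge Edge length of one grid square (vm).
#' @param grid_dims Integer vector of grid dimensions (columns, rows).
#'
#' @return An object of class `arena_config` (a list of the above fields
#'   plus `arena_diameter = 2 * navigable_radius`).
#' @examples
#' arena <- arena_config()
#' arena$arena_diameter # 13576 vm, ~72 real-world meters
#' @export
arena_config <- function(navigable_radius = 6788,
                         speed_zone_inner_radius = 5657,
                         boundary_present = FALSE,
                         boundary_radius = 6788,
                         boundary_height = 2050,
                         landmark_present = FALSE,
                         landmark_xy = c(1600, 800),
                         landmark_height = 1300,
                         eye_height = 310,
                         grid_edge = 800,
                         grid_dims = c(8L, 8L)) {
  stopifnot(
    speed_zone_inner_radius < navigable_radius,
    length(landmark_xy) == 2L, length(grid_dims) == 2L,
    grid_edge > 0, all(grid_dims >= 1)
  )
  # The grid must fit inside the navigable disc (its far corner included).
  half_diag <- sqrt(sum((grid_dims * grid_edge / 2)^2))
  stopifnot(half_diag <= navigable_radius)
  structure(
    list(
      navigable_radius = navigable_radius,
      speed_zone_inner_radius = speed_zone_inner_radius,
      boundary_present = boundary_present,
      boundary_radius = boundary_radius,
      boundary_height = boundary_height,
      landmark_present = landmark_present,
      landmark_xy = as.numeric(landmark_xy),
      landmark_height = landmark_height,
      eye_height = eye_height,
      grid_edge = grid_edge,
      grid_dims = as.integer(grid_dims),
      arena_diameter = 2 * navigable_radius
    ),
    class = "arena_config"
  )
}

#' Arena variant for a given subtask
#'
#' Convenience wrapper: "PPI" (pure path integration) has neither cue,
#' "BPI" shows the boundary wall, "LPI" shows the landmark.
#'
#' @param subtask One of `"PPI"`, `"BPI"`, `"LPI"`.
#' @param ... Passed on to [arena_config()].
#' @return An `arena_config`.
#' @export
subtask_arena <- function(subtask = c("PPI", "BPI", "LPI"), ...) {
  subtask <- match.arg(subtask)
  arena_config(
    boundary_present = subtask == "BPI",
    landmark_present = subtask == "LPI",
    ...
  )
}

#' Centers of the 8 x 8 location grid
#'
#' @param arena An [arena_config()].
#' @return A matrix with one row per grid cell (column-major over columns
#'   then rows) and columns `x`, `y` in vm, centered on the arena center.
#' @export
grid_cell_centers <- function(arena = arena_config()) {
  nc <- arena$grid_dims[1]
  nr <- arena$grid_dims[2]
  cx <- (seq_len(nc) - (nc + 1) / 2) * arena$grid_edge
  cy <- (seq_len(nr) - (nr + 1) / 2) * arena$grid_edge
  out <- as.matrix(expand.grid(x = cx, y = cy))
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Convert virtual meters to real-world meters
#'
#' The conversion is anchored on the avatar's eye height: 310 vm
#' corresponds to ~1.65 m, so `d * 1.65 / 310`.
#'
#' @param d Distances in vm (non-negative).
#' @return Distances in meters.
#' @examples
#' vm_to_meters(310)   # 1.65
#' vm_to_meters(13576) # ~72 m arena diameter
#' @export
vm_to_meters <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances in vm must be finite and non-negative")
  }
  d * 1.65 / 310
}

#' Movement-speed attenuation factor
#'
#' Speed is attenuated in the outer ring of the arena so that the
#' effective movement radius is the same with and without a visible
#' boundary: beyond the inner radius of the speed zone, speed falls
#' linearly to zero at the navigable radius -- but only when heading
#' away from the center. Heading toward the center (negative radial
#' velocity component) always allows full speed.
#'
#' @param xy Position, length-2 numeric or n x 2 matrix (vm).
#' @param heading_deg Heading(s) in degrees (0 = +x axis,
#'   counterclockwise).
#' @param arena An [arena_config()].
#' @return Speed factor(s) in \[0, 1\].
#' @examples
#' speed_factor(c(5000, 0), 0)    # 1: inside the full-speed zone
#' speed_factor(c(6788, 0), 0)    # 0: at the rim, heading outward
#' speed_factor(c(6222.5, 0), 0)  # 0.5: midpoint of the ramp
#' @export
speed_factor <- function(xy, heading_deg, arena = arena_config()) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  r <- vnorm(xy)
  if (any(r > arena$navigable_radius + 1e-9)) {
    stop("position outside the navigable radius")
  }
  heading_deg <- rep_len(heading_deg, nrow(xy))
  # radial unit vector; at the exact center every heading counts as inward
  ur <- xy / ifelse(r > 0, r, 1)
  uh <- cbind(cos(deg2rad(heading_deg)), sin(deg2rad(heading_deg)))
  outward <- rowSums(ur * uh) >= 0 & r > 0
  ramp <- (arena$navigable_radius - r) /
    (arena$navigable_radius - arena$speed_zone_inner_radius)
  out <- ifelse(r <= arena$speed_zone_inner_radius | !outward,
                1, pmax(0, pmin(1, ramp)))
  as.numeric(out)
}

#' Star feedback from the drop error
#'
#' After each trial the participant's response is scored with zero to
#' three stars using strict thresholds on the drop error (Euclidean
#' distance between response and goal): below 1600 vm gives three stars,
#' below 3200 vm two, below 6400 vm one, otherwise zero. Boundary values
#' fall to the lower star count.
#'
#' @param drop_error Drop error(s) in vm, non-negative.
#' @return Integer star counts in 0..3.
#' @examples
#' assign_star_feedback(c(0, 1600, 3199, 6400))
#' @export
assign_star_feedback <- function(drop_error) {
  if (any(!is.finite(drop_error)) || any(drop_error < 0)) {
    stop("drop_error must be finite and non-negative")
  }
  as.integer((drop_error < 1600) + (drop_error < 3200) + (drop_error < 6400))
}

#' Generate a balanced set of task trials
#'
#' Builds the trial sets for the path-integration subtasks. Each subtask
#' block holds 16 trials containing one to five trees in the composition
#' 1 tree x 3 trials, 2 x 3, 3 x 4, 4 x 3, 5 x 3 (48 tree locations), so
#' that the 16 goal (basket) locations and 48 tree locations together
#' visit each of the 64 grid squares exactly once per block. Trial order
#' and the cell assignment are randomized by `seed`. The long paradigm
#' version doubles every subtask (96 trials in total) with block order
#' pseudorandomized so the same subtask never repeats back-to-back; the
#' short version has one block per subtask (48 trials).
#'
#' @param seed Integer seed controlling trial order and cell assignment.
#' @param long_version Logical; two blocks per subtask if `TRUE`.
#' @param arena An [arena_config()] (defines the location grid).
#' @return A data frame of class `pi_trial_set` with one row per trial:
#'   `block`, `subtask`, `trial_index` (within block), `n_trees`,
#'   `goal_x`, `goal_y`, and list columns `trees` (n_trees x 2 matrix of
#'   tree positions; the last tree is the retrieval location) and `cells`
#'   (grid-cell indices used by the trial, goal first).
#' @examples
#' ts <- generate_trial_set(1)
#' table(ts$subtask) # 16 trials each
#' @export
generate_trial_set <- function(seed, long_version = FALSE,
                               arena = arena_config()) {
  centers <- grid_cell_centers(arena)
  n_cells <- nrow(centers)
  composition <- rep(1:5, times = c(3L, 3L, 4L, 3L, 3L))
  stopifnot(sum(composition) + length(composition) == n_cells)

  subtasks <- c("PPI", "BPI", "LPI")
  blocks <- if (long_version) rep(subtasks, 2L) else subtasks

  with_seed(seed, {
    if (long_version) {
      # pseudorandomize block order so the same subtask never repeats
      for (i in 1:100) {
        ord <- sample(blocks)
        if (!any(ord[-1] == ord[-length(ord)])) break
      }
      if (any(ord[-1] == ord[-length(ord)])) {
        stop("could not pseudorandomize block order") # unreachable in practice
      }
      blocks <- ord
    }
    rows <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      n_trees <- sample(composition)        # randomized trial order
      perm <- sample.int(n_cells)           # one full-coverage permutation
      offset <- 0L
      cells <- trees <- vector("list", length(n_trees))
      goal_cell <- integer(length(n_trees))
      for (i in seq_along(n_trees)) {
        take <- perm[offset + seq_len(1L + n_trees[i])]
        offset <- offset + 1L + n_trees[i]
        goal_cell[i] <- take[1]
        cells[[i]] <- take
        trees[[i]] <- centers[take[-1], , drop = FALSE]
      }
      rows[[b]] <- data.frame(
        block = b,
        subtask = blocks[b],
        trial_index = seq_along(n_trees),
        n_trees = n_trees,
        goal_x = centers[goal_cell, 1],
        goal_y = centers[goal_cell, 2]
      )
      rows[[b]]$trees <- trees
      rows[[b]]$cells <- cells
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("pi_trial_set", "data.frame")
    out
  })
}

#' Write a trajectory logfile
#'
#' Trajectory streams are tab-delimited UTF-8 text with a mandatory
#' header and one row per 200-ms position sample, columns `t_ms`, `x_vm`,
#' `y_vm`, `heading_deg`, `phase`, `trial`.
#'
#' @param stream Trajectory data frame with the columns above.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_logfile <- function(stream, path) {
  cols <- c("t_ms", "x_vm", "y_vm", "heading_deg", "phase", "trial")
  stopifnot(all(cols %in% names(stream)))
  utils::write.table(stream[, cols], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a trajectory logfile
#'
#' Parses the tab-delimited trajectory dialect written by
#' [write_logfile()] and validates the sampling contract: within each
#' trial, time must be strictly increasing in steps of exactly 200 ms.
#'
#' @param path Logfile path.
#' @return A trajectory data frame (possibly zero rows, with a warning,
#'   for an empty file).
#' @export
read_logfile <- function(path) {
  cols <- c("t_ms", "x_vm", "y_vm", "heading_deg", "phase", "trial")
  raw <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("empty logfile: ", path)
    out <- data.frame(t_ms = numeric(), x_vm = numeric(), y_vm = numeric(),
                      heading_deg = numeric(), phase = character(),
                      trial = integer())
    return(out)
  }
  if (!all(cols %in% names(raw))) {
    stop("malformed logfile header in ", path, "; expected columns ",
         paste(cols, collapse = ", "))
  }
  num <- c("t_ms", "x_vm", "y_vm", "heading_deg")
  for (v in num) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(is.na(x) & !is.na(raw[[v]]))
    if (length(bad)) {
      stop(sprintf("parse error in %s: non-numeric '%s' at line %d",
                   path, v, bad[1] + 1L)) # +1 for the header line
    }
    raw[[v]] <- x
  }
  raw <- raw[order(raw$trial, raw$t_ms), , drop = FALSE]
  for (tr in unique(raw$trial)) {
    t <- raw$t_ms[raw$trial == tr]
    if (any(diff(t) <= 0)) {
      stop("non-monotone time within trial ", tr, " in ", path)
    }
    if (any(diff(t) != 200)) {
      stop("sampling violation in trial ", tr, " of ", path,
           ": samples must be exactly 200 ms apart")
    }
  }
  rownames(raw) <- NULL
  raw
}
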