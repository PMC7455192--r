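#' Annotate fMRI volumes with direction and speed; drop slow volumes
#'
#' For every volume the 200-ms trajectory samples that *caused* its
#' signal -- the window `[onset - hrf_lag, onset + TR - hrf_lag)`, i.e.
#' behavior one hemodynamic peak delay before acquisition -- are
#' summarized: circular mean movement direction (vector average --
#' robust at the 0/360 wrap), mean speed, and the set of contributing
#' trials. Volumes whose mean speed falls below `speed_fraction` of the
#' subject's average movement speed are excluded, as are volumes without
#' movement samples.
#'
#' @param trajectory Logfile-dialect data frame, time-aligned with the
#'   BOLD series (volume `v` covers `[(v-1)*tr, v*tr)` seconds).
#' @param bold A `bold_series` (or a list with `tr` and `n_volumes`).
#' @param speed_fraction Exclusion threshold as a fraction of the mean
#'   movement speed (default 0.33).
#' @param hrf_lag Hemodynamic delay (s) by which behavior is shifted
#'   when attributed to volumes; defaults to the canonical [hrf()] peak
#'   (5 s). Set to 0 to annotate with strictly concurrent samples.
#' @return A data frame with `volume`, `mean_direction`, `mean_speed`,
#'   and list column `trials`; one row per retained volume.
#' @export
annotate_and_filter <- function(trajectory, bold, speed_fraction = 0.33,
                                hrf_lag = 5) {
  dt <- diff(trajectory$t_ms[1:2]) / 1000
  xy <- cbind(trajectory$x_vm, trajectory$y_vm)
  step <- vnorm(rbind(c(0, 0), diff(xy)))
  step[1] <- 0
  speed <- step / dt
  # sample midpoint convention, mirroring the volume averaging of the
  # BOLD resampler; behavior is shifted forward by the hemodynamic lag
  vol <- floor((trajectory$t_ms / 1000 - dt / 2 + hrf_lag) / bold$tr) + 1L
  keep_idx <- vol >= 1L & vol <= bold$n_volumes
  moving <- speed > 1e-9

  mean_speed_all <- mean(speed[moving & keep_idx])
  mv <- which(moving & keep_idx)
  if (length(mv) == 0L) stop("no volumes with movement samples: empty analysis")
  vf <- factor(vol[mv])
  # direction from movement samples (circular mean via complex resultant);
  # speed over the whole window, so volumes dominated by standing or
  # turning in place drop out below
  res <- tapply(exp(1i * deg2rad(trajectory$heading_deg[mv])), vf, mean)
  dir <- ifelse(Mod(res) < 1e-12, NA_real_, wrap360(rad2deg(Arg(res))))
  all_vf <- factor(vol[keep_idx], levels = levels(vf))
  spd <- tapply(speed[keep_idx], all_vf, mean)
  ann <- data.frame(volume = as.integer(levels(vf)),
                    mean_direction = as.numeric(dir),
                    mean_speed = as.numeric(spd))
  ann$trials <- unname(tapply(trajectory$trial[mv], vf,
                              function(x) unique(x), simplify = FALSE))
  # a volume whose headings cancel exactly has no usable direction
  keep <- ann$mean_speed >= speed_fraction * mean_speed_all &
    !is.na(ann$mean_direction)
  out <- ann[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no volumes survive the slow-movement filter")
  rownames(out) <- NULL
  out
}

#' Average volume patterns within 5-degree direction bins
#'
#' @param annotations Output of [annotate_and_filter()].
#' @param bold A `bold_series` whose rows are volumes.
#' @param bin_width Bin width in degrees (default 5, i.e. 72 bins).
#' @return A list of class `bin_patterns`: `bin` (0-based index),
#'   `center` (degrees), `pattern` (bins x voxels matrix of mean
#'   patterns), `trials` (list of contributing trial sets), `n_volumes`.
#' @export
bin_directions <- function(annotations, bold, bin_width = 5) {
  idx <- floor(annotations$mean_direction / bin_width)
  idx[idx >= 360 / bin_width] <- 0L  # direction exactly 360 wraps to bin 0
  occupied <- sort(unique(idx))
  if (length(occupied) < 2L) {
    stop("fewer than 2 occupied direction bins: insufficient data")
  }
  pat <- t(vapply(occupied, function(b) {
    colMeans(bold$data[annotations$volume[idx == b], , drop = FALSE])
  }, numeric(ncol(bold$data))))
  trials <- lapply(occupied, function(b) {
    sort(unique(unlist(annotations$trials[idx == b])))
  })
  structure(
    list(bin = occupied,
         center = occupied * bin_width + bin_width / 2,
         pattern = pat,
         trials = trials,
         n_volumes = as.integer(table(factor(idx, levels = occupied)))),
    class = "bin_patterns"
  )
}

#' Fisher-z pattern similarity between direction bins
#'
#' Pearson correlations across voxels for every pair of direction bins,
#' Fisher z-transformed (`atanh`, with |r| capped at `1 - 1e-12`), with
#' the angular difference between bin centers (minimal circular distance
#' in 360-degree space). Pairs of bins whose contributing trial sets
#' intersect are excluded (temporal-autocorrelation guard: bins average
#' across trials, so any shared trial links the two patterns in time).
#'
#' @param bins A `bin_patterns` object.
#' @param exclude_same_trial Apply the shared-trial exclusion?
#' @return A data frame with `bin_i`, `bin_j`, `angle` (degrees in
#'   \[0, 180\]), `r`, `z`; zero-variance patterns are skipped with a
#'   warning.
#' @export
pattern_similarity <- function(bins, exclude_same_trial = TRUE) {
  nb <- length(bins$bin)
  stopifnot(nb >= 2, ncol(bins$pattern) >= 2)
  sds <- apply(bins$pattern, 1, stats::sd)
  if (any(sds == 0)) warning("zero-variance bin pattern(s) skipped")
  rmat <- suppressWarnings(stats::cor(t(bins$pattern)))
  # bin x trial incidence -> pairs sharing any trial
  all_trials <- sort(unique(unlist(bins$trials)))
  inc <- vapply(bins$trials, function(tt) all_trials %in% tt,
                logical(length(all_trials)))
  shared <- crossprod(inc * 1) > 0  # nb x nb
  ij <- which(upper.tri(rmat), arr.ind = TRUE)
  keep <- sds[ij[, 1]] > 0 & sds[ij[, 2]] > 0
  if (exclude_same_trial) keep <- keep & !shared[ij]
  ij <- ij[keep, , drop = FALSE]
  if (nrow(ij) == 0L) stop("no bin pairs survive the exclusions")
  r <- rmat[ij]
  data.frame(
    bin_i = bins$bin[ij[, 1]], bin_j = bins$bin[ij[, 2]],
    angle = ang_dist(bins$center[ij[, 1]], bins$center[ij[, 2]]),
    r = r,
    z = atanh(pmax(pmin(r, 1 - 1e-12), -1 + 1e-12))
  )
}

#' Rotational-symmetry contrast on pattern similarities
#'
#' Classifies every bin pair by its angular difference `alpha`: with
#' period `P = 360 / s`, pairs whose `alpha mod P` lies within `P/4` of 0
#' (circularly) are "aligned" (for sixfold symmetry: within 15 degrees of
#' a multiple of 60), the rest "misaligned" (near the half-period, e.g.
#' mod 60 = 30). The contrast is the mean Fisher z of aligned minus
#' misaligned pairs; a positive sixfold contrast is the grid-like
#' representation signature. The boundary (exactly P/4) counts as
#' aligned. The optional head-direction control removes pairs with
#' `alpha <= 15` degrees in 360-degree space before conditioning, so
#' similarity of same-direction movements cannot drive the contrast.
#'
#' @param pairs Data frame from [pattern_similarity()].
#' @param s Symmetry order (6 = hexadirectional; 4, 5, 7, 8 are
#'   controls).
#' @param exclude_headdir Remove near-zero angular differences first?
#' @param headdir_window Degrees of the head-direction exclusion window.
#' @return A list of class `symmetry_contrast`: `s`, `contrast`,
#'   `mean_z_aligned`, `mean_z_misaligned`, `n_aligned`, `n_misaligned`.
#' @export
symmetry_contrast <- function(pairs, s = 6, exclude_headdir = FALSE,
                              headdir_window = 15) {
  stopifnot(nrow(pairs) > 0, s >= 1)
  if (exclude_headdir) {
    pairs <- pairs[pairs$angle > headdir_window, , drop = FALSE]
  }
  period <- 360 / s
  m <- pairs$angle %% period
  dist0 <- pmin(m, period - m)
  aligned <- dist0 <= period / 4
  if (!any(aligned) || all(aligned)) {
    stop("undefined contrast: aligned or misaligned condition is empty")
  }
  structure(
    list(s = s,
         contrast = mean(pairs$z[aligned]) - mean(pairs$z[!aligned]),
         mean_z_aligned = mean(pairs$z[aligned]),
         mean_z_misaligned = mean(pairs$z[!aligned]),
         n_aligned = sum(aligned),
         n_misaligned = sum(!aligned)),
    class = "symmetry_contrast"
  )
}

#' Run the full grid-like-representation pipeline
#'
#' Convenience chain: [annotate_and_filter()] -> [bin_directions()] ->
#' [pattern_similarity()] -> [symmetry_contrast()].
#'
#' @param trajectory,bold,speed_fraction See [annotate_and_filter()].
#' @param s,exclude_headdir See [symmetry_contrast()].
#' @param exclude_same_trial See [pattern_similarity()].
#' @return A `symmetry_contrast`.
#' @export
glr_contrast <- function(trajectory, bold, s = 6, speed_fraction = 0.33,
                         exclude_same_trial = TRUE,
                         exclude_headdir = FALSE, hrf_lag = 5) {
  ann <- annotate_and_filter(trajectory, bold, speed_fraction,
                             hrf_lag = hrf_lag)
  bins <- bin_directions(ann, bold)
  pairs <- pattern_similarity(bins, exclude_same_trial = exclude_same_trial)
  symmetry_contrast(pairs, s = s, exclude_headdir = exclude_headdir)
}

# Rayleigh z statistic (n * R^2) for directions in degrees.
rayleigh_z <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  n <- length(th)
  r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  n * r^2
}

#' Permutation Rayleigh test of directional uniformity
#'
#' Bins movement directions into 5-degree bins (in 360-degree space, or
#' in 60-degree space after `direction mod 60`, where sixfold-symmetric
#' sampling biases would appear), computes the Rayleigh z on the binned
#' directions, and compares it against a surrogate distribution obtained
#' by shuffling every observation into a uniformly random bin (the
#' uniform-sampling null). The returned p value is the rank of the
#' empirical z among the surrogates,
#' `(1 + #{z_surr >= z}) / (n_shuffle + 1)`; a fully concentrated sample
#' attains the minimum `1 / (n_shuffle + 1)`.
#'
#' @param directions Movement directions in degrees (>= 10 values).
#' @param space 360 (full circle) or 60 (grid-periodic space).
#' @param bin_width Bin width in degrees.
#' @param n_shuffle Number of shuffles.
#' @param seed Integer seed.
#' @return A list with `z` (empirical), `p` (surrogate rank p),
#'   `n_shuffle`.
#' @export
rayleigh_uniformity <- function(directions, space = 360, bin_width = 5,
                                n_shuffle = 10000, seed = 1) {
  stopifnot(space %in% c(60, 360))
  if (length(directions) < 10) stop("need at least 10 directions")
  d <- wrap360(directions) %% space
  # scale to the full circle so the Rayleigh statistic applies in 60-space
  scale <- 360 / space
  bins <- floor(d / bin_width)
  n_bins <- space / bin_width
  bins[bins >= n_bins] <- 0
  counts <- tabulate(bins + 1L, nbins = n_bins)
  centers <- (seq_len(n_bins) - 0.5) * bin_width * scale
  z_emp <- rayleigh_z(rep(centers, counts))
  n_obs <- sum(counts)
  z_surr <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      cs <- tabulate(sample.int(n_bins, n_obs, replace = TRUE),
                     nbins = n_bins)
      rayleigh_z(rep(centers, cs))
    }, numeric(1))
  })
  list(z = z_emp,
       p = (1 + sum(z_surr >= z_emp)) / (n_shuffle + 1),
       n_shuffle = n_shuffle)
}

#' Temporal and spatial signal-to-noise ratio
#'
#' Temporal SNR: per-voxel mean over SD across time points, averaged over
#' voxels. Spatial SNR: per-volume mean over SD across voxels, averaged
#' over volumes. A zero SD anywhere returns `NA` with a warning
#' (constant-series guard).
#'
#' @param bold A `bold_series` (volumes x voxels matrix in `$data`).
#' @return A list with `temporal` and `spatial`.
#' @export
snr <- function(bold) {
  x <- bold$data
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  sd_t <- apply(x, 2, stats::sd)
  sd_s <- apply(x, 1, stats::sd)
  if (any(sd_t == 0) || any(sd_s == 0)) {
    warning("zero variance encountered; SNR undefined")
    return(list(temporal = NA_real_, spatial = NA_real_))
  }
  list(temporal = mean(colMeans(x) / sd_t),
       spatial = mean(rowMeans(x) / sd_s))
}
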