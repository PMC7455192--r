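# Minimal hand-built fixtures: a bold series is just a list with $data,
# $tr, $n_volumes, so edge cases can be constructed directly.

mk_bold <- function(data, tr = 2.5) {
  list(data = data, tr = tr, n_volumes = nrow(data))
}

# trajectory with one constant heading per volume window (12.5 samples),
# shifted so the lag-annotated window sees exactly that heading
mk_vol_traj <- function(headings, per_vol = 12.5, hrf_lag = 5) {
  n <- ceiling(length(headings) * per_vol)
  hd <- headings[pmin(length(headings),
                      floor(((1:n) - 0.5) / per_vol) + 1)]
  xy <- apply(cbind(cos(hd * pi / 180), sin(hd * pi / 180)) * 200, 2, cumsum)
  # shift times back by the lag so window v annotates heading v
  data.frame(t_ms = 200 * (1:n) - hrf_lag * 1000, x_vm = xy[, 1],
             y_vm = xy[, 2], heading_deg = hd, phase = "outgoing",
             trial = pmin(length(headings),
                          floor(((1:n) - 0.5) / per_vol) + 1))
}

test_that("volume annotation takes circular means and filters slow volumes", {
  # constant heading 90 within a volume
  traj <- mk_vol_traj(rep(90, 4))
  bold <- mk_bold(matrix(rnorm(4 * 5), 4))
  ann <- annotate_and_filter(traj, bold)
  expect_true(all(abs(ann$mean_direction - 90) < 1e-6))

  # circular mean across the wrap: {350, 10} -> 0, not 180
  expect_equal(pathintlab:::circ_mean(c(350, 10)), 0, tolerance = 1e-9)
  traj2 <- mk_vol_traj(c(350, 10, 350, 10))
  traj2$heading_deg <- rep(c(350, 10), length.out = nrow(traj2))
  ann2 <- annotate_and_filter(traj2, mk_bold(matrix(rnorm(20), 4)))
  expect_true(all(pmin(ann2$mean_direction, 360 - ann2$mean_direction) < 1))

  # all speeds equal -> nothing excluded
  expect_equal(nrow(ann), 4L)
})

test_that("direction binning averages patterns within 5-degree bins", {
  traj <- mk_vol_traj(c(2, 3, 200, 200))
  bold <- mk_bold(rbind(c(1, 0, 2), c(3, 2, 0), c(5, 5, 5), c(7, 9, 11)))
  ann <- annotate_and_filter(traj, bold)
  bins <- bin_directions(ann, bold)
  expect_equal(length(bins$bin), 2L)
  i0 <- which(bins$bin == 0)
  expect_equal(bins$pattern[i0, ], c(2, 1, 1))       # mean of volumes 1, 2
  expect_equal(bins$center, bins$bin * 5 + 2.5)
  expect_equal(sort(unlist(bins$trials[[i0]])), 1:2)

  # single occupied bin is insufficient
  traj1 <- mk_vol_traj(c(1, 2, 3, 4))
  expect_error(bin_directions(annotate_and_filter(traj1, bold), bold),
               "fewer than 2")
})

test_that("pattern similarity: hand Pearson, caps, and trial exclusion", {
  traj <- mk_vol_traj(c(2, 90, 181, 270))
  # volumes: patterns chosen so (1,0) vs (0,1) after mean removal -> r = -1
  bold <- mk_bold(rbind(c(1, 0), c(0, 1), c(5, 1), c(1, 5)))
  ann <- annotate_and_filter(traj, bold)
  bins <- bin_directions(ann, bold)
  pairs <- pattern_similarity(bins)
  expect_equal(nrow(pairs), choose(4, 2))
  expect_true(all(abs(abs(pairs$r) - 1) < 1e-12))
  expect_true(all(is.finite(pairs$z)))            # capped at atanh(1-1e-12)
  expect_equal(max(pairs$z), atanh(1 - 1e-12))

  # two bins sharing a trial are excluded
  traj$trial <- rep(c(7, 7, 2, 3), each = 13)[1:nrow(traj)]
  ann <- annotate_and_filter(traj, bold)
  bins <- bin_directions(ann, bold)
  pairs <- pattern_similarity(bins)
  shared7 <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- which(bins$bin == pairs$bin_i[k]); j <- which(bins$bin == pairs$bin_j[k])
    length(intersect(bins$trials[[i]], bins$trials[[j]])) > 0
  }, logical(1))
  expect_false(any(shared7))
})

test_that("symmetry conditions partition all pairs, with stated tie rule", {
  # exhaustive check over all 72 x 71 / 2 center pairs
  centers <- 0:71 * 5 + 2.5
  ij <- which(upper.tri(diag(72)), arr.ind = TRUE)
  alpha <- pathintlab:::ang_dist(centers[ij[, 1]], centers[ij[, 2]])
  pairs <- data.frame(angle = alpha, z = 0)
  for (s in c(4, 5, 6, 7, 8)) {
    period <- 360 / s
    m <- alpha %% period
    aligned <- pmin(m, period - m) <= period / 4
    sc <- symmetry_contrast(pairs, s = s)
    expect_equal(sc$n_aligned + sc$n_misaligned, nrow(pairs))
    expect_equal(sc$n_aligned, sum(aligned))
  }
  # worked cases: 120 is aligned at s = 6; 90 is the half-period
  expect_equal(symmetry_contrast(data.frame(angle = c(120, 90),
                                            z = c(1, 0)), 6)$contrast, 1)
})

test_that("head-direction exclusion removes near-zero angular differences", {
  pairs <- data.frame(angle = c(5, 10, 15, 60, 90), z = c(9, 9, 9, 1, 0))
  sc <- symmetry_contrast(pairs, s = 6, exclude_headdir = TRUE)
  expect_equal(sc$n_aligned + sc$n_misaligned, 2L)
  expect_equal(sc$contrast, 1)
})

test_that("surrogate Rayleigh test behaves at the extremes", {
  set.seed(30)
  r <- rayleigh_uniformity(runif(720, 0, 360), n_shuffle = 400, seed = 1)
  expect_gt(r$p, 0.01)
  # fully concentrated sample attains the minimum p
  rc <- rayleigh_uniformity(rep(90, 100), n_shuffle = 400, seed = 1)
  expect_equal(rc$p, 1 / 401)
  expect_error(rayleigh_uniformity(c(1, 2), n_shuffle = 10), "at least 10")
  # 60-degree space variant runs and is calibrated enough not to fire
  r60 <- rayleigh_uniformity(runif(720, 0, 360), space = 60,
                             n_shuffle = 400, seed = 2)
  expect_gt(r60$p, 0.01)
})

test_that("temporal and spatial SNR recover generating parameters", {
  set.seed(8)
  x <- matrix(rnorm(400 * 50, 100, 10), 400)
  s <- snr(mk_bold(x))
  expect_equal(s$temporal, 10, tolerance = 0.5)
  expect_equal(s$spatial, 10, tolerance = 0.5)
  # doubling the noise halves the temporal SNR
  s2 <- snr(mk_bold(matrix(rnorm(400 * 50, 100, 20), 400)))
  expect_equal(s$temporal / s2$temporal, 2, tolerance = 0.1)
  expect_warning(s3 <- snr(mk_bold(matrix(5, 3, 3))), "zero variance")
  expect_true(is.na(s3$temporal))
})

test_that("pipeline is invariant to voxel permutation", {
  traj <- mk_run_trajectory(13, n_trials = 12)
  b <- simulate_grid_bold(traj, voxel_sim_spec(n_voxels = 12,
                                               grid_amplitude = 1,
                                               noise_sd = 0.5), seed = 3)
  c1 <- glr_contrast(traj, b, s = 6)$contrast
  b$data <- b$data[, sample(ncol(b$data))]
  expect_equal(glr_contrast(traj, b, s = 6)$contrast, c1, tolerance = 1e-10)
})
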