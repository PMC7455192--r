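#' Canonical double-gamma hemodynamic response function
#'
#' The widely used canonical form: a gamma density peaking near 5 s minus
#' a scaled gamma undershoot peaking near 15 s,
#' `hrf(t) = dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6`.
#' Zero at `t = 0` and for negative `t`.
#'
#' @param t Time in seconds.
#' @param peak_shape,peak_rate Shape/rate of the response gamma.
#' @param under_shape,under_rate Shape/rate of the undershoot gamma.
#' @param under_ratio Undershoot amplitude ratio.
#' @return Response amplitude (arbitrary units).
#' @examples
#' tt <- seq(0, 30, 0.1)
#' tt[which.max(hrf(tt))] # ~5 s
#' @export
hrf <- function(t, peak_shape = 6, peak_rate = 1,
                under_shape = 16, under_rate = 1, under_ratio = 1 / 6) {
  out <- stats::dgamma(t, peak_shape, peak_rate) -
    stats::dgamma(t, under_shape, under_rate) * under_ratio
  out[t < 0] <- 0
  out
}

# Convolve a 5 Hz (or dt-sampled) neural series with the HRF.
convolve_hrf <- function(x, dt = 0.2, span = 32, ...) {
  kern <- hrf(seq(0, span, by = dt), ...) * dt
  n <- length(x)
  m <- length(kern)
  nn <- stats::nextn(n + m - 1, c(2, 3, 5))  # fast FFT length
  fx <- stats::fft(c(x, numeric(nn - n)))
  fk <- stats::fft(c(kern, numeric(nn - m)))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n)] / nn
}

# Convolve every column of a matrix with the HRF in one FFT batch.
convolve_hrf_mat <- function(xmat, dt = 0.2, span = 32, ...) {
  kern <- hrf(seq(0, span, by = dt), ...) * dt
  n <- nrow(xmat)
  m <- length(kern)
  nn <- stats::nextn(n + m - 1, c(2, 3, 5))
  fk <- stats::fft(c(kern, numeric(nn - m)))
  pad <- matrix(0, nn - n, ncol(xmat))
  fx <- stats::mvfft(rbind(xmat, pad))
  out <- Re(stats::mvfft(fx * fk, inverse = TRUE)) / nn
  out[seq_len(n), , drop = FALSE]
}

# Average a dt-sampled series into TR windows -> one value per volume.
# Sample i covers ((i-1)*dt, i*dt]; it is assigned to the volume containing
# its midpoint, which stays exact when tr/dt is non-integer (e.g. 12.5
# samples per 2.5-s volume at 5 Hz).
resample_tr <- function(x, dt = 0.2, tr = 2.5) {
  n_vol <- floor(length(x) * dt / tr)
  if (n_vol < 1) return(numeric(0))
  mid <- (seq_along(x) - 0.5) * dt
  idx <- floor(mid / tr) + 1L
  keep <- idx <= n_vol
  as.numeric(tapply(x[keep], idx[keep], mean))
}

#' Voxel-simulation specification
#'
#' @param n_voxels Number of voxels in the region of interest.
#' @param tr Repetition time in seconds.
#' @param grid_amplitude Amplitude of the directional (grid-population)
#'   modulation, signal units.
#' @param symmetry_order Rotational symmetry of the planted signal (6 =
#'   hexadirectional).
#' @param noise_sd SD of additive Gaussian voxel noise.
#' @param ar1 Lag-1 autocorrelation of the voxel noise (0 = white).
#' @param baseline Baseline signal level.
#' @param preferred_phase Optional vector of per-voxel preferred
#'   directions (degrees); drawn uniformly when `NULL`.
#' @param modulator_betas Optional named list of per-voxel weight vectors
#'   for additional 5 Hz modulator series passed to
#'   [simulate_grid_bold()].
#' @return An object of class `voxel_sim_spec`.
#' @export
voxel_sim_spec <- function(n_voxels = 30, tr = 2.5, grid_amplitude = 1,
                           symmetry_order = 6, noise_sd = 1, ar1 = 0,
                           baseline = 100, preferred_phase = NULL,
                           modulator_betas = NULL) {
  stopifnot(n_voxels >= 2, symmetry_order >= 1, noise_sd >= 0, tr > 0,
            abs(ar1) < 1)
  structure(
    list(n_voxels = n_voxels, tr = tr, grid_amplitude = grid_amplitude,
         symmetry_order = symmetry_order, noise_sd = noise_sd, ar1 = ar1,
         baseline = baseline, preferred_phase = preferred_phase,
         modulator_betas = modulator_betas),
    class = "voxel_sim_spec"
  )
}

#' Simulate multi-voxel ROI BOLD from a trajectory
#'
#' Generates a plantable grid-population signal: voxel `v` has neural
#' activity `grid_amplitude * cos(s * (theta(t) - phi_v))` during
#' movement samples (zero when stationary), where `theta` is the
#' momentary movement direction, `s` the symmetry order and `phi_v` the
#' voxel's preferred phase. Optional modulator series are added with
#' per-voxel weights. The neural series is convolved with the
#' canonical [hrf()] at the trajectory's 5 Hz resolution, averaged
#' within TR windows, and white Gaussian noise is added.
#'
#' @param trajectory Logfile-dialect data frame (200-ms samples with
#'   `heading_deg`, `x_vm`, `y_vm`, `trial`).
#' @param spec A [voxel_sim_spec()].
#' @param seed Integer seed.
#' @param modulators Optional named list of 5 Hz series (same length as
#'   the trajectory) combined via `spec$modulator_betas`.
#' @param roi_label Label stored on the returned series.
#' @return An object of class `bold_series`: list with `data` (volumes x
#'   voxels matrix), `tr`, `n_volumes`, `volume_onsets` (s),
#'   `preferred_phase`, and `roi_label`.
#' @export
simulate_grid_bold <- function(trajectory, spec = voxel_sim_spec(),
                               seed = 1, modulators = NULL,
                               roi_label = "synthetic_roi") {
  n <- nrow(trajectory)
  stopifnot(n > 1)
  dt <- diff(trajectory$t_ms[1:2]) / 1000
  xy <- cbind(trajectory$x_vm, trajectory$y_vm)
  disp <- rbind(c(0, 0), diff(xy))
  moving <- vnorm(disp) > 1e-9
  if (!any(moving)) warning("trajectory contains no movement samples")
  theta <- deg2rad(trajectory$heading_deg)

  with_seed(seed, {
    phi <- spec$preferred_phase %||% stats::runif(spec$n_voxels, 0, 360)
    phi_r <- deg2rad(phi)
    neural <- spec$grid_amplitude *
      cos(outer(spec$symmetry_order * theta, spec$symmetry_order * phi_r,
                "-")) # cos(s*theta - s*phi)
    neural[!moving, ] <- 0
    if (!is.null(modulators)) {
      for (nm in names(modulators)) {
        b <- spec$modulator_betas[[nm]]
        if (is.null(b)) next
        neural <- neural + outer(as.numeric(modulators[[nm]]),
                                 rep_len(b, spec$n_voxels))
      }
    }
    conv <- convolve_hrf_mat(neural, dt = dt)
    # volume assignment by sample midpoint (see resample_tr)
    n_vol <- floor(nrow(conv) * dt / spec$tr)
    idx <- floor(((seq_len(nrow(conv)) - 0.5) * dt) / spec$tr) + 1L
    keep <- idx <= n_vol
    vols <- rowsum(conv[keep, , drop = FALSE], idx[keep]) /
      as.numeric(table(idx[keep]))
    if (is.null(dim(vols))) vols <- matrix(vols, nrow = 1)
    noise <- matrix(stats::rnorm(length(vols), 0, spec$noise_sd),
                    nrow(vols))
    ar1 <- spec$ar1 %||% 0
    if (ar1 != 0) {
      noise <- apply(noise, 2, function(e) {
        as.numeric(stats::filter(e, ar1, method = "recursive")) *
          sqrt(1 - ar1^2) # keep the marginal SD at noise_sd
      })
    }
    vols <- vols + spec$baseline + noise
    structure(
      list(data = vols, tr = spec$tr, n_volumes = nrow(vols),
           volume_onsets = (seq_len(nrow(vols)) - 1) * spec$tr,
           preferred_phase = phi, roi_label = roi_label),
      class = "bold_series"
    )
  })
}
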