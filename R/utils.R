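# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed; kept below 2^31.
derive_seed <- function(seed, k) {
  (as.double(seed) * 2654435761 + as.double(k) * 40503) %% 2147483647
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (degrees) into [0, 360).
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Minimal circular distance between two angles in degrees, in [0, 180].
ang_dist <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b))
  pmin(d, 360 - d)
}

# Circular mean of angles in degrees (vector average); NA when resultant ~ 0.
circ_mean <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  s <- mean(sin(th))
  c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap360(rad2deg(atan2(s, c)))
}

# Euclidean norm of rows of a 2-column matrix, or of a length-2 vector.
vnorm <- function(p) {
  if (is.matrix(p)) sqrt(rowSums(p^2)) else sqrt(sum(p^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
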