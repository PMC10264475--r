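# Small numerical helpers shared across modules.

#' Round half away from zero
#'
#' Rounding convention used for all printed percent-change columns:
#' `round_half_away(0.5) == 1`, `round_half_away(-0.5) == -1`. Base R's
#' `round()` rounds half to even, which disagrees with the reporting
#' convention for exactly-half values.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values (still stored as doubles).
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section (Fibonacci) spiral point set. Deterministic for a given
#' `n`, with near-uniform area per point; used as the Shrake-Rupley test
#' sphere.
#'
#' @param n number of points (>= 1).
#' @return an `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Convert a unit quaternion (x, y, z, w) to a 3x3 rotation matrix.
quaternion_to_rotation <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Sample rotation matrices uniformly over SO(3)
#'
#' Shoemake's subgroup-algorithm quaternion sampler. Consumes the R RNG
#' stream; wrap in [with_preserved_seed()] for reproducibility.
#'
#' @param n number of rotations.
#' @return list of `n` proper rotation matrices (3x3, det = +1).
#' @export
random_rotations <- function(n) {
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  u3 <- stats::runif(n)
  q <- cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
  lapply(seq_len(n), function(k) quaternion_to_rotation(q[k, ]))
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Internal: assert a numeric matrix of coordinates (n x 3, finite).
check_coords <- function(x, what = "coordinates") {
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x)) {
    stop(what, " must be a numeric matrix with 3 columns", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(what, " contain non-finite values", call. = FALSE)
  }
  invisible(x)
}
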