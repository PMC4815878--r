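#' Uniform random rotations
#'
#' Samples unit quaternions uniformly over SO(3) by the standard
#' three-uniform-variate construction (Shoemake). Randomness comes from R's
#' RNG stream; callers seed with `set.seed()` for reproducibility — no global
#' state is kept by the package.
#'
#' @param n number of rotations.
#' @return an n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
random_orientation <- function(n = 1) {
  stopifnot(n >= 1)
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  q <- cbind(a * sin(2 * pi * u2),
             a * cos(2 * pi * u2),
             b * sin(2 * pi * u3),
             b * cos(2 * pi * u3))
  colnames(q) <- c("w", "x", "y", "z")
  q
}

#' Rotation matrix of a unit quaternion
#'
#' @param q length-4 numeric (w, x, y, z); normalized internally.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

# Near-uniform unit directions: Fibonacci sphere.
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z * z))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}
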