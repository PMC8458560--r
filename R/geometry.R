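# Small 3D vector helpers shared by the statistics, generator and
# reconstruction code. All angles here are radians; degrees appear only at
# the user-facing boundary.

vec_norm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rodrigues rotation of v about unit axis k by angle theta (right-hand rule).
rotate_about <- function(v, k, theta) {
  v * cos(theta) + cross3(k, v) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

# n uniform random unit vectors (rows).
runif_sphere <- function(n) {
  z <- stats::rnorm(3L * n)
  m <- matrix(z, ncol = 3L)
  m / sqrt(rowSums(m * m))
}

# A unit vector uniform on the circle orthogonal to unit vector u.
runif_orthogonal <- function(u) {
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(u, a))
  e2 <- cross3(u, e1)
  phi <- stats::runif(1L, 0, 2 * pi)
  e1 * cos(phi) + e2 * sin(phi)
}

# One draw from the von Mises-Fisher distribution on the 2-sphere with mean
# direction mu (unit) and concentration kappa >= 0. Uses the standard
# inversion for the cosine of the polar angle: for S^2 the density of
# w = cos(theta) is kappa * exp(kappa * w) / (2 sinh kappa) on [-1, 1].
rvmf1 <- function(mu, kappa) {
  if (kappa < 1e-8) return(drop(runif_sphere(1L)))
  u <- stats::runif(1L)
  # w = 1 + log(u + (1 - u) e^{-2 kappa}) / kappa, computed stably
  w <- 1 + log1p(-(1 - u) * (1 - exp(-2 * kappa))) / kappa
  w <- max(-1, min(1, w))
  v <- runif_orthogonal(mu)
  drop(w * mu + sqrt(max(0, 1 - w * w)) * v)
}
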