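# Independent oracles used across the suite. These deliberately take
# different computational routes than the package code they check.

# Circumcenter of three non-collinear points in 3D (vector identity route;
# the package recovers the same point through the chord-sagitta relation).
circumcenter3 <- function(a, b, c) {
  ab <- b - a
  ac <- c - a
  n <- crossv(ab, ac)
  num <- sum(ac * ac) * crossv(n, ab) + sum(ab * ab) * crossv(ac, n)
  a + num / (2 * sum(n * n))
}

crossv <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Brute-force ray-sphere intersection: sample the ray parameter on a fine
# grid and look for points inside the sphere.
ray_sphere_brute <- function(origin, dir, center, radius, t_max = 500, n = 20000) {
  t <- seq(t_max / n, t_max, length.out = n)
  px <- origin[1] + t * dir[1]
  py <- origin[2] + t * dir[2]
  pz <- origin[3] + t * dir[3]
  d2 <- (px - center[1])^2 + (py - center[2])^2 + (pz - center[3])^2
  any(d2 <= radius^2)
}

# Uniform-ish random rotation via QR of a Gaussian matrix, det forced to +1.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

dir_mat <- function(est) as.matrix(est[, c("dir_x", "dir_y", "dir_z")])
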