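# Small vector-geometry helpers shared by the analysis and generator code.
# All coordinates are in Angstrom; boxes are cubic with edge `box` (Angstrom)
# and the minimum-image convention applies whenever a box is present.

.xyz <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

# component-wise minimum-image displacement
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

# Euclidean distances between paired rows of a and b (n x 3 each)
.row_dist <- function(a, b, box = NULL) {
  d <- .min_image(a - b, box)
  sqrt(rowSums(d * d))
}

# full cross-distance matrix between rows of a (m x 3) and b (k x 3)
.cross_dist <- function(a, b, box = NULL) {
  dx <- .min_image(outer(a[, 1], b[, 1], "-"), box)
  dy <- .min_image(outer(a[, 2], b[, 2], "-"), box)
  dz <- .min_image(outer(a[, 3], b[, 3], "-"), box)
  sqrt(dx * dx + dy * dy + dz * dz)
}

# minimum distance between two coordinate sets
.min_cross_dist <- function(a, b, box = NULL) {
  min(.cross_dist(a, b, box))
}

# angle (degrees) at vertex v between points a and b, vectorized over rows
.angle_at <- function(v, a, b, box = NULL) {
  u1 <- .min_image(a - v, box)
  u2 <- .min_image(b - v, box)
  n1 <- sqrt(rowSums(u1 * u1))
  n2 <- sqrt(rowSums(u2 * u2))
  cosang <- rowSums(u1 * u2) / (n1 * n2)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# uniformly random rotation matrix (used in invariance tests and coil packing)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2
  ), nrow = 3, byrow = TRUE)
}

# run expr with a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# NeRF internal-coordinate placement: position of atom D given bonded chain
# C-B-A with bond length |D-A|, angle D-A-B (deg), dihedral D-A-B-C (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  ab <- .unit(a - b)
  n <- .unit(.cross3(b - c, ab))
  m <- .cross3(n, ab)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  a + d2[1] * ab + d2[2] * m + d2[3] * n
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
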