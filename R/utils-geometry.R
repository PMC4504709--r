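## Small 3-vector helpers shared across the geometry modules. All lengths in
## Angstrom, all angles in degrees at the API surface (radians internally).

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

## Signed angle (degrees, in (-180, 180]) from a to b about the axis m,
## measured in the plane perpendicular to m (right-hand rule).
signedAngleAbout <- function(a, b, m) {
  m <- unitv(m)
  ap <- a - sum(a * m) * m
  bp <- b - sum(b * m) * m
  na <- vnorm(ap); nb <- vnorm(bp)
  if (na < 1e-9 || nb < 1e-9) return(NA_real_)
  ang <- atan2(sum(cross3(ap, bp) * m), sum(ap * bp))
  deg(ang)
}

## Torsion angle (degrees) defined by four points, IUPAC sign convention.
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -deg(atan2(y, x))
}

## Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotationMatrix <- function(u, theta) {
  u <- unitv(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

## Run expr with a locally seeded RNG, restoring global state afterwards.
## All package randomness flows through this so generators are pure
## functions of their seed.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Place atom D given positions A-B-C, bond length |CD|, angle B-C-D (deg)
## and torsion A-B-C-D (deg): the standard internal-to-Cartesian step.
placeAtom <- function(a, b, c, length, angle, torsion) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- rad(angle); tor <- rad(torsion)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
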