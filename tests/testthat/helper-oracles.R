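# Independent oracles and small constructors used across the suite. These
# deliberately avoid the package's own code paths wherever they are used as
# the expected value.

# -- quaternion oracle ---------------------------------------------------

randomUnitQuaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

quatMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quatAngleDeg <- function(q) 2 * acos(min(1, abs(q[1]))) * 180 / pi

rotationAboutZ <- function(angleDeg) {
  th <- angleDeg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# -- analytic surface-area oracles --------------------------------------

sphereArea <- function(r, probe = 1.4) 4 * pi * (r + probe)^2

# Exposed area of two overlapping probe-expanded spheres (spherical caps).
twoSphereExposed <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  stopifnot(d < R1 + R2, d > abs(R1 - R2))
  cos1 <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  cos2 <- (d^2 + R2^2 - R1^2) / (2 * d * R2)
  a1 <- 4 * pi * R1^2 - 2 * pi * R1^2 * (1 - cos1)
  a2 <- 4 * pi * R2^2 - 2 * pi * R2^2 * (1 - cos2)
  c(a1 = a1, a2 = a2, total = a1 + a2)
}

# -- mass-action oracle (numeric root finding, no closed form) ----------

freeMacromoleculeNumeric <- function(total, ligand, kd) {
  f <- function(m) m * (1 + (ligand / (kd + m))) - total
  uniroot(f, c(0, total), tol = 1e-15)$root
}

# -- ITC mass-balance integration oracle --------------------------------
# Stepwise overflow-cell bookkeeping with the equilibrium solved by uniroot,
# independent of the package's quadratic form.

itcHeatsOracle <- function(n, kd, dh, geometry) {
  V0 <- geometry$cellVolume
  Xs <- geometry$syringeConcentration
  m <- geometry$cellConcentration
  x <- 0
  Cprev <- 0
  heats <- numeric(length(geometry$injectionVolumes))
  for (i in seq_along(heats)) {
    f <- geometry$injectionVolumes[i] / V0
    m <- m * (1 - f)
    x <- x * (1 - f) + Xs * f
    sites <- n * m
    freeSites <- if (x == 0 || sites == 0) sites else
      uniroot(function(s) s * (1 + x / (kd + s)) - sites,
              c(0, sites), tol = 1e-16)$root
    C <- sites - freeSites
    heats[i] <- dh * 1e9 * (C - Cprev * (1 - f)) * V0
    Cprev <- C
  }
  heats
}

# -- fixtures ------------------------------------------------------------

randomCloud <- function(n, scale = 10) matrix(rnorm(3 * n, sd = scale), n, 3)

# A minimal hand-written two-residue PDB text.
tinyPdbLines <- function() {
  c(paste0("ATOM      1  N   ALA A   1      11.104   6.134  -6.504",
           "  1.00  0.00           N"),
    paste0("ATOM      2  CA  ALA A   1      11.639   6.071  -5.147",
           "  1.00  0.00           C"),
    paste0("ATOM      3  CA  GLY A   2      12.345   7.123  -4.000",
           "  1.00  0.00           C"),
    "END")
}
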