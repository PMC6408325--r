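## superposition: least-squares rigid-body fitting (Kabsch), RMSD and
## rotation-angle extraction. This is the geometric core every conformational
## metric builds on, so it is authored here rather than delegated; bio3d's
## independent implementation serves as the cross-check oracle in the tests.

.asCoordMatrix <- function(x) {
  if (is.data.frame(x)) x <- coordMatrix(x)
  x <- as.matrix(x)
  if (ncol(x) != 3L || !is.numeric(x)) stop("expected an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rigid motion (rotation + translation, never a reflection)
#' minimizing the RMSD of `moving` onto `fixed` over paired points: center
#' both sets, take the SVD of the cross-covariance, and correct the sign of
#' the smallest singular direction so the determinant is +1.
#'
#' @param moving,fixed paired n x 3 coordinate matrices (or atom tables),
#'   n >= 3, not collinear.
#' @return a [SuperpositionResult-class]; the transform maps a row vector `p`
#'   to `p %*% t(rotation) + translation`.
#' @examples
#' set.seed(1)
#' cloud <- matrix(rnorm(60), ncol = 3)
#' kabschFit(cloud, cloud)  # rmsd 0, angle 0
#' @export
kabschFit <- function(moving, fixed) {
  m <- .asCoordMatrix(moving)
  f <- .asCoordMatrix(fixed)
  if (nrow(m) != nrow(f))
    stop("geometry error: point counts differ (", nrow(m), " vs ",
         nrow(f), ")")
  if (nrow(m) < 3L) stop("geometry error: need at least 3 point pairs")
  cm <- colMeans(m)
  cf <- colMeans(f)
  mc <- sweep(m, 2L, cm)
  fc <- sweep(f, 2L, cf)
  ## degenerate configurations (coincident or collinear points) have a
  ## rank-deficient point spread and no unique rotation
  if (svd(mc, nu = 0, nv = 0)$d[2L] < 1e-10 ||
      svd(fc, nu = 0, nv = 0)$d[2L] < 1e-10)
    stop("geometry error: degenerate (collinear or coincident) point set")
  H <- crossprod(mc, fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- mc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - fc)^2)))
  tr <- cf - as.numeric(cm %*% t(R))
  methods::new("SuperpositionResult", rotation = R, translation = tr,
               rmsd = rmsd, nPoints = nrow(m),
               rotationAngleDeg = .angleFromRotation(R))
}

.angleFromRotation <- function(R) {
  cosang <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Rotation angle of a rigid transform
#'
#' Scalar rotation magnitude in degrees, `acos((tr(R) - 1) / 2)`, in
#' [0, 180]. Invariant under conjugation by any proper rotation, so it does
#' not depend on the frame in which the transform is expressed.
#'
#' @param transform a [SuperpositionResult-class] or a 3x3 rotation matrix.
#' @return angle in degrees.
#' @export
rotationAngle <- function(transform) {
  R <- if (is(transform, "SuperpositionResult")) transform@rotation
       else as.matrix(transform)
  if (!identical(dim(R), c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("geometry error: not a proper orthonormal rotation matrix")
  .angleFromRotation(R)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix or atom table.
#' @param transform a [SuperpositionResult-class].
#' @return transformed n x 3 matrix (pairwise distances are preserved).
#' @export
applyTransform <- function(coords, transform) {
  stopifnot(is(transform, "SuperpositionResult"))
  x <- .asCoordMatrix(coords)
  sweep(x %*% t(transform@rotation), 2L, transform@translation, "+")
}

#' Invert a rigid transform
#' @param transform a [SuperpositionResult-class].
#' @return the inverse transform (rmsd/nPoints carried over unchanged).
#' @export
invertTransform <- function(transform) {
  stopifnot(is(transform, "SuperpositionResult"))
  R <- t(transform@rotation)
  methods::new("SuperpositionResult", rotation = R,
               translation = as.numeric(-transform@translation %*% t(R)),
               rmsd = transform@rmsd, nPoints = transform@nPoints,
               rotationAngleDeg = transform@rotationAngleDeg)
}

#' RMSD of paired coordinates without fitting
#'
#' @param coordsA,coordsB paired n x 3 matrices or atom tables.
#' @return square root of the mean squared deviation, Angstrom; symmetric in
#'   its arguments.
#' @export
rmsdFixed <- function(coordsA, coordsB) {
  a <- .asCoordMatrix(coordsA)
  b <- .asCoordMatrix(coordsB)
  if (nrow(a) != nrow(b)) stop("geometry error: point counts differ")
  sqrt(mean(rowSums((a - b)^2)))
}

## Rotation matrix about a unit axis (Rodrigues), used by the generators.
.rotationAboutAxis <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## A random proper rotation from a uniformly random unit quaternion.
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  .quaternionToMatrix(q)
}

.quaternionToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
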