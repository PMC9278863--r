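#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' \code{x -> R x + t}. Used throughout to express superpositions and
#' domain motions.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal (tolerance 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix must be proper (det +1); got det = ", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 numeric matrix of coordinates.
#' @param tf A \code{rigid_transform}.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  xyz <- rbind(xyz)  # accept a bare length-3 vector
  sweep(xyz %*% t(tf$rotation), 2, -tf$translation)
}

#' Invert a rigid transform
#' @param tf A \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by \code{angle_deg} degrees about \code{axis}
#' (normalized internally).
#'
#' @param axis length-3 direction of the rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' Angle theta recovered from trace(R) = 1 + 2 cos(theta), clamped to
#' guard against round-off outside [-1, 1].
#'
#' @param rotation 3x3 rotation matrix.
#' @return Angle in degrees, in [0, 180].
#' @export
rotation_angle <- function(rotation) {
  ct <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation angle:",
      format(rotation_angle(x$rotation), digits = 4), "deg\n",
      " translation:", paste(format(x$translation, digits = 4), collapse = ", "),
      "A\n")
  invisible(x)
}

# internal: angle (degrees) between two vectors
vec_angle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, ct))) * 180 / pi
}

# internal: unit-normalize
unitize <- function(v) v / sqrt(sum(v^2))
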