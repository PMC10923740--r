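## Rigid transforms: carriers for registration results and fragment motion.

#' Create a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector (mm).
#' @return object of class `hto_transform`; applying it maps `p` to
#'   `rotation %*% p + translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("validation error: rotation must be orthonormal with det +1",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "hto_transform")
}

#' Identity transform
#' @export
transform_identity <- function() rigid_transform()

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `hto_transform` objects.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t an `hto_transform`.
#' @export
transform_invert <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Rotation about an arbitrary axis
#'
#' @param point a point on the axis (mm).
#' @param direction axis direction (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return an `hto_transform`.
#' @export
rotation_about_axis <- function(point, direction, angle_deg) {
  u <- unit3(direction)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, as.numeric(point - R %*% point))
}

#' Apply a rigid transform
#'
#' Generic over points (length-3 vector or n x 3 matrix), meshes and
#' landmark sets; pairwise distances are preserved.
#'
#' @param obj point(s), `hto_mesh` or `hto_landmarks`.
#' @param t an `hto_transform`.
#' @return the transformed object, same type as the input.
#' @export
apply_transform <- function(obj, t) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(obj, t) {
  if (is.matrix(obj)) {
    sweep(obj %*% t(t$rotation), 2, -t$translation)
  } else {
    as.numeric(t$rotation %*% as.numeric(obj) + t$translation)
  }
}

#' @export
apply_transform.hto_mesh <- function(obj, t) {
  obj$vertices <- apply_transform(obj$vertices, t)
  obj
}

#' @export
apply_transform.hto_landmarks <- function(obj, t) {
  obj$positions <- apply_transform(obj$positions, t)
  obj
}

#' @export
print.hto_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("hto_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

## --- small vector helpers shared across the package ---

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate-frame error: zero-length direction", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## unsigned angle between vectors, degrees
vec_angle <- function(a, b) {
  ca <- sum(unit3(a) * unit3(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

## signed angle from a to b about axis n, degrees
signed_angle <- function(a, b, n) {
  n <- unit3(n)
  a <- unit3(a); b <- unit3(b)
  atan2(sum(n * cross3(a, b)), sum(a * b)) * 180 / pi
}
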