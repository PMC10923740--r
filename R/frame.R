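## Anatomic tibial coordinate frame.
##
## The tibial plateau defines the xy-plane: y runs posterior-to-anterior
## along the medial plateau (TMCP -> TMCA), the plane additionally contains
## the direction of the proximal joint line (MMPP -> MLPP), z is the plane
## normal oriented proximally, and x completes a right-handed frame (lateral
## for a RIGHT tibia, medial for a LEFT one). Origin is the tibial knee
## center (TKC).

#' Build the anatomic coordinate frame from plateau landmarks
#'
#' @param landmarks an `hto_landmarks` containing at least TMCA, TMCP, MMPP,
#'   MLPP and TKC.
#' @return object of class `hto_frame` with `origin`, `x_axis`, `y_axis`,
#'   `z_axis` (orthonormal, right-handed) and `side`.
#' @export
build_frame <- function(landmarks) {
  require_landmarks(landmarks, c("TMCA", "TMCP", "MMPP", "MLPP", "TKC"))
  tmca <- lm_get(landmarks, "TMCA"); tmcp <- lm_get(landmarks, "TMCP")
  mmpp <- lm_get(landmarks, "MMPP"); mlpp <- lm_get(landmarks, "MLPP")
  if (sqrt(sum((tmca - tmcp)^2)) < 1e-9)
    stop("degenerate-frame error: TMCA and TMCP coincide", call. = FALSE)
  if (sqrt(sum((mmpp - mlpp)^2)) < 1e-9)
    stop("degenerate-frame error: MMPP and MLPP coincide", call. = FALSE)
  y <- unit3(tmca - tmcp)            # posterior -> anterior
  u <- unit3(mlpp - mmpp)            # medial -> lateral joint line
  if (min(vec_angle(y, u), 180 - vec_angle(y, u)) < 1)
    stop("degenerate-frame error: frame-defining lines nearly collinear",
         call. = FALSE)
  ## z = plane normal oriented proximally; the five defining landmarks are
  ## (near-)coplanar on the plateau, so proximal is resolved via the declared
  ## side: for a RIGHT tibia u x y points proximal, for a LEFT tibia y x u.
  z <- if (landmarks$side == "RIGHT") unit3(cross3(u, y)) else unit3(cross3(y, u))
  x <- unit3(cross3(y, z))
  structure(list(origin = lm_get(landmarks, "TKC"),
                 x_axis = x, y_axis = y, z_axis = z,
                 side = landmarks$side),
            class = "hto_frame")
}

#' @export
print.hto_frame <- function(x, ...) {
  cat(sprintf("hto_frame (%s): origin (%.2f, %.2f, %.2f) mm\n", x$side,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  x (%+.4f %+.4f %+.4f)  y (%+.4f %+.4f %+.4f)  z (%+.4f %+.4f %+.4f)\n",
              x$x_axis[1], x$x_axis[2], x$x_axis[3],
              x$y_axis[1], x$y_axis[2], x$y_axis[3],
              x$z_axis[1], x$z_axis[2], x$z_axis[3]))
  invisible(x)
}

## world -> frame coordinates (rows of points)
to_frame <- function(points, frame) {
  B <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (is.matrix(points)) sweep(points, 2, frame$origin) %*% B
  else as.numeric(crossprod(B, points - frame$origin))
}

## frame -> world coordinates
from_frame <- function(points, frame) {
  B <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (is.matrix(points)) sweep(points %*% t(B), 2, -frame$origin)
  else as.numeric(B %*% points + frame$origin)
}

## frame-z coordinate of world points
frame_z <- function(points, frame) {
  if (is.matrix(points)) as.numeric(sweep(points, 2, frame$origin) %*% frame$z_axis)
  else sum((points - frame$origin) * frame$z_axis)
}

## medial direction along the frame x-axis: -x for RIGHT tibia, +x for LEFT
medial_sign <- function(frame_or_side) {
  side <- if (is.character(frame_or_side)) frame_or_side else frame_or_side$side
  if (side == "RIGHT") -1 else 1
}
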