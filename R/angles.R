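## Tibial joint-angle measurement: anatomical axis, MPTA, medial/lateral
## slope and torsion.
##
## Conventions (all side-normalized so mirror specimens report equal values):
##   MPTA     — medial-side angle between the proximal joint line
##              (MMPP -> MLPP) and the shaft axis, both projected into the
##              frame's coronal (x-z) plane; ~87 deg normal.
##   slope    — 90 deg minus the 3D angle between the posterior -> anterior
##              plateau line and the proximally directed shaft axis; a
##              plateau dipping posteriorly-distally is positive.
##   torsion  — angle between the dorsal plateau tangent (PMC -> PLC) and the
##              distal reference line (IFT -> MMAL), both projected into the
##              frame's axial (x-y) plane, folded to the line range
##              (-90, 90]; external rotation positive.

#' Tibial angle container
#'
#' @param mpta,medial_slope,lateral_slope,torsion angles in degrees.
#' @return object of class `hto_angles`.
#' @export
tibial_angles <- function(mpta, medial_slope, lateral_slope, torsion) {
  stopifnot(is.finite(mpta), is.finite(medial_slope), is.finite(lateral_slope),
            is.finite(torsion))
  if (mpta <= 45 || mpta >= 135)
    stop("validation error: MPTA outside (45, 135) degrees", call. = FALSE)
  if (abs(medial_slope) >= 45 || abs(lateral_slope) >= 45)
    stop("validation error: slope outside (-45, 45) degrees", call. = FALSE)
  if (abs(torsion) >= 90)
    stop("validation error: torsion outside (-90, 90) degrees", call. = FALSE)
  structure(list(mpta = mpta, medial_slope = medial_slope,
                 lateral_slope = lateral_slope, torsion = torsion),
            class = "hto_angles")
}

#' @export
print.hto_angles <- function(x, ...) {
  cat(sprintf("hto_angles: MPTA %.2f | medial slope %.2f | lateral slope %.2f | torsion %.2f deg\n",
              x$mpta, x$medial_slope, x$lateral_slope, x$torsion))
  invisible(x)
}

#' @export
as.data.frame.hto_angles <- function(x, ...) {
  data.frame(mpta_deg = x$mpta, medial_slope_deg = x$medial_slope,
             lateral_slope_deg = x$lateral_slope, torsion_deg = x$torsion)
}

#' Anatomical shaft axis from mid-shaft cross-sections
#'
#' The axis runs through the centroids of the shaft cross-sections at one
#' and two thirds of the shaft length below the plateau. Shaft length is
#' measured along frame z from the plateau landmark level (maximum frame-z
#' over the plateau landmarks) to the distal-most mesh vertex.
#'
#' @param mesh an `hto_mesh`.
#' @param frame an `hto_frame`.
#' @param landmarks the `hto_landmarks` the frame was built from.
#' @return a list of class `hto_axis` with `point` (on the axis, mm) and
#'   `direction` (unit vector, oriented proximally).
#' @export
anatomical_axis <- function(mesh, frame, landmarks) {
  plateau <- intersect(c("TMCA", "TMCP", "TLCA", "TLCP", "MMPP", "MLPP", "TKC"),
                       rownames(landmarks$positions))
  z_prox <- max(frame_z(landmarks$positions[plateau, , drop = FALSE], frame))
  z_min <- min(frame_z(mesh$vertices, frame))
  L <- z_prox - z_min
  if (L <= 0)
    stop("out-of-range error: plateau level below distal mesh end", call. = FALSE)
  c1 <- cross_section_centroid(mesh, frame, z_prox - L / 3)
  c2 <- cross_section_centroid(mesh, frame, z_prox - 2 * L / 3)
  structure(list(point = c2, direction = unit3(c1 - c2), length = L),
            class = "hto_axis")
}

#' Medial proximal tibial angle (MPTA)
#'
#' @param landmarks `hto_landmarks` with MMPP and MLPP.
#' @param axis an `hto_axis` (proximally oriented shaft axis).
#' @param frame an `hto_frame`.
#' @return MPTA in degrees, in (45, 135).
#' @export
compute_mpta <- function(landmarks, axis, frame) {
  require_landmarks(landmarks, c("MMPP", "MLPP"))
  u <- lm_get(landmarks, "MLPP") - lm_get(landmarks, "MMPP")  # medial -> lateral
  d <- axis$direction
  ## project into the coronal (x-z) plane: drop the frame-y component
  proj <- function(v) {
    vp <- c(sum(v * frame$x_axis), sum(v * frame$z_axis))
    if (sqrt(sum(vp^2)) < 1e-6 * sqrt(sum(v^2)))
      stop("degeneracy error: projection collapses in the coronal plane",
           call. = FALSE)
    vp
  }
  up <- proj(u); dp <- proj(d)
  ## medial-side angle between the joint line and the axis equals the planar
  ## angle between the med->lat joint line and the proximal axis direction
  ang <- acos(pmin(1, pmax(-1, sum(up * dp) / sqrt(sum(up^2) * sum(dp^2))))) * 180 / pi
  ang
}

#' Medial or lateral tibial slope
#'
#' @param landmarks `hto_landmarks` with (TMCA, TMCP) or (TLCA, TLCP).
#' @param axis an `hto_axis`.
#' @param side `"MEDIAL"` or `"LATERAL"`.
#' @return slope in degrees; positive when the plateau dips
#'   posteriorly-distally.
#' @export
compute_slope <- function(landmarks, axis, side = c("MEDIAL", "LATERAL")) {
  side <- match.arg(toupper(side), c("MEDIAL", "LATERAL"))
  nm <- if (side == "MEDIAL") c("TMCA", "TMCP") else c("TLCA", "TLCP")
  require_landmarks(landmarks, nm)
  pa <- unit3(lm_get(landmarks, nm[1]) - lm_get(landmarks, nm[2]))  # post -> ant
  asin(pmin(1, pmax(-1, sum(pa * axis$direction)))) * 180 / pi
}

#' Tibial torsion
#'
#' Angle between the dorsal tangent to the proximal plateau (PMC -> PLC) and
#' the distal reference line (deepest point of the incisura fibularis to the
#' outermost point of the medial malleolus), projected into the frame's
#' axial plane; reported as a line-to-line angle in (-90, 90], external
#' rotation positive, side-normalized.
#'
#' @param landmarks `hto_landmarks` with PMC, PLC, IFT and MMAL.
#' @param frame an `hto_frame`.
#' @return torsion in degrees.
#' @export
compute_torsion <- function(landmarks, frame) {
  require_landmarks(landmarks, c("PMC", "PLC", "IFT", "MMAL"))
  u1 <- lm_get(landmarks, "PLC") - lm_get(landmarks, "PMC")
  u2 <- lm_get(landmarks, "MMAL") - lm_get(landmarks, "IFT")
  proj <- function(v) {
    vp <- v - sum(v * frame$z_axis) * frame$z_axis
    if (sqrt(sum(vp^2)) < 1e-6 * sqrt(sum(v^2)))
      stop("degeneracy error: projection collapses in the axial plane",
           call. = FALSE)
    vp
  }
  raw <- signed_angle(proj(u1), proj(u2), frame$z_axis)
  raw <- if (landmarks$side == "RIGHT") raw else -raw
  ## line-to-line angle: fold to (-90, 90]
  fold <- ((raw + 90) %% 180) - 90
  if (fold == -90) fold <- 90
  fold
}

#' Measure all tibial angles of one specimen
#'
#' Composes [build_frame()], [anatomical_axis()] and the three angle
#' computations; deterministic for fixed inputs and invariant to the
#' specimen's pose in world coordinates.
#'
#' @param mesh an `hto_mesh`.
#' @param landmarks an `hto_landmarks` with the full 12-name vocabulary.
#' @return an `hto_angles`.
#' @export
measure_angles <- function(mesh, landmarks) {
  require_landmarks(landmarks, HTO_LANDMARK_NAMES)
  frame <- build_frame(landmarks)
  axis <- anatomical_axis(mesh, frame, landmarks)
  angles_from_axis(landmarks, frame, axis)
}

## angle battery given a precomputed frame-independent axis; split out so
## landmark-jitter studies can re-measure without re-slicing the mesh
angles_from_axis <- function(landmarks, frame, axis) {
  tibial_angles(mpta = compute_mpta(landmarks, axis, frame),
                medial_slope = compute_slope(landmarks, axis, "MEDIAL"),
                lateral_slope = compute_slope(landmarks, axis, "LATERAL"),
                torsion = compute_torsion(landmarks, frame))
}
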