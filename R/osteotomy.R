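## Virtual biplanar medial open-wedge osteotomy: plan construction, mesh
## splitting and rigid fragment motion about the lateral hinge.
##
## Plan geometry (all in the anatomic frame):
##   - ascending cut: coronal plane (normal = frame y) 10 mm behind the most
##     ventral point of the tuberosity (TTV), bounded above so the anterior
##     plateau rim stays proximal;
##   - main cut: contains the medial-slope line (TMCA -> TMCP), enters the
##     medial cortex half a plateau-width distal to the medial plateau, and
##     aims at the point 15 mm distal to the lateral plateau; its in-bone
##     extent ends 15 mm medial to the lateral cortex (the hinge);
##   - the opening angle about the hinge axis (frame y through the lateral
##     cortex point) is solved so the gap at the most medial cut point
##     equals the target, measured along frame z.

#' Plan a medial open-wedge HTO
#'
#' @param mesh an `hto_mesh` of the proximal tibia.
#' @param landmarks an `hto_landmarks` with the full vocabulary.
#' @param frame optional `hto_frame` (rebuilt from the landmarks if NULL).
#' @param axis optional `hto_axis` (not needed for the plan geometry itself;
#'   accepted so a precomputed measurement pipeline can be reused).
#' @param gap_target medial opening in mm, in (1, 20); default 8.
#' @param lateral_bridge intact lateral bridge length in mm (default 15).
#' @param aim_offset distal offset of the lateral aim point below the
#'   lateral plateau in mm (default 15).
#' @param ascending_offset posterior offset of the ascending cut behind TTV
#'   in mm (default 10).
#' @param ascending_top height of the ascending cut's upper bound above TTV
#'   in mm (default 20).
#' @return object of class `hto_plan`.
#' @export
plan_hto <- function(mesh, landmarks, frame = NULL, axis = NULL,
                     gap_target = 8, lateral_bridge = 15, aim_offset = 15,
                     ascending_offset = 10, ascending_top = 20) {
  require_landmarks(landmarks, HTO_LANDMARK_NAMES)
  if (!is.finite(gap_target) || gap_target <= 1 || gap_target >= 20)
    stop("precondition error: gap_target must lie in (1, 20) mm", call. = FALSE)
  if (is.null(frame)) frame <- build_frame(landmarks)

  mmpp <- lm_get(landmarks, "MMPP")
  mlpp <- lm_get(landmarks, "MLPP")
  tmca <- lm_get(landmarks, "TMCA")
  tmcp <- lm_get(landmarks, "TMCP")
  ttv <- lm_get(landmarks, "TTV")
  W <- sqrt(sum((mmpp - mlpp)^2))

  ## medial entry: cortex point W/2 distal (frame z) to the medial plateau
  med_dir <- medial_sign(frame) * frame$x_axis
  mmpp_f <- to_frame(mmpp, frame)
  entry_origin <- from_frame(c(0, mmpp_f[2], mmpp_f[3] - W / 2), frame)
  t_entry <- ray_mesh_hits(entry_origin, med_dir, mesh)
  if (length(t_entry) == 0L)
    stop("planning error: medial entry ray misses the cortex", call. = FALSE)
  medial_entry <- entry_origin + max(t_entry) * med_dir

  ## lateral aim point: 15 mm distal to the lateral plateau
  aim <- mlpp - aim_offset * frame$z_axis

  ## main cut plane: contains the medial slope line, entry and aim
  v_slope <- unit3(tmcp - tmca)
  w <- unit3(aim - medial_entry)            # in-plane, medial -> lateral
  n_main <- unit3(cross3(v_slope, w))
  if (sum(n_main * frame$z_axis) < 0) n_main <- -n_main

  ## hinge: lateral cortex exit of the in-plane medial->lateral ray
  t_h <- ray_mesh_hits(medial_entry, w, mesh)
  if (length(t_h) == 0L)
    stop("planning error: hinge ray misses the lateral cortex", call. = FALSE)
  hinge_point <- medial_entry + max(t_h) * w
  cut_end <- hinge_point - lateral_bridge * w

  ## extreme points of the main-cut contour
  contours <- mesh_section(mesh, medial_entry, n_main)
  if (length(contours) == 0L)
    stop("planning error: main cut plane misses the mesh", call. = FALSE)
  cpts <- do.call(rbind, lapply(contours, function(ct) ct$points))
  med_coord <- as.numeric(cpts %*% med_dir)
  medial_point <- cpts[which.max(med_coord), ]
  y_coord <- as.numeric(sweep(cpts, 2, frame$origin) %*% frame$y_axis)
  anterior_point <- cpts[which.max(y_coord), ]

  plan <- structure(list(
    ascending_cut = list(point = ttv - ascending_offset * frame$y_axis,
                         normal = frame$y_axis,
                         z_top = frame_z(ttv, frame) + ascending_top),
    main_cut = list(point = medial_entry, normal = n_main),
    hinge_point = hinge_point,
    hinge_direction = frame$y_axis,
    medial_entry = medial_entry,
    medial_point = medial_point,
    anterior_point = anterior_point,
    cut_end = cut_end,
    cut_dir = w,
    gap_target = gap_target,
    lateral_bridge = lateral_bridge,
    aim_point = aim,
    opening_angle = NA_real_,
    frame = frame), class = "hto_plan")
  plan$opening_angle <- solve_opening_angle(plan, medial_point, gap_target)
  ## canonicalize the hinge direction so +opening_angle opens the gap
  plan$hinge_direction <- attr(plan$opening_angle, "axis_direction")
  plan$opening_angle <- as.numeric(plan$opening_angle)
  plan
}

#' @export
print.hto_plan <- function(x, ...) {
  cat(sprintf("hto_plan: gap %.1f mm -> opening angle %.3f deg, bridge %.0f mm\n",
              x$gap_target, x$opening_angle, x$lateral_bridge))
  cat(sprintf("  hinge (%.1f, %.1f, %.1f), medial entry (%.1f, %.1f, %.1f) mm\n",
              x$hinge_point[1], x$hinge_point[2], x$hinge_point[3],
              x$medial_entry[1], x$medial_entry[2], x$medial_entry[3]))
  invisible(x)
}

#' Solve the opening angle for a prescribed medial gap
#'
#' Finds the rotation angle about the hinge axis that displaces the most
#' medial cut-contour point by `gap_target` along the frame z-axis
#' (bisection to 1e-8 mm).
#'
#' @param plan an `hto_plan` (hinge and frame are used).
#' @param medial_point the most medial point of the main-cut contour.
#' @param gap_target desired z-gap in mm.
#' @return opening angle in degrees, in (0, 30); the attribute
#'   `axis_direction` carries the hinge direction oriented so a positive
#'   angle opens the gap.
#' @export
solve_opening_angle <- function(plan, medial_point, gap_target) {
  frame <- plan$frame
  r <- sqrt(sum(cross3(medial_point - plan$hinge_point,
                       unit3(plan$hinge_direction))^2))
  if (r < 1e-6)
    stop("geometry error: medial point lies on the hinge axis", call. = FALSE)
  dz_for <- function(dir, theta) {
    t <- rotation_about_axis(plan$hinge_point, dir, theta)
    frame_z(apply_transform(medial_point, t), frame) - frame_z(medial_point, frame)
  }
  ## choose the rotation sense that moves the medial point distally (opens
  ## the gap below the fixed proximal fragment)
  dir <- unit3(plan$hinge_direction)
  if (dz_for(dir, 1) > 0) dir <- -dir
  f <- function(theta) -dz_for(dir, theta) - gap_target
  if (f(30) < 0)
    stop("geometry error: no opening angle in (0, 30) deg reaches the gap (hinge too close to the medial point)",
         call. = FALSE)
  lo <- 0; hi <- 30
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  theta <- (lo + hi) / 2
  structure(theta, axis_direction = dir)
}

#' Execute a planned osteotomy on the mesh
#'
#' Splits the mesh into the proximal (plateau) fragment and the distal
#' fragment (shaft plus the tuberosity flange anterior of the ascending
#' cut) and rotates the distal fragment about the hinge axis by the solved
#' opening angle.
#'
#' @param mesh an `hto_mesh`.
#' @param landmarks the `hto_landmarks` of the specimen.
#' @param plan an `hto_plan` from [plan_hto()].
#' @return object of class `hto_osteotomy` with `proximal_fragment`,
#'   `distal_fragment` (already moved), `fragment_transform`,
#'   `realized_landmarks`, `plan`, `landmarks_source` and `gap_measured`.
#' @export
execute_hto <- function(mesh, landmarks, plan) {
  frame <- plan$frame
  mc <- plan$main_cut; ac <- plan$ascending_cut
  above <- clip_mesh_by_plane(mesh, mc$point, mc$normal)
  below <- clip_mesh_by_plane(mesh, mc$point, -mc$normal)
  if (is.null(above) || is.null(below))
    stop("topology error: main cut leaves the mesh in 1 component",
         call. = FALSE)
  posterior <- clip_mesh_by_plane(above, ac$point, -ac$normal)
  anterior <- clip_mesh_by_plane(above, ac$point, ac$normal)
  ztop_pt <- frame$origin + ac$z_top * frame$z_axis
  flange <- NULL; ant_up <- NULL
  if (!is.null(anterior)) {
    flange <- clip_mesh_by_plane(anterior, ztop_pt, -frame$z_axis)
    ant_up <- clip_mesh_by_plane(anterior, ztop_pt, frame$z_axis)
  }
  proximal <- if (is.null(posterior)) ant_up
              else if (is.null(ant_up)) posterior
              else concat_meshes(posterior, ant_up)
  distal <- if (is.null(flange)) below else concat_meshes(below, flange)
  if (is.null(proximal) || is.null(distal))
    stop("topology error: cuts do not separate the mesh into 2 fragments",
         call. = FALSE)

  t <- rotation_about_axis(plan$hinge_point, plan$hinge_direction,
                           plan$opening_angle)
  distal_moved <- apply_transform(distal, t)
  realized <- transform_landmarks(landmarks, plan, t)

  ## measure the realized gap from the fragment cut contours at the most
  ## medial point: corresponding boundary points sit at the same material
  ## location on either side of the cut
  d_prox <- sqrt(rowSums(sweep(proximal$vertices, 2, plan$medial_point)^2))
  p_prox <- proximal$vertices[which.min(d_prox), ]
  mp_moved <- apply_transform(plan$medial_point, t)
  d_dist <- sqrt(rowSums(sweep(distal_moved$vertices, 2, mp_moved)^2))
  p_dist <- distal_moved$vertices[which.min(d_dist), ]
  gap_measured <- abs(frame_z(p_prox, frame) - frame_z(p_dist, frame))

  structure(list(proximal_fragment = proximal, distal_fragment = distal_moved,
                 fragment_transform = t, realized_landmarks = realized,
                 plan = plan, landmarks_source = landmarks,
                 gap_measured = gap_measured),
            class = "hto_osteotomy")
}

#' @export
print.hto_osteotomy <- function(x, ...) {
  cat(sprintf("hto_osteotomy: opening %.3f deg, realized medial z-gap %.3f mm\n",
              x$plan$opening_angle, x$gap_measured))
  cat(sprintf("  proximal %d faces | distal %d faces\n",
              nrow(x$proximal_fragment$faces), nrow(x$distal_fragment$faces)))
  invisible(x)
}

## side classification shared by mesh split and landmark transport:
## distal iff below the main cut OR (anterior of the ascending cut AND
## below its upper bound) — the tuberosity flange travels with the shaft
classify_distal <- function(points, plan) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  frame <- plan$frame
  s_m <- as.numeric(sweep(points, 2, plan$main_cut$point) %*% plan$main_cut$normal)
  s_a <- as.numeric(sweep(points, 2, plan$ascending_cut$point) %*%
                      plan$ascending_cut$normal)
  zf <- frame_z(points, frame)
  list(distal = s_m < 0 | (s_a > 0 & zf < plan$ascending_cut$z_top),
       s_m = s_m, s_a = s_a)
}

#' Transport landmarks through an executed osteotomy
#'
#' Landmarks on the distal side of the cuts (shaft, malleolus, tuberosity
#' flange) are moved by the fragment transform; plateau landmarks stay.
#' Landmarks within 0.5 mm of a cut plane are assigned by sign with an
#' ambiguity warning.
#'
#' @param landmarks an `hto_landmarks`.
#' @param plan an `hto_plan`.
#' @param fragment_transform the distal-fragment `hto_transform`.
#' @return an `hto_landmarks` with attribute `moved` (names of transported
#'   landmarks).
#' @export
transform_landmarks <- function(landmarks, plan, fragment_transform) {
  pos <- landmarks$positions
  cls <- classify_distal(pos, plan)
  near <- abs(cls$s_m) < 0.5 | abs(cls$s_a) < 0.5
  if (any(near))
    warning("ambiguity warning: landmark(s) within 0.5 mm of a cut plane, assigned by sign: ",
            paste(rownames(pos)[near], collapse = ", "), call. = FALSE)
  moved <- rownames(pos)[cls$distal]
  pos[cls$distal, ] <- apply_transform(pos[cls$distal, , drop = FALSE],
                                       fragment_transform)
  out <- landmark_set(landmarks$side, pos)
  attr(out, "moved") <- moved
  out
}

## all positive ray parameters where origin + t*dir crosses the mesh
ray_mesh_hits <- function(origin, dir, mesh) {
  sort(.cpp_ray_mesh(as.numeric(origin), as.numeric(unit3(dir)),
                     mesh$vertices, mesh$faces))
}

## clip a mesh to the half-space {p : (p - point) . normal >= 0}; crossing
## triangles are re-triangulated with interpolated boundary vertices shared
## via canonical edge keys. Returns NULL when nothing remains.
clip_mesh_by_plane <- function(mesh, point, normal) {
  n <- unit3(normal)
  v <- mesh$vertices
  s <- as.numeric(sweep(v, 2, point) %*% n)
  f <- mesh$faces
  sf <- matrix(s[f] >= 0, ncol = 3)
  nin <- rowSums(sf)
  keep_faces <- f[nin == 3L, , drop = FALSE]
  crossing <- which(nin == 1L | nin == 2L)

  newv <- list(); newf <- list()
  ekeys <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  edge_idx <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- ekeys[[key]]
    if (is.null(id)) {
      t <- s[i] / (s[i] - s[j])
      newv[[length(newv) + 1L]] <<- v[i, ] + t * (v[j, ] - v[i, ])
      id <- nv0 + length(newv)
      ekeys[[key]] <- id
    }
    id
  }
  for (fi in crossing) {
    vs <- f[fi, ]
    inside <- s[vs] >= 0
    if (sum(inside) == 1L) {
      k <- which(inside)
      a <- vs[k]; b <- vs[k %% 3L + 1L]; cc <- vs[(k + 1L) %% 3L + 1L]
      i1 <- edge_idx(a, b); i2 <- edge_idx(a, cc)
      newf[[length(newf) + 1L]] <- c(a, i1, i2)
    } else {
      k <- which(!inside)
      a <- vs[k]; b <- vs[k %% 3L + 1L]; cc <- vs[(k + 1L) %% 3L + 1L]
      i1 <- edge_idx(a, b); i2 <- edge_idx(a, cc)
      ## quad b, c, i2, i1 keeps the original winding
      newf[[length(newf) + 1L]] <- c(b, cc, i2)
      newf[[length(newf) + 1L]] <- c(b, i2, i1)
    }
  }
  faces <- rbind(keep_faces,
                 if (length(newf)) do.call(rbind, newf))
  if (is.null(faces) || nrow(faces) == 0L) return(NULL)
  verts <- rbind(v, if (length(newv)) do.call(rbind, newv))
  ## drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  if (length(used) < 4L) return(NULL)
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  tri_mesh(verts[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3), merge_tol = 0)
}
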