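## Parametric proximal-tibia phantom with analytically known landmarks and
## ground-truth angles.
##
## The phantom is a stylized long bone, not an anthropomorphic model: a
## tapered elliptical shaft, a flared metaphysis, a two-facet plateau plane
## tilted to realize the target MPTA and medial/lateral slopes, a distal
## section twisted about the shaft axis to realize the target torsion, an
## anterior tuberosity bump (TTV), a medial malleolus bump (MMAL) and a
## fibular-notch indentation (IFT). Landmark coordinates are emitted from
## the same closed-form surface function that generates the mesh, so they
## lie on the surface exactly; the joint-line tilt and the distal twist are
## solved (1-D root finding) so that the *measured* MPTA and torsion equal
## the targets despite the small frame-tilt couplings.

#' Parameters of a synthetic tibia
#'
#' @param side `"LEFT"` or `"RIGHT"`.
#' @param total_length shaft length plateau-to-distal-tip in mm.
#' @param plateau_width MMPP-MLPP distance in mm.
#' @param plateau_depth anteroposterior plateau extent in mm.
#' @param shaft_radius nominal mid-shaft radius in mm (elliptical, with a
#'   linear distal taper).
#' @param target_mpta,target_medial_slope,target_lateral_slope,target_torsion
#'   ground-truth angles in degrees.
#' @param tuberosity_offset height of the anterior tuberosity bump (mm).
#' @param malleolus_offset height of the medial malleolus bump (mm).
#' @param mesh_resolution `c(circumferential, longitudinal)` segment counts;
#'   minimum 24 x 60; the circumferential count is rounded up to a multiple
#'   of 8 so the landmark feature angles fall on mesh vertices.
#' @param seed integer; the construction is deterministic, the seed is
#'   recorded for provenance.
#' @return object of class `hto_tibia_params`.
#' @export
synthetic_tibia_params <- function(side = "RIGHT",
                                   total_length = 360,
                                   plateau_width = 75,
                                   plateau_depth = 50,
                                   shaft_radius = 13,
                                   target_mpta = 87,
                                   target_medial_slope = 8,
                                   target_lateral_slope = 7,
                                   target_torsion = 35,
                                   tuberosity_offset = 12,
                                   malleolus_offset = 10,
                                   mesh_resolution = c(48, 120),
                                   seed = 1L) {
  side <- match.arg(toupper(side), c("LEFT", "RIGHT"))
  lens <- c(total_length, plateau_width, plateau_depth, shaft_radius,
            tuberosity_offset, malleolus_offset)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("parameter error: all lengths must be positive", call. = FALSE)
  if (abs(90 - target_mpta) > 40 || abs(target_medial_slope) >= 45 ||
      abs(target_lateral_slope) >= 45 || abs(target_torsion) >= 85)
    stop("parameter error: infeasible angle combination (plateau tilt or torsion too large)",
         call. = FALSE)
  mesh_resolution <- as.integer(round(mesh_resolution))
  if (length(mesh_resolution) != 2L || mesh_resolution[1] < 24L ||
      mesh_resolution[2] < 60L)
    stop("parameter error: mesh_resolution must be at least 24 x 60",
         call. = FALSE)
  mesh_resolution[1] <- 8L * ceiling(mesh_resolution[1] / 8)
  structure(list(side = side, total_length = total_length,
                 plateau_width = plateau_width, plateau_depth = plateau_depth,
                 shaft_radius = shaft_radius, target_mpta = target_mpta,
                 target_medial_slope = target_medial_slope,
                 target_lateral_slope = target_lateral_slope,
                 target_torsion = target_torsion,
                 tuberosity_offset = tuberosity_offset,
                 malleolus_offset = malleolus_offset,
                 mesh_resolution = mesh_resolution, seed = as.integer(seed)),
            class = "hto_tibia_params")
}

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

## wrap an angle difference to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

## internal geometry of the phantom in its canonical (RIGHT, frame-aligned)
## pose; all analytic, shared by mesh sampling and landmark placement.
## z_tub/z_mal/z_ift override the default feature levels.
phantom_geometry <- function(p, alpha_deg, psi_deg, z_tub = NULL,
                             z_mal = NULL, z_ift = NULL) {
  L <- p$total_length
  a0 <- p$plateau_width / 2
  b0 <- p$plateau_depth / 2
  a_s <- 1.15 * p$shaft_radius
  b_s <- 0.95 * p$shaft_radius
  meta_len <- 0.3 * L                  # metaphyseal flare length
  flare_z <- 0.85 * L
  xb <- 0.2 * a0                      # half-width of the medial/lateral slope blend

  half_axes <- function(z) {
    taper <- 1 - 0.15 * pmin(1, pmax(0, (-z - meta_len) / (flare_z - meta_len)))
    flare <- smoothstep((-z - flare_z) / (L - flare_z))
    ash <- a_s * taper * (1 + 0.35 * flare)
    bsh <- b_s * taper * (1 + 0.30 * flare)
    s <- smoothstep((z + meta_len) / meta_len)
    list(a = ash + (a0 - ash) * s, b = bsh + (b0 - bsh) * s)
  }

  sigma_at <- function(x) {
    s <- smoothstep((x + xb) / (2 * xb))
    p$target_medial_slope + (p$target_lateral_slope - p$target_medial_slope) * s
  }
  z_top <- function(x, y)
    tan(alpha_deg * pi / 180) * x + tan(sigma_at(x) * pi / 180) * y

  ## feature placement (local, pre-twist angles)
  theta_tub <- pi / 2
  theta_mal <- pi
  theta_ift <- -pi / 4
  if (is.null(z_tub)) z_tub <- -0.125 * L
  if (is.null(z_mal)) z_mal <- -0.955 * L
  if (is.null(z_ift)) z_ift <- z_mal + 4
  twist_at <- function(z)
    psi_deg * pi / 180 * smoothstep((-z - 0.5 * L) / (0.5 * L))

  bump_mult <- function(theta, z) {
    ha <- half_axes(z_tub)
    ht <- p$tuberosity_offset / ha$b
    hm_ha <- half_axes(z_mal)
    hm <- p$malleolus_offset / hm_ha$a
    1 +
      ht * exp(-(wrap_angle(theta - theta_tub) / (25 * pi / 180))^2 -
                 ((z - z_tub) / 12)^2) +
      hm * exp(-(wrap_angle(theta - theta_mal) / (30 * pi / 180))^2 -
                 ((z - z_mal) / 8)^2) -
      0.22 * exp(-(wrap_angle(theta - theta_ift) / (20 * pi / 180))^2 -
                   ((z - z_ift) / 8)^2)
  }

  surface_point <- function(theta, z) {
    ha <- half_axes(z)
    m <- bump_mult(theta, z)
    px <- ha$a * cos(theta) * m
    py <- ha$b * sin(theta) * m
    phi <- twist_at(z)
    c(cos(phi) * px - sin(phi) * py, sin(phi) * px + cos(phi) * py, z)
  }

  list(L = L, a0 = a0, b0 = b0, meta_len = meta_len, xb = xb,
       half_axes = half_axes, z_top = z_top, twist_at = twist_at,
       surface_point = surface_point,
       theta_tub = theta_tub, z_tub = z_tub,
       theta_mal = theta_mal, theta_ift = theta_ift,
       z_mal = z_mal, z_ift = z_ift)
}

## analytic landmark set of the canonical phantom (RIGHT pose)
phantom_landmarks <- function(p, geom) {
  a0 <- geom$a0; b0 <- geom$b0
  xm <- 0.5 * a0; yap <- 0.8 * b0
  xp <- 0.55 * a0; yp <- 0.8 * b0
  zt <- geom$z_top
  sp <- geom$surface_point
  pos <- rbind(
    TMCA = c(-xm, yap, zt(-xm, yap)),
    TMCP = c(-xm, -yap, zt(-xm, -yap)),
    TLCA = c(xm, yap, zt(xm, yap)),
    TLCP = c(xm, -yap, zt(xm, -yap)),
    MMPP = c(-a0, 0, zt(-a0, 0)),
    MLPP = c(a0, 0, zt(a0, 0)),
    TKC = c(0, 0, 0),
    PMC = c(-xp, -yp, zt(-xp, -yp)),
    PLC = c(xp, -yp, zt(xp, -yp)),
    TTV = sp(geom$theta_tub, geom$z_tub),
    IFT = sp(geom$theta_ift, geom$z_ift),
    MMAL = sp(geom$theta_mal, geom$z_mal))
  landmark_set("RIGHT", pos)
}

#' Generate a synthetic tibia
#'
#' Builds a watertight phantom mesh together with analytically placed
#' landmarks and the ground-truth angle set. Deterministic for fixed
#' parameters.
#'
#' @param params an `hto_tibia_params` (see [synthetic_tibia_params()]).
#' @return list of class `hto_specimen` with `mesh` (`hto_mesh`),
#'   `landmarks` (`hto_landmarks`), `angles` (`hto_angles`, ground truth)
#'   and `params`.
#' @export
generate_tibia <- function(params = synthetic_tibia_params()) {
  stopifnot(inherits(params, "hto_tibia_params"))
  p <- params
  n_c <- p$mesh_resolution[1]
  n_l <- p$mesh_resolution[2]
  L <- p$total_length

  ## ring layout first: bump centers are snapped onto mesh rings so the
  ## feature apices (and thus TTV/IFT/MMAL) are exact mesh vertices.
  ## The wall stops just below the lowest point of the tilted plateau ring
  ## (which replaces the top level) so wall quads never fold.
  theta <- seq(0, 2 * pi, length.out = n_c + 1)[-(n_c + 1)]
  a0 <- p$plateau_width / 2
  b0 <- p$plateau_depth / 2
  dip <- tan(abs(90 - p$target_mpta) * pi / 180) * a0 +
    tan(max(abs(p$target_medial_slope), abs(p$target_lateral_slope)) * pi / 180) * b0
  levels <- c(seq(-L, -(dip + 2), length.out = n_l - 1L), 0)
  z_tub <- levels[which.min(abs(levels - (-0.125 * L)))]
  z_mal <- levels[which.min(abs(levels - (-0.955 * L)))]

  ## --- solve the joint-line coronal tilt alpha so measured MPTA == target ---
  measured_mpta_for <- function(alpha) {
    geom <- phantom_geometry(p, alpha, 0, z_tub, z_mal)
    lms <- phantom_landmarks(p, geom)
    frame <- build_frame(lms)
    axis <- structure(list(point = c(0, 0, -L / 2), direction = c(0, 0, 1)),
                      class = "hto_axis")
    compute_mpta(lms, axis, frame)
  }
  alpha <- stats::uniroot(function(a) measured_mpta_for(a) - p$target_mpta,
                          interval = c(-40, 40), tol = 1e-10)$root
  frame0 <- build_frame(phantom_landmarks(
    p, phantom_geometry(p, alpha, 0, z_tub, z_mal)))

  ## --- solve the distal twist psi so measured torsion == target, and the
  ## IFT level so the distal reference line is parallel to the plateau
  ## (axial) plane: torsion then stays decoupled from coronal rotations ---
  measured_torsion_for <- function(psi, z_ift) {
    geom <- phantom_geometry(p, alpha, psi, z_tub, z_mal, z_ift)
    lms <- phantom_landmarks(p, geom)
    compute_torsion(lms, frame0)
  }
  ## fraction of the full twist that has accrued at the feature level
  scale_mal <- smoothstep((-z_mal - 0.5 * L) / (0.5 * L))
  z_ift <- z_mal + 4
  psi <- 0
  for (pass in 1:3) {
    t0 <- measured_torsion_for(0, z_ift)
    delta <- ((p$target_torsion - t0 + 90) %% 180) - 90
    psi0 <- delta / max(scale_mal, 0.5)
    psi <- stats::uniroot(function(ps) {
      d <- measured_torsion_for(ps, z_ift) - p$target_torsion
      ((d + 90) %% 180) - 90
    }, interval = c(psi0 - 15, psi0 + 15), extendInt = "yes", tol = 1e-10)$root
    flatness <- function(z) {
      geom <- phantom_geometry(p, alpha, psi, z_tub, z_mal, z)
      lms <- phantom_landmarks(p, geom)
      sum((lm_get(lms, "MMAL") - lm_get(lms, "IFT")) * frame0$z_axis)
    }
    z_ift <- stats::uniroot(flatness, interval = c(z_mal - 2, z_mal + 12),
                            extendInt = "yes", tol = 1e-10)$root
  }

  geom <- phantom_geometry(p, alpha, psi, z_tub, z_mal, z_ift)

  nv_wall <- n_c * n_l
  verts <- matrix(0, nrow = nv_wall, ncol = 3)
  for (k in seq_len(n_l)) {
    z <- levels[k]
    if (k == n_l) {
      ## plateau ring: ellipse boundary lifted onto the tilted plateau plane
      x <- geom$a0 * cos(theta); y <- geom$b0 * sin(theta)
      verts[(k - 1) * n_c + seq_len(n_c), ] <-
        cbind(x, y, geom$z_top(x, y))
    } else {
      for (j in seq_len(n_c))
        verts[(k - 1) * n_c + j, ] <- geom$surface_point(theta[j], z)
    }
  }

  faces <- vector("list", n_l - 1L)
  jn <- c(seq_len(n_c)[-1], 1L)
  for (k in seq_len(n_l - 1L)) {
    base <- (k - 1L) * n_c
    f <- cbind(base + seq_len(n_c), base + jn, base + n_c + jn,
               base + n_c + seq_len(n_c))
    faces[[k]] <- rbind(cbind(f[, 1], f[, 2], f[, 3]),
                        cbind(f[, 1], f[, 3], f[, 4]))
  }
  faces <- do.call(rbind, faces)

  ## --- caps (top follows the plateau surface; bottom is flat) ---
  n_q <- max(4L, round(n_c / 8))
  rho <- seq(1, 0, length.out = n_q + 1)[-1]        # interior ring scales + center
  add_cap <- function(boundary_idx, boundary_xy, zfun, reverse) {
    ring_prev <- boundary_idx
    vlist <- NULL
    flist <- NULL
    nv0 <- nrow(verts) + if (is.null(vlist)) 0 else nrow(vlist)
    for (q in seq_along(rho)) {
      if (rho[q] > 1e-9) {
        xy <- boundary_xy * rho[q]
        vnew <- cbind(xy, zfun(xy))
        idx <- nv0 + seq_len(n_c); nv0 <- nv0 + n_c
        vlist <- rbind(vlist, vnew)
        f <- cbind(ring_prev, ring_prev[jn], idx[jn], idx)
        flist <- rbind(flist,
                       cbind(f[, 1], f[, 2], f[, 3]),
                       cbind(f[, 1], f[, 3], f[, 4]))
        ring_prev <- idx
      } else {
        cen <- nv0 + 1L
        vlist <- rbind(vlist, c(0, 0, zfun(matrix(0, 1, 2))))
        flist <- rbind(flist, cbind(ring_prev, ring_prev[jn], cen))
      }
    }
    if (reverse) flist <- flist[, c(1, 3, 2)]
    list(verts = vlist, faces = flist)
  }
  top_idx <- (n_l - 1L) * n_c + seq_len(n_c)
  top_xy <- cbind(geom$a0 * cos(theta), geom$b0 * sin(theta))
  topcap <- add_cap(top_idx, top_xy,
                    function(xy) geom$z_top(xy[, 1], xy[, 2]), reverse = FALSE)
  verts <- rbind(verts, topcap$verts)
  faces <- rbind(faces, topcap$faces)
  bot_idx <- seq_len(n_c)
  bot_xy <- verts[bot_idx, 1:2, drop = FALSE]
  botcap <- add_cap(bot_idx, bot_xy, function(xy) rep(-L, nrow(xy)),
                    reverse = TRUE)
  verts <- rbind(verts, botcap$verts)
  faces <- rbind(faces, botcap$faces)

  mesh <- tri_mesh(verts, faces, merge_tol = 1e-9)
  if (mesh_signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]

  landmarks <- phantom_landmarks(p, geom)

  ## mirror for a LEFT tibia
  if (p$side == "LEFT") {
    mesh$vertices[, 1] <- -mesh$vertices[, 1]
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
    pos <- landmarks$positions
    pos[, 1] <- -pos[, 1]
    landmarks <- landmark_set("LEFT", pos)
  }

  angles <- tibial_angles(p$target_mpta, p$target_medial_slope,
                          p$target_lateral_slope, p$target_torsion)
  structure(list(mesh = mesh, landmarks = landmarks, angles = angles,
                 params = p, alpha = alpha, psi = psi),
            class = "hto_specimen")
}

#' @export
print.hto_specimen <- function(x, ...) {
  cat(sprintf("hto_specimen (%s): length %.0f mm, plateau %.0f x %.0f mm\n",
              x$params$side, x$params$total_length, x$params$plateau_width,
              x$params$plateau_depth))
  cat("  ground truth: "); print(x$angles)
  invisible(x)
}
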