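## Surgical-execution and observer error models for the synthetic cohort.

#' Surgical error model
#'
#' Three interpretable error modes observed in cadaver HTO series:
#' a multiplicative shortfall of the opening angle (general
#' under-correction), an axial tilt of the hinge axis (couples the coronal
#' correction into the sagittal slope), and an extra closure of the
#' anterior gap (ventral under-correction, wedges seated posteriorly only),
#' plus isotropic landmark placement noise for the post-op measurement.
#'
#' @param opening_angle_scale multiplicative factor on the opening angle,
#'   in (0, 2); 1 = as planned.
#' @param hinge_tilt_axial tilt of the hinge axis in the axial plane
#'   (degrees).
#' @param anterior_sag extra closure of the anterior cut gap (mm).
#' @param landmark_sigma isotropic landmark jitter SD (mm).
#' @param seed RNG seed for the landmark jitter.
#' @return object of class `hto_error_model`.
#' @export
error_model <- function(opening_angle_scale = 1, hinge_tilt_axial = 0,
                        anterior_sag = 0, landmark_sigma = 0, seed = NULL) {
  if (!is.finite(opening_angle_scale) || opening_angle_scale <= 0 ||
      opening_angle_scale >= 2)
    stop("validation error: opening_angle_scale must lie in (0, 2)",
         call. = FALSE)
  if (landmark_sigma < 0 || anterior_sag < 0)
    stop("validation error: sigma and anterior_sag must be non-negative",
         call. = FALSE)
  structure(list(opening_angle_scale = opening_angle_scale,
                 hinge_tilt_axial = hinge_tilt_axial,
                 anterior_sag = anterior_sag,
                 landmark_sigma = landmark_sigma, seed = seed),
            class = "hto_error_model")
}

#' Simulate an imperfect surgical execution of a planned osteotomy
#'
#' Re-executes the fragment motion with the opening angle scaled, the hinge
#' axis tilted in the axial plane, and an additional small rotation about
#' the in-plane medial-lateral axis that closes the anterior gap by
#' `anterior_sag` mm. Deterministic per seed.
#'
#' @param result an `hto_osteotomy` from [execute_hto()].
#' @param model an `hto_error_model`.
#' @return list with `mesh` (realized full tibia), `landmarks` (realized,
#'   jittered when `landmark_sigma > 0`) and `transform` (the erroneous
#'   distal-fragment motion).
#' @export
simulate_surgical_error <- function(result, model = error_model()) {
  stopifnot(inherits(result, "hto_osteotomy"),
            inherits(model, "hto_error_model"))
  plan <- result$plan
  frame <- plan$frame

  theta <- plan$opening_angle * model$opening_angle_scale
  dir <- unit3(plan$hinge_direction)
  if (model$hinge_tilt_axial != 0) {
    tilt <- rotation_about_axis(plan$hinge_point, frame$z_axis,
                                model$hinge_tilt_axial)
    dir <- as.numeric(tilt$rotation %*% dir)
  }
  t_err <- rotation_about_axis(plan$hinge_point, dir, theta)

  if (model$anterior_sag > 0) {
    ## rotation about the in-plane medial->lateral axis through the hinge
    ## that lowers the anterior cut point by anterior_sag (closing the
    ## ventral gap); solved by bisection like the opening angle
    ap <- plan$anterior_point
    dz_for <- function(phi) {
      tt <- rotation_about_axis(plan$hinge_point, plan$cut_dir, phi)
      frame_z(apply_transform(ap, tt), frame) - frame_z(ap, frame)
    }
    sgn <- if (dz_for(1) < 0) 1 else -1
    f <- function(phi) -dz_for(sgn * phi) - model$anterior_sag
    hi <- 20
    if (f(hi) > 0) {
      lo <- 0
      while (hi - lo > 1e-9) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      t_sag <- rotation_about_axis(plan$hinge_point, plan$cut_dir,
                                   sgn * (lo + hi) / 2)
      t_err <- transform_compose(t_err, t_sag)
    } else {
      warning("simulation warning: anterior_sag unreachable by a 20 deg tilt; skipped",
              call. = FALSE)
    }
  }

  ## self-intersection guard: the erroneous motion must not drive the
  ## distal cut face more than 2 mm above the proximal cut face
  probe <- rbind(plan$medial_point, plan$anterior_point)
  dz <- frame_z(apply_transform(probe, t_err), frame) - frame_z(probe, frame)
  if (any(dz > 2))
    warning("simulation warning: fragments self-intersect by more than 2 mm",
            call. = FALSE)

  distal0 <- apply_transform(result$distal_fragment,
                             transform_invert(result$fragment_transform))
  realized_mesh <- concat_meshes(result$proximal_fragment,
                                 apply_transform(distal0, t_err))
  realized_lm <- transform_landmarks(result$landmarks_source, plan, t_err)
  if (model$landmark_sigma > 0)
    realized_lm <- jitter_landmarks(realized_lm, model$landmark_sigma,
                                    seed = model$seed)
  list(mesh = realized_mesh, landmarks = realized_lm, transform = t_err)
}

#' Jitter landmarks with isotropic Gaussian noise
#'
#' Emulates inter-observer landmark placement variability: each landmark is
#' perturbed independently by a zero-mean isotropic Gaussian.
#'
#' @param landmarks an `hto_landmarks`.
#' @param sigma_mm noise SD in mm (>= 0).
#' @param seed RNG seed for reproducibility (NULL = current RNG state).
#' @return a jittered `hto_landmarks`.
#' @export
jitter_landmarks <- function(landmarks, sigma_mm, seed = NULL) {
  if (sigma_mm < 0)
    stop("validation error: sigma must be non-negative", call. = FALSE)
  if (sigma_mm == 0) return(landmarks)
  if (!is.null(seed)) set.seed(seed)
  pos <- landmarks$positions
  pos <- pos + matrix(stats::rnorm(length(pos), sd = sigma_mm), nrow(pos), 3)
  out <- landmarks
  out$positions <- pos
  out
}
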