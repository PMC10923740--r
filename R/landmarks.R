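## Named anatomical landmarks on the tibial surface.

## Controlled vocabulary required for the full angle analysis.
HTO_LANDMARK_NAMES <- c(
  "TMCA", "TMCP",   # medial plateau most proximal anterior / posterior
  "TLCA", "TLCP",   # lateral plateau most proximal anterior / posterior
  "MMPP", "MLPP",   # most medial / most lateral proximal points
  "TKC",            # tibial knee center
  "PMC", "PLC",     # most posterior medial / lateral plateau points (dorsal tangent)
  "TTV",            # most ventral point of the tibial tuberosity
  "IFT",            # deepest point of the incisura fibularis tibiae
  "MMAL"            # outermost point of the medial malleolus
)

#' Create a landmark set
#'
#' @param side `"LEFT"` or `"RIGHT"`.
#' @param positions named list of length-3 points, or an n x 3 matrix with
#'   row names; coordinates in mm.
#' @param warn_unknown warn about names outside the controlled vocabulary.
#' @return object of class `hto_landmarks` with elements `side`, `positions`
#'   (matrix with row names) and `unknown` (names outside the vocabulary).
#' @export
landmark_set <- function(side, positions, warn_unknown = TRUE) {
  side <- match.arg(toupper(side), c("LEFT", "RIGHT"))
  if (is.list(positions))
    positions <- do.call(rbind, lapply(positions, as.numeric))
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L || is.null(rownames(positions)))
    stop("validation error: positions must be named 3D points", call. = FALSE)
  if (anyDuplicated(rownames(positions)))
    stop("validation error: duplicate landmark names", call. = FALSE)
  unknown <- setdiff(rownames(positions), HTO_LANDMARK_NAMES)
  if (length(unknown) && warn_unknown)
    warning("unknown landmark name(s) preserved: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(side = side, positions = positions, unknown = unknown),
            class = "hto_landmarks")
}

#' @export
print.hto_landmarks <- function(x, ...) {
  cat(sprintf("hto_landmarks: %s tibia, %d landmarks (%s)\n", x$side,
              nrow(x$positions), paste(rownames(x$positions), collapse = " ")))
  invisible(x)
}

## fetch one landmark as a length-3 vector, with a contract error if absent
lm_get <- function(landmarks, name) {
  if (!name %in% rownames(landmarks$positions))
    stop(sprintf("named-landmark error: landmark '%s' is required but missing",
                 name), call. = FALSE)
  as.numeric(landmarks$positions[name, ])
}

require_landmarks <- function(landmarks, names) {
  missing <- setdiff(names, rownames(landmarks$positions))
  if (length(missing))
    stop("named-landmark error: missing landmark(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read landmarks from JSON
#'
#' Schema: `{"side": "LEFT", "landmarks": {"TMCA": [x,y,z], ...}}`,
#' coordinates in mm. Unknown names are preserved and flagged in a warning.
#'
#' @param path JSON file path.
#' @return an `hto_landmarks` object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("I/O error: no such file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("format error: malformed landmark JSON in '", path,
                         "': ", conditionMessage(e), call. = FALSE))
  if (is.null(obj$side) || is.null(obj$landmarks))
    stop("format error: landmark JSON needs 'side' and 'landmarks' fields",
         call. = FALSE)
  pos <- lapply(obj$landmarks, function(p) as.numeric(unlist(p)))
  if (any(lengths(pos) != 3L))
    stop("format error: each landmark must be a 3D point", call. = FALSE)
  landmark_set(obj$side, pos)
}

#' Write landmarks to JSON
#'
#' @param landmarks an `hto_landmarks` object.
#' @param path output file path.
#' @export
write_landmarks <- function(landmarks, path) {
  pos <- lapply(seq_len(nrow(landmarks$positions)),
                function(i) as.numeric(landmarks$positions[i, ]))
  names(pos) <- rownames(landmarks$positions)
  jsonlite::write_json(list(side = landmarks$side, landmarks = pos),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check landmark positions against a mesh bounding box
#'
#' Landmarks are expected on or near the bone surface; positions outside the
#' mesh bounding box inflated by `slack` mm indicate a unit or side mix-up.
#'
#' @param landmarks an `hto_landmarks`.
#' @param mesh an `hto_mesh`.
#' @param slack inflation of the bounding box in mm.
#' @return invisibly TRUE; errors otherwise.
#' @export
check_landmarks_on_mesh <- function(landmarks, mesh, slack = 5) {
  bb <- mesh_bbox(mesh)
  p <- landmarks$positions
  bad <- p[, 1] < bb[1, 1] - slack | p[, 1] > bb[2, 1] + slack |
         p[, 2] < bb[1, 2] - slack | p[, 2] > bb[2, 2] + slack |
         p[, 3] < bb[1, 3] - slack | p[, 3] > bb[2, 3] + slack
  if (any(bad))
    stop("validation error: landmark(s) outside mesh bounding box: ",
         paste(rownames(p)[bad], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
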