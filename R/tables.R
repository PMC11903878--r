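#' Tabular containers
#'
#' All pipeline tables are plain data frames with a class attribute and a
#' validator, so they print, subset and merge like ordinary data frames.
#'
#' Columns:
#' * `particle_table`: `particle_id`, `tomo_id`, `x_nm`, `y_nm`, `z_nm`,
#'   `qw`, `qx`, `qy`, `qz`, `pool` (one of `"lumenal"`, `"pericentriolar"`,
#'   `"unassigned"`).
#' * `localization_table`: `trace_id`, `structure_id`, `iteration`,
#'   `x_nm`, `y_nm`, `z_nm`, `efo_khz`.
#' * `ring_model`: `spoke` (1..14, unique), `x`, `y`, `z` (Angstrom), with
#'   attribute `model_id`.
#'
#' @name table-containers
#' @keywords internal
NULL

.POOL_LEVELS <- c("lumenal", "pericentriolar", "unassigned")

#' Build a particle table
#'
#' @param particle_id,tomo_id Identifier vectors (coerced to character).
#' @param position n x 3 matrix of positions (nm).
#' @param orientation n x 4 matrix of scalar-first unit quaternions.
#' @param pool Optional pool labels; defaults to `"unassigned"`.
#' @return A `particle_table` data frame.
#' @export
particle_table <- function(particle_id, tomo_id, position, orientation,
                           pool = "unassigned") {
  position <- as.matrix(position)
  orientation <- as.matrix(orientation)
  n <- length(particle_id)
  df <- data.frame(
    particle_id = as.character(particle_id),
    tomo_id = rep_len(as.character(tomo_id), n),
    x_nm = position[, 1], y_nm = position[, 2], z_nm = position[, 3],
    qw = orientation[, 1], qx = orientation[, 2],
    qy = orientation[, 3], qz = orientation[, 4],
    pool = rep_len(as.character(pool), n),
    stringsAsFactors = FALSE
  )
  validate_particle_table(df)
}

#' @rdname particle_table
#' @param x Data frame to validate.
#' @export
validate_particle_table <- function(x) {
  need <- c("particle_id", "tomo_id", "x_nm", "y_nm", "z_nm",
            "qw", "qx", "qy", "qz", "pool")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("particle table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(paste(x$tomo_id, x$particle_id))) {
    stop("particle_id must be unique within tomo_id")
  }
  qn <- sqrt(x$qw^2 + x$qx^2 + x$qy^2 + x$qz^2)
  if (nrow(x) && any(abs(qn - 1) > 1e-6)) {
    stop("particle table orientations must be unit quaternions")
  }
  if (!all(x$pool %in% .POOL_LEVELS)) {
    stop("pool labels must be one of: ", paste(.POOL_LEVELS, collapse = ", "))
  }
  class(x) <- unique(c("particle_table", class(x)))
  x
}

particle_positions <- function(x) {
  unname(as.matrix(x[, c("x_nm", "y_nm", "z_nm")]))
}

particle_quaternions <- function(x) {
  unname(as.matrix(x[, c("qw", "qx", "qy", "qz")]))
}

#' Build a localization table
#'
#' @param trace_id,structure_id Identifier vectors.
#' @param iteration Integer acquisition-iteration index (>= 0).
#' @param position n x 3 matrix (nm).
#' @param efo_khz Effective frequency at offset (kHz, >= 0).
#' @return A `localization_table` data frame.
#' @export
localization_table <- function(trace_id, structure_id, iteration, position,
                               efo_khz) {
  position <- as.matrix(position)
  df <- data.frame(
    trace_id = as.character(trace_id),
    structure_id = rep_len(as.character(structure_id), length(trace_id)),
    iteration = as.integer(iteration),
    x_nm = position[, 1], y_nm = position[, 2], z_nm = position[, 3],
    efo_khz = as.numeric(efo_khz),
    stringsAsFactors = FALSE
  )
  validate_localization_table(df)
}

#' @rdname localization_table
#' @param x Data frame to validate.
#' @export
validate_localization_table <- function(x) {
  need <- c("trace_id", "structure_id", "iteration",
            "x_nm", "y_nm", "z_nm", "efo_khz")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("localization table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$efo_khz < 0)) stop("efo_khz must be >= 0")
    if (any(x$iteration < 0)) stop("iteration must be >= 0")
  }
  class(x) <- unique(c("localization_table", class(x)))
  x
}

#' Build a ring model
#'
#' A set of labeled gamma-tubulin center coordinates (Angstrom) for one
#' gamma-TuRC conformational model; spokes are numbered 1..14 and each may
#' appear at most once. Models missing spokes (e.g. a 13-spoke closed
#' microtubule-capping reference without spoke 1) are flagged `partial`.
#'
#' @param spoke Integer spoke indices in 1..14.
#' @param centers n x 3 matrix of center coordinates (Angstrom).
#' @param model_id Identifier string.
#' @return A `ring_model` data frame (sorted by spoke) with attributes
#'   `model_id` and `partial`.
#' @export
ring_model <- function(spoke, centers, model_id = "ring") {
  centers <- as.matrix(centers)
  spoke <- as.integer(spoke)
  if (any(spoke < 1L | spoke > 14L)) stop("spoke indices must lie in 1..14")
  if (anyDuplicated(spoke)) stop("duplicate spoke index in ring model")
  o <- order(spoke)
  df <- data.frame(spoke = spoke[o],
                   x = centers[o, 1], y = centers[o, 2], z = centers[o, 3])
  attr(df, "model_id") <- model_id
  attr(df, "partial") <- length(spoke) < 14L
  class(df) <- unique(c("ring_model", class(df)))
  df
}

ring_centers_matrix <- function(ring) {
  unname(as.matrix(ring[, c("x", "y", "z")]))
}

#' Build an MTT segment table
#'
#' One row per refined microtubule-triplet (MTT) segment: the segment
#' center (nm), the refined orientation as a unit quaternion whose local +z
#' lies along the triplet axis and local +x points toward the centriole
#' axis, and the locally interpolated MTT axis direction used for
#' orientation-consistency rejection.
#'
#' @param segment_id,mtt_id Identifier vectors.
#' @param center n x 3 matrix (nm).
#' @param orientation n x 4 matrix of unit quaternions.
#' @param axis_direction n x 3 matrix of unit vectors.
#' @return An `mtt_segment_table` data frame.
#' @export
mtt_segment_table <- function(segment_id, mtt_id, center, orientation,
                              axis_direction) {
  center <- as.matrix(center); orientation <- as.matrix(orientation)
  axis_direction <- as.matrix(axis_direction)
  df <- data.frame(
    segment_id = as.character(segment_id),
    mtt_id = rep_len(as.character(mtt_id), length(segment_id)),
    x_nm = center[, 1], y_nm = center[, 2], z_nm = center[, 3],
    qw = orientation[, 1], qx = orientation[, 2],
    qy = orientation[, 3], qz = orientation[, 4],
    ax = axis_direction[, 1], ay = axis_direction[, 2],
    az = axis_direction[, 3],
    stringsAsFactors = FALSE
  )
  qn <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
  an <- sqrt(df$ax^2 + df$ay^2 + df$az^2)
  if (nrow(df) && (any(abs(qn - 1) > 1e-6) || any(abs(an - 1) > 1e-6))) {
    stop("segment orientations and axis directions must be unit length")
  }
  class(df) <- unique(c("mtt_segment_table", class(df)))
  df
}
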