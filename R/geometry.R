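#' Rigid transforms, polylines and axis fitting
#'
#' Shared geometric primitives: a rigid transform is a list with a
#' scalar-first unit `rotation` quaternion and a length-3 `translation`
#' (applied as `x -> R x + t`); a polyline is an ordered vertex matrix with
#' cumulative arc length; an axis is an anchor point plus unit direction.
#'
#' @name rigid-geometry
#' @keywords internal
NULL

#' Construct a rigid transform
#' @param rotation Unit quaternion `(w, x, y, z)`.
#' @param translation Numeric length-3 vector.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- quat_canonicalize(rotation)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf A `rigid_transform`.
#' @param points Length-3 vector or n x 3 matrix of row points.
#' @return Transformed points, same shape.
#' @export
apply_rigid <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.matrix(points)) {
    sweep(rotate_vector(tf$rotation, points), 2, tf$translation, "+")
  } else {
    rotate_vector(tf$rotation, as.numeric(points)) + tf$translation
  }
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  qi <- quat_canonicalize(quat_conjugate(tf$rotation))
  rigid_transform(qi, -rotate_vector(qi, tf$translation))
}

#' Compose rigid transforms (`a` after `b`: x -> a(b(x)))
#' @param a,b `rigid_transform` objects.
#' @return Composition as a `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(quat_multiply(a$rotation, b$rotation),
                  rotate_vector(a$rotation, b$translation) + a$translation)
}

#' Construct a polyline
#'
#' @param vertices n x 3 numeric matrix of ordered vertices (n >= 2),
#'   consecutive vertices distinct.
#' @return Object of class `polyline` with fields `vertices` and `arc`
#'   (cumulative arc length per vertex, starting at 0).
#' @export
polyline <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3L, nrow(vertices) >= 2L, all(is.finite(vertices)))
  seg <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                         vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(seg == 0)) stop("polyline: consecutive vertices must be distinct")
  structure(list(vertices = unname(vertices), arc = c(0, cumsum(seg))),
            class = "polyline")
}

#' Total arc length of a polyline
#' @param line A `polyline`.
#' @return Scalar length.
#' @export
polyline_length <- function(line) line$arc[length(line$arc)]

#' Closest point on a polyline
#'
#' Minimum point-to-segment distance over all segments, with the foot point
#' and its arc-length coordinate (clamped to `[0, total length]`).
#'
#' @param p Numeric length-3 point.
#' @param line A `polyline`.
#' @return List with `distance`, `foot` (length-3), `arc_coordinate`.
#' @export
point_to_polyline <- function(p, line) {
  stopifnot(inherits(line, "polyline"))
  p <- as.numeric(p)
  V <- line$vertices
  n <- nrow(V)
  A <- V[-n, , drop = FALSE]
  B <- V[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  AP <- sweep(-A, 2, p, "+")
  t <- pmin(pmax(rowSums(AP * AB) / len2, 0), 1)
  foot <- A + AB * t
  d2 <- rowSums((foot - matrix(p, nrow(foot), 3, byrow = TRUE))^2)
  i <- which.min(d2)
  arc <- line$arc[i] + t[i] * sqrt(len2[i])
  list(distance = sqrt(d2[i]),
       foot = foot[i, ],
       arc_coordinate = min(max(arc, 0), polyline_length(line)))
}

#' Minimum distances from points to a set of polylines
#'
#' For each row of `points`, the minimum [point_to_polyline()] distance over
#' all lines, with the index of the nearest line.
#'
#' @param points n x 3 matrix.
#' @param lines List of `polyline` objects.
#' @return Data frame with columns `distance`, `line_index`, `arc_coordinate`.
#' @export
points_to_polylines <- function(points, lines) {
  points <- as.matrix(points)
  out <- data.frame(distance = numeric(nrow(points)),
                    line_index = integer(nrow(points)),
                    arc_coordinate = numeric(nrow(points)))
  for (i in seq_len(nrow(points))) {
    best <- Inf; bi <- NA_integer_; ba <- NA_real_
    for (j in seq_along(lines)) {
      r <- point_to_polyline(points[i, ], lines[[j]])
      if (r$distance < best) { best <- r$distance; bi <- j; ba <- r$arc_coordinate }
    }
    out$distance[i] <- best
    out$line_index[i] <- bi
    out$arc_coordinate[i] <- ba
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1; reflections are corrected,
#' never returned) and translation minimizing the RMSD between
#' `moving[subset, ]` and `fixed[subset, ]`, then applies it to the full
#' moving set.
#'
#' @param moving,fixed n x 3 matrices of paired points.
#' @param subset Integer indices used to fit the superposition (default all
#'   rows); at least 3 non-collinear points.
#' @return List with `transform` (a `rigid_transform`), `rmsd` (over the
#'   subset only) and `transformed` (full moving set after the transform).
#' @export
kabsch_superpose <- function(moving, fixed, subset = seq_len(nrow(moving))) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3L, ncol(fixed) == 3L)
  subset <- as.integer(subset)
  stopifnot(all(subset >= 1L), all(subset <= nrow(moving)), length(subset) >= 3L)
  X <- moving[subset, , drop = FALSE]
  Y <- fixed[subset, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity: rank of the centered subset must exceed 1
  sv_x <- svd(Xc)$d
  if (sv_x[2] <= 1e-9 * max(sv_x[1], 1)) {
    stop("degenerate superposition: subset points are collinear")
  }
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  tf <- rigid_transform(matrix_to_quat(R), t)
  moved <- apply_rigid(tf, moving)
  rmsd <- sqrt(mean(rowSums((moved[subset, , drop = FALSE] - Y)^2)))
  list(transform = tf, rmsd = rmsd, transformed = moved)
}

#' Principal scatter directions of a point cloud
#' @param points n x 3 matrix.
#' @return `eigen()` result of the centered scatter (covariance) matrix,
#'   plus `centroid`.
#' @keywords internal
principal_directions <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  Xc <- sweep(points, 2, ctr)
  e <- eigen(crossprod(Xc) / nrow(points), symmetric = TRUE)
  e$centroid <- ctr
  e
}

# deterministic sign convention: positive z, tie -> positive y, then x
.orient_direction <- function(d, tol = 1e-12) {
  if (abs(d[3]) > tol) {
    if (d[3] < 0) d <- -d
  } else if (abs(d[2]) > tol) {
    if (d[2] < 0) d <- -d
  } else if (d[1] < 0) {
    d <- -d
  }
  d
}

#' Total-least-squares axis fit
#'
#' Fits the line through the centroid minimizing the sum of squared
#' perpendicular (radial) distances to the points -- the dominant scatter
#' direction. The direction sign is fixed toward positive z (ties broken
#' toward positive y, then x).
#'
#' @param points n x 3 matrix, n >= 3, not all identical.
#' @return Object of class `axis3d`: list with `point` (centroid) and unit
#'   `direction`.
#' @export
fit_axis_tls <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 3L, all(is.finite(points)))
  e <- principal_directions(points)
  if (e$values[1] <= 0) stop("ambiguous axis: degenerate point cloud")
  if ((e$values[1] - e$values[2]) <= 1e-6 * e$values[1]) {
    stop("ambiguous axis: top two scatter eigenvalues are equal")
  }
  structure(list(point = e$centroid,
                 direction = .orient_direction(e$vectors[, 1])),
            class = "axis3d")
}

#' Radial and axial coordinates about an axis
#'
#' @param points n x 3 matrix.
#' @param axis An `axis3d`.
#' @return Data frame with `r` (perpendicular distance to the axis line,
#'   >= 0) and `s` (signed projection onto the direction, measured from the
#'   axis anchor point).
#' @export
axis_coordinates <- function(points, axis) {
  stopifnot(inherits(axis, "axis3d"))
  points <- as.matrix(points)
  rel <- sweep(points, 2, axis$point)
  s <- as.numeric(rel %*% axis$direction)
  perp <- rel - outer(s, axis$direction)
  data.frame(r = sqrt(rowSums(perp^2)), s = s)
}
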