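#' Ring-geometry deviation analysis
#'
#' Quantifies how far a gamma-TuRC conformational model deviates from a
#' closed microtubule-capping reference: models are superposed on a spoke
#' subset (default spokes 2-8; 3-8 available by argument) by least-squares
#' rigid superposition, and the per-spoke deviation is the Euclidean
#' distance between corresponding gamma-tubulin centers afterwards. Units
#' are Angstrom throughout.
#'
#' @name conformation
#' @keywords internal
NULL

#' Align a ring model to the z-axis
#'
#' Fits the ring-normal direction over the selected spokes -- the minor
#' scatter direction of centers lying near a plane (or short helix) --
#' rotates the model so the normal maps to +z and the selected centroid to
#' the origin, and fixes handedness so spoke indices increase
#' counter-clockwise viewed from +z.
#'
#' @param ring A `ring_model`.
#' @param reference_spokes Spokes used for the fit (default all present).
#' @return The aligned `ring_model`.
#' @export
align_ring_to_z <- function(ring, reference_spokes = ring$spoke) {
  sel <- ring$spoke %in% reference_spokes
  if (sum(sel) < 3L) stop("need at least 3 reference spokes")
  P <- ring_centers_matrix(ring)[sel, , drop = FALSE]
  e <- principal_directions(P)
  # ring normal = minor scatter direction; ambiguous if the two smallest
  # eigenvalues tie (e.g. collinear centers)
  if ((e$values[2] - e$values[3]) <= 1e-6 * max(e$values[1], 1e-12)) {
    stop("degenerate ring geometry: normal direction is ambiguous")
  }
  normal <- e$vectors[, 3]
  R <- t(.frame_from_z(normal))  # world -> ring frame with normal on +z
  ctr <- e$centroid
  apply_ring <- function(Rm) {
    Q <- sweep(ring_centers_matrix(ring), 2, ctr) %*% t(Rm)
    ring_model(ring$spoke, Q, model_id = attr(ring, "model_id"))
  }
  out <- apply_ring(R)
  # handedness: spoke azimuths must increase counter-clockwise from +z
  Psel <- ring_centers_matrix(out)[sel, , drop = FALSE]
  az <- atan2(Psel[, 2], Psel[, 1])
  daz <- diff(az)
  daz <- (daz + pi) %% (2 * pi) - pi
  if (sum(daz) < 0) {
    flip <- diag(c(1, -1, -1))  # 180 degrees about x: negates the normal
    out <- apply_ring(flip %*% R)
  }
  out
}

#' Per-spoke deviation profile between two ring models
#'
#' Superposes `query` onto `reference` over the spoke `subset` (Kabsch,
#' proper rotation only) and reports, for every spoke present in both
#' models, the Euclidean distance between the transformed query center and
#' the reference center.
#'
#' @param query,reference `ring_model` objects.
#' @param subset Spokes used for the superposition (default 2:8).
#' @return Object of class `deviation_profile`: data frame with `spoke`
#'   and `deviation_A`, plus attributes `subset` and `rmsd_A`.
#' @export
ring_deviation_profile <- function(query, reference, subset = 2:8) {
  miss_q <- setdiff(subset, query$spoke)
  miss_r <- setdiff(subset, reference$spoke)
  if (length(miss_q) || length(miss_r)) {
    stop("missing superposition spoke(s): ",
         paste(unique(c(miss_q, miss_r)), collapse = ", "))
  }
  common <- intersect(query$spoke, reference$spoke)
  qi <- match(common, query$spoke)
  ri <- match(common, reference$spoke)
  Pq <- ring_centers_matrix(query)[qi, , drop = FALSE]
  Pr <- ring_centers_matrix(reference)[ri, , drop = FALSE]
  sub_idx <- match(subset, common)
  fit <- kabsch_superpose(Pq, Pr, subset = sub_idx)
  dev <- sqrt(rowSums((fit$transformed - Pr)^2))
  out <- data.frame(spoke = common, deviation_A = dev)
  attr(out, "subset") <- subset
  attr(out, "rmsd_A") <- fit$rmsd
  class(out) <- unique(c("deviation_profile", class(out)))
  out
}

#' Synthetic helical ring-model geometry
#'
#' An idealized 14-spoke gamma-TuRC ring: spokes on a left-truncated helix
#' with 13 positions per turn, configurable radius and rise. Used as a
#' stand-in reference when no experimentally derived center table is
#' supplied.
#'
#' @param spokes Spoke indices to emit (default 1:14).
#' @param radius_A Ring radius (Angstrom).
#' @param rise_A Axial rise per full turn (Angstrom).
#' @param model_id Identifier.
#' @return A `ring_model`.
#' @export
synthetic_ring_model <- function(spokes = 1:14, radius_A = 100,
                                 rise_A = 110, model_id = "synthetic_ring") {
  az <- (spokes - 1) * 2 * pi / 13
  z <- (spokes - 1) * rise_A / 13
  ring_model(spokes,
             cbind(radius_A * cos(az), radius_A * sin(az), z),
             model_id = model_id)
}
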