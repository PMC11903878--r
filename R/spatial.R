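#' Distance-pool statistics
#'
#' Pool classification, signed distances to MTT B-tubule centerlines,
#' nearest-neighbor statistics, radial/axial profiles, and median-unbiased
#' (Hyndman-Fan type 8) percentile summaries.
#'
#' @name spatial-stats
#' @keywords internal
NULL

#' Median-unbiased (type 8) percentile
#'
#' Order-statistic interpolation at the plotting position
#' `h = p * (n + 1/3) + 1/3`, approximately median-unbiased regardless of
#' the underlying distribution; `h` is clamped to `[1, n]` so `p = 0`
#' returns the minimum and `p = 1` the maximum.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param p Probability (scalar or vector) in `[0, 1]`.
#' @return Percentile estimate(s), same length as `p`.
#' @export
percentile_median_unbiased <- function(values, p) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input: no values")
  if (!all(is.finite(values))) stop("values must be finite")
  if (any(p < 0 | p > 1)) stop("domain error: p must lie in [0, 1]")
  x <- sort(values)
  n <- length(x)
  vapply(p, function(pp) {
    h <- pp * (n + 1 / 3) + 1 / 3
    h <- min(max(h, 1), n)
    fl <- floor(h)
    lo <- x[fl]
    hi <- x[min(fl + 1, n)]
    lo + (h - fl) * (hi - lo)
  }, numeric(1))
}

#' Summarize a distance distribution
#'
#' Median and 90% / 95% central intervals, all by the median-unbiased
#' type-8 estimator.
#'
#' @param values Non-empty numeric vector.
#' @return Object of class `distance_summary`: list with `n`, `median`,
#'   `interval_90` (5th and 95th percentiles) and `interval_95` (2.5th and
#'   97.5th).
#' @export
summarize_distribution <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input: no values to summarize")
  structure(list(
    n = length(values),
    median = percentile_median_unbiased(values, 0.5),
    interval_90 = percentile_median_unbiased(values, c(0.05, 0.95)),
    interval_95 = percentile_median_unbiased(values, c(0.025, 0.975))
  ), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("n = %d, median = %.2f, 90%% between %.2f and %.2f\n",
              x$n, x$median, x$interval_90[1], x$interval_90[2]))
  invisible(x)
}

#' Classify particles into lumenal and pericentriolar pools
#'
#' Deterministic geometric replacement for a visual pool split: a particle
#' is lumenal iff its radial coordinate about the centriole axis is below
#' `wall_radius - margin` *and* its axial coordinate lies within the
#' centriole length extent (+/- margin); otherwise pericentriolar.
#'
#' @param particles A `particle_table`.
#' @param model A `centriole_model`.
#' @param margin_nm Safety margin (nm) shrinking the lumen radially and
#'   widening the axial extent.
#' @return The table with `pool` filled in.
#' @export
classify_pools <- function(particles, model, margin_nm = 10) {
  co <- axis_coordinates(particle_positions(particles), model$axis)
  half <- model$length_nm / 2
  lum <- co$r < (model$wall_radius_nm - margin_nm) &
    abs(co$s) <= (half + margin_nm)
  particles$pool <- ifelse(lum, "lumenal", "pericentriolar")
  validate_particle_table(particles)
}

#' Signed distances to the nearest MTT B-tubule centerline
#'
#' For each particle, the minimum center-to-center [point_to_polyline()]
#' distance over the nine B-tubule lines, signed negative for the lumenal
#' pool and positive for the pericentriolar pool.
#'
#' @param particles A labeled `particle_table` (run [classify_pools()]
#'   first).
#' @param model A `centriole_model`.
#' @return Data frame with `particle_id`, `pool`, `distance_nm` (signed),
#'   `mtt_index`; attribute `summary`: list of `distance_summary` objects
#'   for `all` (absolute values), `lumenal` and `pericentriolar`.
#' @export
signed_mtt_distances <- function(particles, model) {
  if (any(particles$pool == "unassigned")) {
    stop("particles carry unassigned pool labels; run classify_pools() first")
  }
  near <- points_to_polylines(particle_positions(particles), model$mtt_lines)
  signed <- ifelse(particles$pool == "lumenal", -near$distance, near$distance)
  out <- data.frame(particle_id = particles$particle_id,
                    pool = particles$pool,
                    distance_nm = signed,
                    mtt_index = near$line_index,
                    stringsAsFactors = FALSE)
  smry <- list(all = summarize_distribution(abs(signed)))
  for (pl in c("lumenal", "pericentriolar")) {
    v <- abs(signed[particles$pool == pl])
    if (length(v)) smry[[pl]] <- summarize_distribution(v)
  }
  attr(out, "summary") <- smry
  out
}

#' Nearest-neighbor center-to-center distances
#'
#' One value per particle: the Euclidean distance to its closest other
#' particle in the same group. Groups are per tomogram, and additionally
#' per pool when `within_pool` is TRUE. Singleton groups are excluded with
#' a warning.
#'
#' @param particles A `particle_table`.
#' @param within_pool Restrict neighbor search to the particle's own pool.
#' @return Data frame with `particle_id`, `pool`, `tomo_id`, `nn_nm`;
#'   attribute `summary`: `distance_summary` of the pooled values.
#' @export
nearest_neighbor_distances <- function(particles, within_pool = TRUE) {
  key <- if (within_pool) {
    paste(particles$tomo_id, particles$pool)
  } else particles$tomo_id
  res <- vector("list", 0L)
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) < 2L) {
      warning("singleton group '", g, "' excluded from nearest-neighbor stats")
      next
    }
    P <- particle_positions(particles)[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    res[[length(res) + 1L]] <- data.frame(
      particle_id = particles$particle_id[idx],
      pool = particles$pool[idx],
      tomo_id = particles$tomo_id[idx],
      nn_nm = apply(D, 1, min),
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(particle_id = character(0), pool = character(0),
               tomo_id = character(0), nn_nm = numeric(0))
  }
  rownames(out) <- NULL
  if (nrow(out)) attr(out, "summary") <- summarize_distribution(out$nn_nm)
  out
}

#' Radial and axial profile of points about an axis
#'
#' Radial distance `r` to the axis line and signed axial coordinate `s`
#' from the axis anchor, with an `r` histogram over the given bin edges.
#'
#' @param points n x 3 matrix.
#' @param axis An `axis3d`.
#' @param breaks Radial histogram bin edges (nm); points beyond the last
#'   edge fall into the last bin.
#' @return Object of class `radial_axial_profile`: list with `coords`
#'   (data frame `r`, `s`), `breaks`, `counts`.
#' @export
radial_axial_profile <- function(points, axis, breaks = seq(0, 200, by = 5)) {
  co <- axis_coordinates(points, axis)
  r_clip <- pmin(co$r, max(breaks) - 1e-12)
  counts <- as.integer(table(cut(r_clip, breaks, include.lowest = TRUE,
                                 right = FALSE)))
  structure(list(coords = co, breaks = breaks, counts = counts),
            class = "radial_axial_profile")
}
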