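#' gamma-TuRC-MTT pair-configuration analysis
#'
#' Reduces each gamma-TuRC and its nearest accepted MTT segment to a
#' 7-dimensional feature -- the center-of-mass shift expressed in the
#' gamma-TuRC local frame (3 coordinates, rigid-motion invariant) plus the
#' canonicalized relative orientation quaternion (4 coordinates) -- then
#' filters by center-of-mass distance, clusters by seeded k-means, and
#' summarizes the main (largest) cluster.
#'
#' The gamma-TuRC local frame convention: +z along the ring's helical axis
#' from the base toward the gamma-tubulin face, +x toward the azimuth of
#' spoke 1; spoke k sits at azimuth `(k - 1) * 360 / 13` degrees from +x
#' (13 spoke positions per helical turn).
#'
#' @name pair-config
#' @keywords internal
NULL

#' Build one pair feature
#'
#' @param p_turc,q_turc gamma-TuRC center (nm) and unit quaternion.
#' @param p_seg,q_seg MTT segment center (nm) and unit quaternion.
#' @param shift_scale_nm Divisor applied to the local shift in the feature
#'   vector so positional and quaternion coordinates have comparable
#'   ranges (default 60, half the upper distance cutoff).
#' @return One-row data frame with `com_distance_nm`, `shift_x/y/z_nm`
#'   (local frame, unscaled), `qrel_w/x/y/z`, and feature columns `f1..f7`.
#' @export
build_pair_feature <- function(p_turc, q_turc, p_seg, q_seg,
                               shift_scale_nm = 60) {
  w <- as.numeric(p_seg) - as.numeric(p_turc)
  shift_local <- rotate_vector(quat_canonicalize(quat_conjugate(q_turc)), w)
  q_rel <- relative_orientation(q_turc, q_seg)
  data.frame(com_distance_nm = sqrt(sum(w^2)),
             shift_x_nm = shift_local[1], shift_y_nm = shift_local[2],
             shift_z_nm = shift_local[3],
             qrel_w = q_rel[1], qrel_x = q_rel[2],
             qrel_y = q_rel[3], qrel_z = q_rel[4],
             f1 = shift_local[1] / shift_scale_nm,
             f2 = shift_local[2] / shift_scale_nm,
             f3 = shift_local[3] / shift_scale_nm,
             f4 = q_rel[1], f5 = q_rel[2], f6 = q_rel[3], f7 = q_rel[4])
}

#' Pair gamma-TuRCs with their closest accepted MTT segment
#'
#' Segments whose refined local +z deviates from the locally interpolated
#' MTT axis direction by more than `axis_tolerance_deg` are rejected before
#' pairing; each gamma-TuRC is then paired with the closest accepted
#' segment by center-to-center distance. An explicit `pairing` (data frame
#' with `particle_id`, `segment_id`) overrides the nearest-segment search.
#'
#' @param turcs A `particle_table`.
#' @param segments An `mtt_segment_table`.
#' @param axis_tolerance_deg Orientation-consistency rejection threshold.
#' @param shift_scale_nm Passed to [build_pair_feature()].
#' @param pairing Optional explicit pairing data frame.
#' @return A `pair_table` data frame (one row per retained gamma-TuRC) with
#'   identifiers, pool label, and the feature columns; attribute `counts`
#'   records segments rejected and gamma-TuRCs dropped.
#' @export
pair_particles_to_mtts <- function(turcs, segments, axis_tolerance_deg = 30,
                                   shift_scale_nm = 60, pairing = NULL) {
  if (nrow(segments) == 0L) stop("empty segment list")
  Qs <- as.matrix(segments[, c("qw", "qx", "qy", "qz")])
  zloc <- rotate_vector_rows(Qs, c(0, 0, 1))
  A <- as.matrix(segments[, c("ax", "ay", "az")])
  dev_deg <- acos(pmin(pmax(rowSums(zloc * A), -1), 1)) * 180 / pi
  keep <- dev_deg <= axis_tolerance_deg
  n_rejected <- sum(!keep)
  seg_keep <- segments[keep, , drop = FALSE]
  if (nrow(seg_keep) == 0L) stop("all MTT segments rejected by axis tolerance")
  P <- particle_positions(turcs)
  S <- as.matrix(seg_keep[, c("x_nm", "y_nm", "z_nm")])
  rows <- vector("list", nrow(turcs))
  dropped <- 0L
  for (i in seq_len(nrow(turcs))) {
    if (is.null(pairing)) {
      d2 <- rowSums(sweep(S, 2, P[i, ])^2)
      j <- which.min(d2)
    } else {
      sid <- pairing$segment_id[pairing$particle_id == turcs$particle_id[i]]
      j <- match(sid[1], seg_keep$segment_id)
      if (is.na(j)) { dropped <- dropped + 1L; next }
    }
    feat <- build_pair_feature(
      P[i, ], as.numeric(turcs[i, c("qw", "qx", "qy", "qz")]),
      S[j, ], as.numeric(seg_keep[j, c("qw", "qx", "qy", "qz")]),
      shift_scale_nm = shift_scale_nm)
    rows[[i]] <- cbind(
      data.frame(particle_id = turcs$particle_id[i],
                 tomo_id = turcs$tomo_id[i],
                 pool = turcs$pool[i],
                 segment_id = seg_keep$segment_id[j],
                 stringsAsFactors = FALSE),
      feat)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- list(segments_rejected = n_rejected,
                              turcs_dropped = dropped,
                              pairs = nrow(out))
  class(out) <- unique(c("pair_table", class(out)))
  out
}

#' Filter pairs by center-of-mass distance
#'
#' Retains pairs with `d_min <= com_distance <= d_max` (both bounds
#' inclusive); defaults are the 60-120 nm window.
#'
#' @param pairs A `pair_table`.
#' @param d_min,d_max Distance cutoffs (nm).
#' @return Filtered `pair_table`; attribute `counts` updated with rows
#'   before/after.
#' @export
filter_pairs_by_distance <- function(pairs, d_min = 60, d_max = 120) {
  if (d_min > d_max) stop("config error: d_min must be <= d_max")
  keep <- pairs$com_distance_nm >= d_min & pairs$com_distance_nm <= d_max
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- list(before = nrow(pairs), after = nrow(out))
  class(out) <- unique(c("pair_table", class(out)))
  out
}

# seeded k-means++ over a deterministically ordered copy of the data, so
# cluster assignments do not depend on input row order
.kmeanspp_init <- function(X, k, seed) {
  set.seed(seed)
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i1 <- sample.int(n, 1)
  centers[1, ] <- X[i1, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ij <- sample.int(n, 1, prob = pr)
    centers[j + 1L, ] <- X[ij, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1L, ])^2))
  }
  centers
}

#' Cluster pair configurations in 7D
#'
#' Lloyd's k-means with seeded k-means++ initialization and multiple
#' restarts (best within-cluster sum of squares retained). Initialization
#' runs over a lexicographically sorted copy of the feature matrix and
#' final assignments are by nearest centroid, so results are invariant to
#' input row order. The main cluster is the largest; its mean shift is the
#' arithmetic mean of member local shifts (nm, unscaled) and its mean
#' relative orientation the antipode-aware [quat_mean()].
#'
#' With a diffuse (orientation-random) background at fraction b, the main
#' cluster collects essentially all preferred-configuration pairs plus
#' about one k-th of the background, so the fraction estimate carries an
#' upward bias of roughly `b / k`. The default `k = 10` keeps that bias
#' below 0.06 for background fractions up to ~0.6; smaller k merges
#' background into the main cluster and overstates its share.
#'
#' @param pairs A `pair_table` (feature columns `f1..f7`).
#' @param k Number of clusters (default 10).
#' @param seed Integer seed for the initialization stream.
#' @param restarts Number of k-means++ restarts (default 20).
#' @return Object of class `pair_clusters`: list with `k`, `assignments`,
#'   `sizes`, `main_cluster`, `main_fraction_all`, `main_fraction_lumenal`,
#'   `mean_shift_nm`, `mean_q_rel`, `angular_spread_deg`, `tot_withinss`,
#'   `centers`.
#' @export
cluster_pair_configurations <- function(pairs, k = 10, seed = 1,
                                        restarts = 20) {
  X <- as.matrix(pairs[, paste0("f", 1:7)])
  n <- nrow(X)
  if (n < k) stop("fewer pairs than clusters (n < k)")
  ord <- do.call(order, as.data.frame(X))
  Xs <- X[ord, , drop = FALSE]
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- .kmeanspp_init(Xs, k, seed + r - 1L)
    km <- suppressWarnings(
      stats::kmeans(Xs, centers = init, iter.max = 200, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  # assign original rows by nearest final centroid
  C <- best$centers
  D <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
    outer(rep(1, n), rowSums(C^2))
  assign <- max.col(-D, ties.method = "first")
  sizes <- tabulate(assign, nbins = k)
  main <- which.max(sizes)
  members <- which(assign == main)
  shift <- as.matrix(pairs[members, c("shift_x_nm", "shift_y_nm", "shift_z_nm")])
  Qm <- as.matrix(pairs[members, c("qrel_w", "qrel_x", "qrel_y", "qrel_z")])
  mq <- quat_mean(Qm)
  spread <- mean(apply(Qm, 1, function(q) quat_angle(q, mq)))
  lum <- pairs$pool == "lumenal"
  structure(list(
    k = k,
    assignments = assign,
    sizes = sizes,
    main_cluster = main,
    main_fraction_all = sizes[main] / n,
    main_fraction_lumenal = if (any(lum)) {
      sum(lum[members]) / sum(lum)
    } else NA_real_,
    mean_shift_nm = colMeans(shift),
    mean_q_rel = mq,
    angular_spread_deg = spread,
    tot_withinss = best$tot.withinss,
    centers = C
  ), class = "pair_clusters")
}

#' @export
print.pair_clusters <- function(x, ...) {
  cat(sprintf("k-means pair clustering: k = %d, n = %d\n", x$k,
              sum(x$sizes)))
  cat(sprintf("main cluster %d: %d pairs (%.1f%% of all", x$main_cluster,
              x$sizes[x$main_cluster], 100 * x$main_fraction_all))
  if (!is.na(x$main_fraction_lumenal)) {
    cat(sprintf(", %.1f%% of lumenal", 100 * x$main_fraction_lumenal))
  }
  cat(")\n")
  invisible(x)
}

#' Wall-facing angle of a spoke sector
#'
#' Angle between the in-plane unit vector at the sector's mean azimuth in
#' the gamma-TuRC local frame (spoke k at azimuth `(k - 1) * 360 /
#' spokes_per_turn` from local +x) and the projection of the local shift
#' vector onto the local xy-plane. Zero means the sector faces the MTT.
#'
#' @param pairs A `pair_table` (or any data frame with `shift_*_nm`
#'   columns).
#' @param sector Integer spoke indices (subset of 1..14), default 9:12.
#' @param spokes_per_turn Spoke positions per helical turn (13).
#' @return Numeric vector of angles in degrees, one per pair.
#' @export
wall_facing_angle <- function(pairs, sector = 9:12, spokes_per_turn = 13) {
  stopifnot(all(sector >= 1), all(sector <= 14))
  az <- (sector - 1) * 2 * pi / spokes_per_turn
  u <- c(mean(cos(az)), mean(sin(az)))
  u <- u / sqrt(sum(u^2))
  sx <- pairs$shift_x_nm; sy <- pairs$shift_y_nm
  nrm <- sqrt(sx^2 + sy^2)
  if (any(nrm < 1e-12)) stop("undefined angle: zero in-plane shift")
  acos(pmin(pmax((sx * u[1] + sy * u[2]) / nrm, -1), 1)) * 180 / pi
}
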