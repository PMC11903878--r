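#' Synthetic centrosome and MINFLUX data with planted, recoverable geometry
#'
#' These generators emulate the study conditions of the analyses in this
#' package: a nine-fold microtubule-triplet (MTT) centriole wall, a
#' condensed centriole-lumenal gamma-TuRC cluster with a planted preferred
#' pose relative to the nearest MTT plus an orientation-random background,
#' a broad pericentriolar pool, and MINFLUX traces on a cylindrical shell
#' with anisotropic Gaussian localization error and an EFO mixture. Every
#' planted parameter is recoverable by the corresponding analysis stage,
#' which is how the pipeline is validated offline.
#'
#' @name synthetic-data
#' @keywords internal
NULL

#' Default simulation configuration
#'
#' Returns the nested configuration list consumed by the `simulate_*`
#' generators. Defaults echo the spatial scales of centrosomal gamma-TuRC
#' organization: wall radius 115 nm, centriole length 450 nm, lumenal
#' nearest-B-tubule distance 75 +/- 6 nm with ~17 nm minimum packing
#' separation, pericentriolar distances truncated-Gaussian 85 +/- 26 nm
#' (minimum 30 nm), a lumenal background (orientation-random) fraction of
#' 0.37, and MINFLUX cylinders of radius 35 nm sampled by 17 structures x
#' 200 traces with sigma_xy 6 nm and sigma_z 5 nm applied before the 0.7
#' axial rescaling.
#'
#' @param seed Integer seed; every generator call is deterministic given
#'   the config and this seed.
#' @return Nested named list of parameter blocks (`centriole`, `lumenal`,
#'   `pericentriolar`, `minflux`, `pairs`).
#' @export
sim_config <- function(seed = 1) {
  sector_azimuth <- mean((9:12 - 1)) * 360 / 13  # spokes 9-12 mean azimuth
  list(
    seed = as.integer(seed),
    n_tomograms = 15L,
    centriole = list(
      wall_radius_nm = 115, length_nm = 450, n_mtt = 9L,
      twist_deg = 0, vertex_spacing_nm = 10,
      axis_point = c(0, 0, 0), axis_direction = c(0, 0, 1)
    ),
    lumenal = list(
      n = 300L, b_tubule_distance_nm = 75, distance_sd_nm = 6,
      planted_orientation = quat_from_axis_angle(c(0, 0, 1),
                                                 sector_azimuth - 180),
      orientation_noise_deg = 10, background_fraction = 0.37,
      min_separation_nm = 17
    ),
    pericentriolar = list(
      n = 500L, mean_nm = 85, sd_nm = 26, min_nm = 30,
      azimuth_jitter_deg = 15
    ),
    minflux = list(
      n_structures = 17L, cylinder_radius_nm = 35, cylinder_length_nm = 450,
      traces_per_structure = 200L, locs_per_trace_mean = 10,
      short_trace_fraction = 0.05, sigma_xy_nm = 6, sigma_z_nm = 5,
      efo_high_fraction = 0.1, decoy_fraction = 0.1,
      valid_iteration = 9L, z_scale = 0.7
    ),
    pairs = list(
      n = 232L, planted_fraction = 0.42, planted_distance_nm = 75,
      shift_sd_nm = 3, orientation_noise_deg = 10,
      d_min = 60, d_max = 120
    )
  )
}

#' Simulate a centriole model
#'
#' Builds nine B-tubule centerline polylines at the wall radius, spaced
#' exactly 40 degrees in azimuth (plus an optional helical twist over the
#' centriole length), posed at the configured axis.
#'
#' @param config Configuration from [sim_config()].
#' @return Object of class `centriole_model`: list with `axis` (`axis3d`),
#'   `length_nm`, `wall_radius_nm`, `mtt_lines` (list of 9 `polyline`s) and
#'   `mtt_azimuth_deg`.
#' @export
simulate_centriole <- function(config = sim_config()) {
  cc <- config$centriole
  if (cc$wall_radius_nm <= 0) stop("config error: wall_radius_nm must be > 0")
  dir <- cc$axis_direction / sqrt(sum(cc$axis_direction^2))
  pose <- .frame_from_z(dir)
  n_v <- max(2L, ceiling(cc$length_nm / cc$vertex_spacing_nm) + 1L)
  h <- seq(-cc$length_nm / 2, cc$length_nm / 2, length.out = n_v)
  az0 <- (seq_len(cc$n_mtt) - 1) * 360 / cc$n_mtt
  lines <- vector("list", cc$n_mtt)
  for (j in seq_len(cc$n_mtt)) {
    tw <- cc$twist_deg * (h + cc$length_nm / 2) / cc$length_nm
    a <- (az0[j] + tw) * pi / 180
    local <- cbind(cc$wall_radius_nm * cos(a), cc$wall_radius_nm * sin(a), h)
    world <- sweep(local %*% t(pose), 2, cc$axis_point, "+")
    lines[[j]] <- polyline(world)
  }
  structure(list(
    axis = structure(list(point = cc$axis_point, direction = dir),
                     class = "axis3d"),
    length_nm = cc$length_nm,
    wall_radius_nm = cc$wall_radius_nm,
    mtt_lines = lines,
    mtt_azimuth_deg = az0
  ), class = "centriole_model")
}

# rotation matrix with third column along unit z_new (deterministic)
.frame_from_z <- function(z_new) {
  ref <- if (abs(z_new[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x_new <- ref - sum(ref * z_new) * z_new
  x_new <- x_new / sqrt(sum(x_new^2))
  y_new <- c(z_new[2] * x_new[3] - z_new[3] * x_new[2],
             z_new[3] * x_new[1] - z_new[1] * x_new[3],
             z_new[1] * x_new[2] - z_new[2] * x_new[1])
  cbind(x_new, y_new, z_new)
}

#' MTT segments along a centriole wall
#'
#' Samples oriented segments along each B-tubule centerline. The segment
#' frame convention (shared with the pair analysis) is: local +z along the
#' B-tubule direction, local +x pointing radially inward toward the
#' centriole axis.
#'
#' @param model A `centriole_model`.
#' @param spacing_nm Arc-length spacing between consecutive segments.
#' @return An `mtt_segment_table`.
#' @export
centriole_mtt_segments <- function(model, spacing_nm = 8) {
  rows <- list()
  for (j in seq_along(model$mtt_lines)) {
    line <- model$mtt_lines[[j]]
    total <- polyline_length(line)
    arcs <- seq(0, total, by = spacing_nm)
    for (k in seq_along(arcs)) {
      pt <- .polyline_point_at(line, arcs[k])
      zdir <- .polyline_tangent_at(line, arcs[k])
      # inward radial: toward the axis, orthogonalized against the tangent
      ax <- model$axis
      rel <- pt - ax$point
      radial_out <- rel - sum(rel * ax$direction) * ax$direction
      inward <- -radial_out / sqrt(sum(radial_out^2))
      inward <- inward - sum(inward * zdir) * zdir
      inward <- inward / sqrt(sum(inward^2))
      ydir <- c(zdir[2] * inward[3] - zdir[3] * inward[2],
                zdir[3] * inward[1] - zdir[1] * inward[3],
                zdir[1] * inward[2] - zdir[2] * inward[1])
      rows[[length(rows) + 1L]] <- list(
        segment_id = sprintf("mtt%02d_s%04d", j, k),
        mtt_id = sprintf("mtt%02d", j),
        center = pt,
        q = matrix_to_quat(cbind(inward, ydir, zdir)),
        axdir = zdir)
    }
  }
  mtt_segment_table(
    segment_id = vapply(rows, `[[`, "", "segment_id"),
    mtt_id = vapply(rows, `[[`, "", "mtt_id"),
    center = do.call(rbind, lapply(rows, `[[`, "center")),
    orientation = do.call(rbind, lapply(rows, `[[`, "q")),
    axis_direction = do.call(rbind, lapply(rows, `[[`, "axdir")))
}

.polyline_point_at <- function(line, arc) {
  arc <- min(max(arc, 0), polyline_length(line))
  i <- findInterval(arc, line$arc, rightmost.closed = TRUE)
  i <- min(i, nrow(line$vertices) - 1L)
  seg_len <- line$arc[i + 1L] - line$arc[i]
  t <- (arc - line$arc[i]) / seg_len
  line$vertices[i, ] + t * (line$vertices[i + 1L, ] - line$vertices[i, ])
}

.polyline_tangent_at <- function(line, arc) {
  arc <- min(max(arc, 0), polyline_length(line))
  i <- findInterval(arc, line$arc, rightmost.closed = TRUE)
  i <- min(i, nrow(line$vertices) - 1L)
  d <- line$vertices[i + 1L, ] - line$vertices[i, ]
  d / sqrt(sum(d^2))
}

#' Simulate the centriole-lumenal gamma-TuRC pool
#'
#' Places `n` particles inside the wall at nearest-B-tubule center-to-center
#' distances Gaussian around the planted value, concentrated axially in the
#' central third of the centriole, with a minimum-separation rejection rule
#' emulating the dense lumenal packing. A fraction `1 - background_fraction`
#' of particles carries the planted orientation relative to its nearest MTT
#' segment frame (perturbed by up to `orientation_noise_deg`); the remainder
#' is uniform on SO(3).
#'
#' @param model A `centriole_model`.
#' @param config Configuration from [sim_config()]; the total count `n` is
#'   distributed over `config$n_tomograms` tomograms (the per-centriole
#'   structure of the data), and the minimum-separation rule applies within
#'   each tomogram.
#' @return A `particle_table` (pool left `"unassigned"`; labels are the
#'   classifier's job) with attribute `truth`: data frame of the generating
#'   MTT index, planted distance, and background flag per particle.
#' @export
simulate_lumenal_turcs <- function(model, config = sim_config()) {
  lc <- config$lumenal
  cc <- config$centriole
  if (lc$b_tubule_distance_nm >= cc$wall_radius_nm) {
    stop("config error: planted B-tubule distance must be < wall radius")
  }
  set.seed(config$seed)
  segments <- centriole_mtt_segments(model)
  seg_pos <- as.matrix(segments[, c("x_nm", "y_nm", "z_nm")])
  seg_arc <- axis_coordinates(seg_pos, model$axis)$s
  third <- cc$length_nm / 6  # central third: |s| < length/6
  cand <- which(abs(seg_arc) < third)
  n_tomo <- max(1L, as.integer(config$n_tomograms))
  per_tomo <- diff(round(seq(0, lc$n, length.out = n_tomo + 1L)))
  pos <- matrix(NA_real_, lc$n, 3)
  ori <- matrix(NA_real_, lc$n, 4)
  tomo <- character(lc$n)
  truth <- data.frame(mtt = integer(lc$n), distance_nm = numeric(lc$n),
                      background = logical(lc$n), segment_id = character(lc$n),
                      stringsAsFactors = FALSE)
  is_bg <- stats::runif(lc$n) < lc$background_fraction
  placed <- 0L
  for (t_i in seq_len(n_tomo)) {
    first_in_tomo <- placed + 1L
    goal <- placed + per_tomo[t_i]
    tries <- 0L
    while (placed < goal) {
      tries <- tries + 1L
      if (tries > 500L * per_tomo[t_i]) {
        stop("config error: cannot satisfy min_separation at this density")
      }
      i_seg <- sample(cand, 1L)
      d <- stats::rnorm(1, lc$b_tubule_distance_nm, lc$distance_sd_nm)
      if (d <= 0 || d >= cc$wall_radius_nm) next
      q_seg <- as.numeric(segments[i_seg, c("qw", "qx", "qy", "qz")])
      inward <- rotate_vector(q_seg, c(1, 0, 0))
      p <- as.numeric(seg_pos[i_seg, ]) + d * inward
      if (placed >= first_in_tomo) {
        prev <- first_in_tomo:placed
        dd <- sqrt(rowSums((pos[prev, , drop = FALSE] -
                              matrix(p, length(prev), 3, byrow = TRUE))^2))
        if (min(dd) < lc$min_separation_nm) next
      }
      placed <- placed + 1L
      pos[placed, ] <- p
      tomo[placed] <- sprintf("tomo_%02d", t_i)
      if (is_bg[placed]) {
        ori[placed, ] <- random_quaternions(1)[1, ]
      } else {
        q <- quat_multiply(q_seg, quat_conjugate(lc$planted_orientation))
        ori[placed, ] <- quat_perturb(quat_canonicalize(q),
                                      lc$orientation_noise_deg)
      }
      truth$mtt[placed] <- as.integer(sub("mtt(\\d+).*", "\\1",
                                          segments$segment_id[i_seg]))
      truth$distance_nm[placed] <- d
      truth$background[placed] <- is_bg[placed]
      truth$segment_id[placed] <- segments$segment_id[i_seg]
    }
  }
  tab <- particle_table(sprintf("lum_%04d", seq_len(lc$n)), tomo, pos, ori)
  attr(tab, "truth") <- truth
  tab
}

# truncated-normal draw / quantile (lower truncation only)
rtruncnorm_min <- function(n, mean, sd, min) {
  u <- stats::runif(n, stats::pnorm(min, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Quantile of a lower-truncated Gaussian
#' @param p Probability in `[0, 1]`.
#' @param mean,sd,min Law parameters.
#' @return Quantile value.
#' @export
truncnorm_quantile <- function(p, mean, sd, min) {
  a <- stats::pnorm(min, mean, sd)
  stats::qnorm(a + p * (1 - a), mean, sd)
}

#' Simulate the pericentriolar gamma-TuRC pool
#'
#' Places `n` particles outside the wall with nearest-B-tubule distances
#' drawn from a lower-truncated Gaussian and orientations uniform on SO(3).
#' Each particle is offset perpendicular to a randomly chosen B-tubule
#' line, outward, with a small azimuthal jitter about the outward radial.
#'
#' @inheritParams simulate_lumenal_turcs
#' @return A `particle_table` with attribute `truth` (generating MTT index
#'   and planted distance).
#' @export
simulate_pericentriolar_turcs <- function(model, config = sim_config()) {
  pc <- config$pericentriolar
  cc <- config$centriole
  if (pc$mean_nm <= 0) stop("config error: pericentriolar mean must be > 0")
  set.seed(config$seed + 1L)
  segments <- centriole_mtt_segments(model)
  seg_pos <- as.matrix(segments[, c("x_nm", "y_nm", "z_nm")])
  n <- pc$n
  n_tomo <- max(1L, as.integer(config$n_tomograms))
  per_tomo <- diff(round(seq(0, n, length.out = n_tomo + 1L)))
  tomo <- rep(sprintf("tomo_%02d", seq_len(n_tomo)), per_tomo)
  d <- rtruncnorm_min(n, pc$mean_nm, pc$sd_nm, pc$min_nm)
  i_seg <- sample(nrow(segments), n, replace = TRUE)
  jit <- stats::runif(n, -pc$azimuth_jitter_deg, pc$azimuth_jitter_deg)
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    q_seg <- as.numeric(segments[i_seg[i], c("qw", "qx", "qy", "qz")])
    outward <- -rotate_vector(q_seg, c(1, 0, 0))
    zdir <- as.numeric(segments[i_seg[i], c("ax", "ay", "az")])
    out_j <- rotate_vector(quat_from_axis_angle(zdir, jit[i]), outward)
    pos[i, ] <- as.numeric(seg_pos[i_seg[i], ]) + d[i] * out_j
  }
  ori <- random_quaternions(n)
  tab <- particle_table(sprintf("pcm_%04d", seq_len(n)), tomo, pos, ori)
  attr(tab, "truth") <- data.frame(
    mtt = as.integer(sub("mtt(\\d+).*", "\\1", segments$segment_id[i_seg])),
    distance_nm = d)
  tab
}

#' Simulate MINFLUX localizations on cylindrical structures
#'
#' For each structure, emitters are placed uniformly on a cylinder shell of
#' the configured radius and length at a random rigid pose. Each emitter
#' yields one trace whose localization count is `min_locs + Poisson` (a
#' configured fraction of traces is truncated below `min_locs` instead).
#' Localization noise is Gaussian with `sigma_xy_nm` on the world x/y axes
#' and `sigma_z_nm` on world z, applied to the true position *before* the
#' axial distortion: stored z equals `(z_true + noise) / z_scale`, so the
#' pipeline's `z_scale` (0.7) correction recovers the true geometry. EFO
#' values are a mixture with a configured fraction above 100 kHz, and a
#' fraction `decoy_fraction` of extra rows per trace carries iteration
#' indices below `valid_iteration` with inflated noise.
#'
#' @param config Configuration from [sim_config()].
#' @return A `localization_table` with attribute `truth`: data frame with
#'   per-structure cylinder center, axis direction and radius.
#' @export
simulate_minflux <- function(config = sim_config()) {
  mc <- config$minflux
  set.seed(config$seed + 2L)
  out <- vector("list", mc$n_structures)
  truth <- data.frame(structure_id = character(mc$n_structures),
                      cx = 0, cy = 0, cz = 0, dx = 0, dy = 0, dz = 0,
                      radius_nm = mc$cylinder_radius_nm,
                      stringsAsFactors = FALSE)
  for (s in seq_len(mc$n_structures)) {
    sid <- sprintf("S%02d", s)
    q_pose <- random_quaternions(1)[1, ]
    center <- stats::runif(3, -2500, 2500)
    ntr <- mc$traces_per_structure
    theta <- stats::runif(ntr, 0, 2 * pi)
    hh <- stats::runif(ntr, -mc$cylinder_length_nm / 2,
                       mc$cylinder_length_nm / 2)
    emit_local <- cbind(mc$cylinder_radius_nm * cos(theta),
                        mc$cylinder_radius_nm * sin(theta), hh)
    emit_world <- sweep(rotate_vector(q_pose, emit_local), 2, center, "+")
    short <- stats::runif(ntr) < mc$short_trace_fraction
    nloc <- ifelse(short,
                   sample(1:3, ntr, replace = TRUE),
                   4L + stats::rpois(ntr, max(mc$locs_per_trace_mean - 4, 0)))
    rows <- list()
    for (tr in seq_len(ntr)) {
      k <- nloc[tr]
      noise <- cbind(stats::rnorm(k, 0, mc$sigma_xy_nm),
                     stats::rnorm(k, 0, mc$sigma_xy_nm),
                     stats::rnorm(k, 0, mc$sigma_z_nm))
      xyz <- matrix(emit_world[tr, ], k, 3, byrow = TRUE) + noise
      xyz[, 3] <- xyz[, 3] / mc$z_scale  # stored pre-correction
      efo_hi <- stats::runif(k) < mc$efo_high_fraction
      efo <- ifelse(efo_hi, stats::runif(k, 100, 200), stats::runif(k, 20, 95))
      it <- rep(mc$valid_iteration, k)
      # decoy rows from earlier acquisition iterations, noisier
      n_dec <- stats::rbinom(1, k, mc$decoy_fraction)
      if (n_dec > 0) {
        dn <- cbind(stats::rnorm(n_dec, 0, 5 * mc$sigma_xy_nm),
                    stats::rnorm(n_dec, 0, 5 * mc$sigma_xy_nm),
                    stats::rnorm(n_dec, 0, 5 * mc$sigma_z_nm))
        dxyz <- matrix(emit_world[tr, ], n_dec, 3, byrow = TRUE) + dn
        dxyz[, 3] <- dxyz[, 3] / mc$z_scale
        xyz <- rbind(xyz, dxyz)
        efo <- c(efo, stats::runif(n_dec, 20, 95))
        it <- c(it, sample(0:(mc$valid_iteration - 1L), n_dec, replace = TRUE))
      }
      rows[[tr]] <- data.frame(
        trace_id = sprintf("%s_T%04d", sid, tr), structure_id = sid,
        iteration = it, x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3],
        efo_khz = efo, stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, rows)
    dir_w <- rotate_vector(q_pose, c(0, 0, 1))
    truth[s, ] <- list(sid, center[1], center[2], center[3],
                       dir_w[1], dir_w[2], dir_w[3], mc$cylinder_radius_nm)
  }
  tab <- validate_localization_table(do.call(rbind, out))
  rownames(tab) <- NULL
  attr(tab, "truth") <- truth
  tab
}

#' Simulate a gamma-TuRC-MTT pair-configuration set
#'
#' Constructs `n` particle pairs of which a planted fraction shares one
#' preferred relative configuration (planted shift in the gamma-TuRC local
#' frame pointing along the spoke 9-12 sector azimuth, planted relative
#' orientation, both lightly perturbed) while the remainder is background:
#' orientation uniform on SO(3) and shift uniform in the admissible
#' 60-120 nm distance shell. Segment world poses are random, so feature
#' invariance under rigid motion is exercised by construction.
#'
#' @param config Configuration from [sim_config()].
#' @return List with `turcs` (`particle_table`), `segments`
#'   (`mtt_segment_table`), `pairing` (data frame mapping each gamma-TuRC to
#'   its segment), and `truth` (logical vector, TRUE for planted pairs).
#' @export
simulate_pair_set <- function(config = sim_config()) {
  pc <- config$pairs
  lc <- config$lumenal
  set.seed(config$seed + 3L)
  n <- pc$n
  planted <- rep(FALSE, n)
  planted[sample(n, round(n * pc$planted_fraction))] <- TRUE
  q_planted <- lc$planted_orientation
  shift_planted <- -pc$planted_distance_nm *
    rotate_vector(q_planted, c(1, 0, 0))
  q_seg <- random_quaternions(n)
  p_seg <- matrix(stats::runif(3 * n, -1000, 1000), ncol = 3)
  q_turc <- matrix(NA_real_, n, 4)
  p_turc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (planted[i]) {
      q_rel <- quat_perturb(q_planted, pc$orientation_noise_deg)
      shift <- shift_planted + stats::rnorm(3, 0, pc$shift_sd_nm)
    } else {
      q_rel <- random_quaternions(1)[1, ]
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # uniform over the admissible shell volume: density proportional to r^2
      r3 <- stats::runif(1, pc$d_min^3, pc$d_max^3)
      shift <- r3^(1 / 3) * u
    }
    q_turc[i, ] <- quat_canonicalize(
      quat_multiply(q_seg[i, ], quat_conjugate(q_rel)))
    p_turc[i, ] <- p_seg[i, ] - rotate_vector(q_turc[i, ], shift)
  }
  # pool labels: all planted pairs are lumenal and make up ~63% of the
  # lumenal pool; the remaining lumenal slots are background pairs
  lumenal <- planted
  extra <- round(sum(planted) / 0.63) - sum(planted)
  if (extra > 0) lumenal[sample(which(!planted), min(extra, sum(!planted)))] <- TRUE
  turcs <- particle_table(sprintf("pair_%04d", seq_len(n)), "tomo_pairs",
                          p_turc, q_turc,
                          pool = ifelse(lumenal, "lumenal", "pericentriolar"))
  segments <- mtt_segment_table(
    segment_id = sprintf("seg_%04d", seq_len(n)),
    mtt_id = sprintf("seg_%04d", seq_len(n)),
    center = p_seg, orientation = q_seg,
    axis_direction = rotate_vector_rows(q_seg, c(0, 0, 1)))
  list(turcs = turcs, segments = segments,
       pairing = data.frame(particle_id = turcs$particle_id,
                            segment_id = segments$segment_id,
                            stringsAsFactors = FALSE),
       truth = planted)
}

# rotate one local vector by each row-quaternion
rotate_vector_rows <- function(Q, v) {
  t(apply(Q, 1, function(q) rotate_vector(q, v)))
}
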