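small_cfg <- function(seed = 5) {
  cfg <- sim_config(seed)
  cfg$n_tomograms <- 3L
  cfg$lumenal$n <- 60L
  cfg$pericentriolar$n <- 90L
  cfg$minflux$n_structures <- 3L
  cfg$minflux$traces_per_structure <- 60L
  cfg
}

test_that("simulated centriole has nine-fold wall geometry", {
  model <- simulate_centriole()
  expect_length(model$mtt_lines, 9L)
  # azimuthal spacing exactly 40 degrees
  expect_equal(diff(model$mtt_azimuth_deg), rep(40, 8))
  # every polyline has the configured arc length
  lens <- vapply(model$mtt_lines, polyline_length, numeric(1))
  expect_equal(lens, rep(450, 9), tolerance = 1e-6)
  # all vertices at wall radius from the axis
  for (l in model$mtt_lines) {
    expect_equal(axis_coordinates(l$vertices, model$axis)$r,
                 rep(115, nrow(l$vertices)), tolerance = 1e-6)
  }
  expect_error({
    cfg <- sim_config(); cfg$centriole$wall_radius_nm <- -1
    simulate_centriole(cfg)
  }, "config error")
})

test_that("tilted centrioles keep wall distance to the axis", {
  cfg <- sim_config()
  cfg$centriole$axis_direction <- c(sin(pi / 6), 0, cos(pi / 6))
  cfg$centriole$axis_point <- c(100, -50, 20)
  model <- simulate_centriole(cfg)
  for (l in model$mtt_lines[c(1, 5, 9)]) {
    expect_equal(axis_coordinates(l$vertices, model$axis)$r,
                 rep(115, nrow(l$vertices)), tolerance = 1e-6)
  }
})

test_that("MTT segment frames have inward x and tangent z", {
  model <- simulate_centriole()
  seg <- centriole_mtt_segments(model, spacing_nm = 50)
  for (i in c(1L, nrow(seg) %/% 2L, nrow(seg))) {
    q <- as.numeric(seg[i, c("qw", "qx", "qy", "qz")])
    zdir <- rotate_vector(q, c(0, 0, 1))
    expect_equal(zdir, as.numeric(seg[i, c("ax", "ay", "az")]),
                 tolerance = 1e-9)
    xdir <- rotate_vector(q, c(1, 0, 0))
    ctr <- as.numeric(seg[i, c("x_nm", "y_nm", "z_nm")])
    # inward: moving along local +x reduces the radial coordinate
    r0 <- axis_coordinates(rbind(ctr), model$axis)$r
    r1 <- axis_coordinates(rbind(ctr + 10 * xdir), model$axis)$r
    expect_lt(r1, r0)
  }
})

test_that("lumenal generator plants distances and orientations", {
  model <- simulate_centriole()
  # noiseless, background-free: exact planted relative orientation
  cfg0 <- small_cfg(9)
  cfg0$lumenal$background_fraction <- 0
  cfg0$lumenal$orientation_noise_deg <- 0
  lum0 <- simulate_lumenal_turcs(model, cfg0)
  truth <- attr(lum0, "truth")
  seg <- centriole_mtt_segments(model)
  for (i in c(1L, 20L, nrow(lum0))) {
    j <- match(truth$segment_id[i], seg$segment_id)
    q_rel <- relative_orientation(
      as.numeric(lum0[i, c("qw", "qx", "qy", "qz")]),
      as.numeric(seg[j, c("qw", "qx", "qy", "qz")]))
    expect_equal(q_rel, cfg0$lumenal$planted_orientation, tolerance = 1e-9)
  }
  # planted distance law recovered at n = 300
  cfg <- sim_config(5)
  lum <- simulate_lumenal_turcs(model, cfg)
  d <- points_to_polylines(as.matrix(lum[, c("x_nm", "y_nm", "z_nm")]),
                           model$mtt_lines)$distance
  expect_lt(abs(mean(d) - 75), 1)
  # bit-reproducible given config + seed
  lum2 <- simulate_lumenal_turcs(model, cfg)
  expect_identical(as.data.frame(lum), as.data.frame(lum2))
  # min separation holds within each tomogram
  for (tm in unique(lum$tomo_id)) {
    P <- as.matrix(lum[lum$tomo_id == tm, c("x_nm", "y_nm", "z_nm")])
    D <- as.matrix(dist(P)); diag(D) <- Inf
    expect_gte(min(D), cfg$lumenal$min_separation_nm)
  }
})

test_that("full-background lumenal orientations are uniform on SO(3)", {
  model <- simulate_centriole()
  cfg <- sim_config(23)
  cfg$lumenal$background_fraction <- 1
  lum <- simulate_lumenal_turcs(model, cfg)
  ang <- apply(as.matrix(lum[, c("qw", "qx", "qy", "qz")]), 1,
               function(q) quat_angle(q, cfg$lumenal$planted_orientation))
  # mean geodesic angle to any fixed rotation is ~126.5 deg under uniformity
  expect_lt(abs(mean(ang) - 126.5), 6)
})

test_that("pericentriolar generator follows the truncated-Gaussian law", {
  model <- simulate_centriole()
  cfg <- sim_config(5)
  cfg$pericentriolar$n <- 3000L  # law check at low sampling noise
  pcm <- simulate_pericentriolar_turcs(model, cfg)
  d <- points_to_polylines(as.matrix(pcm[, c("x_nm", "y_nm", "z_nm")]),
                           model$mtt_lines)$distance
  expect_gte(min(d), cfg$pericentriolar$min_nm - 1e-6)
  # empirical 5th/95th percentiles vs an independent Monte-Carlo oracle of
  # the truncated law (plain rejection sampling)
  set.seed(1234)
  mc <- rnorm(4e5, 85, 26)
  mc <- mc[mc >= 30]
  q_mc <- quantile(mc, c(0.05, 0.5, 0.95), type = 8)
  q_emp <- percentile_median_unbiased(d, c(0.05, 0.5, 0.95))
  expect_lt(max(abs(q_emp - q_mc)), 3)
  # closed-form quantile helper agrees with the Monte-Carlo oracle
  expect_equal(unname(q_mc),
               truncnorm_quantile(c(0.05, 0.5, 0.95), 85, 26, 30),
               tolerance = 0.2)
  # sd -> 0 degenerates to the mean
  cfg0 <- small_cfg()
  cfg0$pericentriolar$sd_nm <- 1e-9
  d0 <- points_to_polylines(
    as.matrix(simulate_pericentriolar_turcs(model, cfg0)[, c("x_nm", "y_nm", "z_nm")]),
    model$mtt_lines)$distance
  expect_equal(d0, rep(85, length(d0)), tolerance = 1e-3)
})

test_that("MINFLUX generator plants a recoverable cylinder", {
  # noise-free, decoy-free: aggregated centers on the cylinder after z x 0.7
  cfg <- small_cfg(13)
  cfg$minflux$sigma_xy_nm <- 0
  cfg$minflux$sigma_z_nm <- 0
  cfg$minflux$short_trace_fraction <- 0
  cfg$minflux$decoy_fraction <- 0
  cfg$minflux$efo_high_fraction <- 0
  locs <- simulate_minflux(cfg)
  truth <- attr(locs, "truth")
  filt <- filter_localizations(locs)
  centers <- aggregate_traces(filt)
  for (s in truth$structure_id) {
    P <- as.matrix(centers[centers$structure_id == s,
                           c("x_nm", "y_nm", "z_nm")])
    i <- match(s, truth$structure_id)
    ax <- structure(list(point = as.numeric(truth[i, c("cx", "cy", "cz")]),
                         direction = as.numeric(truth[i, c("dx", "dy", "dz")])),
                    class = "axis3d")
    expect_equal(axis_coordinates(P, ax)$r, rep(35, nrow(P)),
                 tolerance = 1e-6)
  }
  # generators emit finite values only, and are bit-reproducible
  expect_true(all(is.finite(as.matrix(locs[, 4:7]))))
  expect_identical(as.data.frame(simulate_minflux(cfg)), as.data.frame(locs))
  # decoy iterations and high EFO appear at the configured rates
  cfg2 <- small_cfg(13)
  locs2 <- simulate_minflux(cfg2)
  expect_gt(sum(locs2$iteration != 9), 0)
  expect_gt(sum(locs2$efo_khz >= 100), 0)
  valid <- locs2[locs2$iteration == 9, ]
  expect_lt(abs(mean(valid$efo_khz >= 100) - 0.1), 0.02)
})

test_that("pair-set generator plants an exact configuration when noiseless", {
  cfg <- small_cfg(3)
  cfg$pairs$n <- 80L
  cfg$pairs$orientation_noise_deg <- 0
  cfg$pairs$shift_sd_nm <- 0
  ps <- simulate_pair_set(cfg)
  pairs <- pair_particles_to_mtts(ps$turcs, ps$segments, pairing = ps$pairing)
  planted_shift <- -cfg$pairs$planted_distance_nm *
    rotate_vector(cfg$lumenal$planted_orientation, c(1, 0, 0))
  for (i in which(ps$truth)[1:5]) {
    expect_equal(as.numeric(pairs[i, c("shift_x_nm", "shift_y_nm", "shift_z_nm")]),
                 planted_shift, tolerance = 1e-6)
    expect_equal(as.numeric(pairs[i, c("qrel_w", "qrel_x", "qrel_y", "qrel_z")]),
                 cfg$lumenal$planted_orientation, tolerance = 1e-9)
  }
  # planted count is exact
  expect_equal(sum(ps$truth), round(0.42 * 80))
})
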