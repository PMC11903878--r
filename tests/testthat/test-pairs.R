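test_that("pair features follow the local-frame algebra", {
  q90 <- quat_from_axis_angle(c(0, 0, 1), 90)
  f <- build_pair_feature(c(0, 0, 0), c(1, 0, 0, 0), c(80, 0, 0), q90,
                          shift_scale_nm = 60)
  expect_equal(as.numeric(f[, c("shift_x_nm", "shift_y_nm", "shift_z_nm")]),
               c(80, 0, 0))
  expect_equal(as.numeric(f[, c("qrel_w", "qrel_x", "qrel_y", "qrel_z")]),
               q90, tolerance = 1e-9)
  expect_equal(as.numeric(f[, paste0("f", 1:7)]),
               c(80 / 60, 0, 0, q90), tolerance = 1e-9)
  expect_equal(f$com_distance_nm, 80)
  # identical poses give a null feature
  set.seed(301)
  q <- random_quaternions(1)[1, ]
  p <- rnorm(3)
  f0 <- build_pair_feature(p, q, p, q)
  expect_equal(as.numeric(f0[, paste0("f", 1:7)]), c(0, 0, 0, 1, 0, 0, 0),
               tolerance = 1e-9)
})

test_that("pair features are exactly invariant under global rigid motion", {
  set.seed(302)
  for (i in 1:10) {
    p_t <- rnorm(3, 0, 50); q_t <- random_quaternions(1)[1, ]
    p_s <- rnorm(3, 0, 50); q_s <- random_quaternions(1)[1, ]
    base <- build_pair_feature(p_t, q_t, p_s, q_s)
    tf <- random_rigid()
    moved <- build_pair_feature(
      apply_rigid(tf, p_t),
      quat_canonicalize(quat_multiply(tf$rotation, q_t)),
      apply_rigid(tf, p_s),
      quat_canonicalize(quat_multiply(tf$rotation, q_s)))
    expect_equal(as.numeric(moved[, paste0("f", 1:7)]),
                 as.numeric(base[, paste0("f", 1:7)]), tolerance = 1e-9)
  }
})

test_that("pairing rejects off-axis segments and picks the nearest", {
  id4 <- c(1, 0, 0, 0)
  # two segments: one aligned with its interpolated axis, one tilted 45 deg
  q_tilt <- quat_from_axis_angle(c(1, 0, 0), 45)
  segs <- mtt_segment_table(
    c("s_near", "s_far", "s_tilted"), c("m1", "m2", "m3"),
    rbind(c(70, 0, 0), c(90, 0, 0), c(10, 0, 0)),
    rbind(id4, id4, q_tilt),
    rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)))
  turcs <- particle_table("t1", "tomo", rbind(c(0, 0, 0)),
                          matrix(id4, ncol = 4))
  pr <- pair_particles_to_mtts(turcs, segs, axis_tolerance_deg = 30)
  # the tilted segment (closest in space) was rejected; nearest accepted wins
  expect_equal(pr$segment_id, "s_near")
  expect_equal(attr(pr, "counts")$segments_rejected, 1L)
  expect_error(pair_particles_to_mtts(turcs, segs[0, ], 30), "empty")
  # on the synthetic centriole, lumenal particles pair to wall segments
  model <- simulate_centriole()
  cfg <- sim_config(6); cfg$lumenal$n <- 40L; cfg$n_tomograms <- 2L
  lum <- simulate_lumenal_turcs(model, cfg)
  seg_all <- centriole_mtt_segments(model)
  pr2 <- pair_particles_to_mtts(lum, seg_all)
  expect_equal(nrow(pr2), 40L)
  expect_true(all(pr2$com_distance_nm < 115))
})

test_that("distance filter applies inclusive 60-120 bounds", {
  mk <- function(d) {
    build_pair_feature(c(0, 0, 0), c(1, 0, 0, 0), c(d, 0, 0), c(1, 0, 0, 0))
  }
  pairs <- do.call(rbind, lapply(c(59, 60, 80, 120, 130), mk))
  kept <- filter_pairs_by_distance(pairs)
  expect_equal(kept$com_distance_nm, c(60, 80, 120))
  expect_equal(attr(kept, "counts"), list(before = 5L, after = 3L))
  expect_error(filter_pairs_by_distance(pairs, d_min = 100, d_max = 50),
               "config error")
})

test_that("k-means recovers planted structure and degenerate cases", {
  cfg <- sim_config(8)
  cfg$pairs$n <- 60L
  ps <- simulate_pair_set(cfg)
  pairs <- pair_particles_to_mtts(ps$turcs, ps$segments, pairing = ps$pairing)
  # k = 1: one cluster holding everything, mean = global mean
  cl1 <- cluster_pair_configurations(pairs, k = 1, seed = 1, restarts = 3)
  expect_equal(cl1$sizes, nrow(pairs))
  expect_equal(cl1$main_fraction_all, 1)
  expect_equal(unname(cl1$mean_shift_nm),
               unname(colMeans(as.matrix(
                 pairs[, c("shift_x_nm", "shift_y_nm", "shift_z_nm")]))))
  expect_error(cluster_pair_configurations(pairs[1:3, ], k = 5), "n < k")
  # two well-separated planted configurations, k = 2: perfect recovery
  id4 <- c(1, 0, 0, 0)
  qz <- quat_from_axis_angle(c(0, 0, 1), 140)
  mk <- function(p_seg, q_seg, n, jitter_seed) {
    set.seed(jitter_seed)
    do.call(rbind, lapply(1:n, function(i) {
      build_pair_feature(rnorm(3, 0, 0.5), id4, p_seg, q_seg)
    }))
  }
  two <- rbind(mk(c(80, 0, 0), id4, 12, 1), mk(c(-70, 40, 0), qz, 8, 2))
  cl2 <- cluster_pair_configurations(two, k = 2, seed = 3, restarts = 5)
  expect_equal(sort(cl2$sizes), c(8L, 12L))
  expect_equal(length(unique(cl2$assignments[1:12])), 1L)
  expect_equal(length(unique(cl2$assignments[13:20])), 1L)
})

test_that("cluster assignments are invariant to input row order", {
  cfg <- sim_config(12)
  cfg$pairs$n <- 80L
  ps <- simulate_pair_set(cfg)
  pairs <- pair_particles_to_mtts(ps$turcs, ps$segments, pairing = ps$pairing)
  cl <- cluster_pair_configurations(pairs, k = 4, seed = 5, restarts = 10)
  set.seed(303)
  perm <- sample(nrow(pairs))
  clp <- cluster_pair_configurations(pairs[perm, ], k = 4, seed = 5,
                                     restarts = 10)
  # same partition up to label names: compare co-membership
  expect_equal(outer(clp$assignments, clp$assignments, "=="),
               outer(cl$assignments[perm], cl$assignments[perm], "=="))
  expect_equal(sort(clp$sizes), sort(cl$sizes))
})

test_that("wall-facing angle measures sector azimuth against the shift", {
  az <- mean((9:12 - 1)) * 360 / 13  # sector 9-12 mean azimuth
  u <- c(cos(az * pi / 180), sin(az * pi / 180), 0)
  mk_shift <- function(s) {
    data.frame(shift_x_nm = s[1], shift_y_nm = s[2], shift_z_nm = s[3])
  }
  expect_equal(wall_facing_angle(mk_shift(75 * u)), 0, tolerance = 1e-9)
  expect_equal(wall_facing_angle(mk_shift(-75 * u)), 180, tolerance = 1e-9)
  expect_error(wall_facing_angle(mk_shift(c(0, 0, 50))), "undefined")
  # out-of-plane shift is projected to the xy plane
  expect_equal(wall_facing_angle(mk_shift(75 * u + c(0, 0, 40))), 0,
               tolerance = 1e-9)
})
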