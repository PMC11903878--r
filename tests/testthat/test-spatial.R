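test_that("type-8 percentile matches the closed-form plotting position", {
  expect_equal(percentile_median_unbiased(c(10, 20, 30, 40, 50), 0.5), 30)
  # h = 0.25 * (4 + 1/3) + 1/3 = 1.41667 -> interpolate x1..x2
  expect_equal(percentile_median_unbiased(1:4, 0.25), 1.416667,
               tolerance = 1e-6)
  # h = 0.9 * 16/3 + 1/3 = 5.133 clamps to n = 5
  expect_equal(percentile_median_unbiased(c(10, 20, 30, 40, 50), 0.9), 50)
  expect_equal(percentile_median_unbiased(c(3, 1, 2), c(0, 1)), c(1, 3))
  expect_error(percentile_median_unbiased(numeric(0), 0.5), "empty")
  expect_error(percentile_median_unbiased(1:5, 1.2), "domain")
  # monotone in p
  set.seed(200)
  v <- rnorm(37)
  ps <- seq(0, 1, by = 0.05)
  expect_false(is.unsorted(percentile_median_unbiased(v, ps)))
})

test_that("type-8 percentile agrees with the independent reference", {
  set.seed(201)
  for (i in 1:200) {
    v <- rnorm(sample(2:60, 1), sd = runif(1, 0.5, 50))
    p <- runif(3)
    expect_equal(percentile_median_unbiased(v, p),
                 unname(quantile(v, p, type = 8)), tolerance = 1e-12)
  }
})

test_that("pool classification uses wall radius and axial extent", {
  model <- simulate_centriole()  # wall 115, length 450, axis = z
  tab <- particle_table(
    c("a", "b", "c", "d"), "t1",
    rbind(c(40, 0, 0),      # inside lumen, mid-length
          c(200, 0, 0),     # radially outside
          c(40, 0, 325),    # inside radius but 100 nm beyond the distal end
          c(110, 0, 0)),    # within margin of the wall
    matrix(rep(c(1, 0, 0, 0), 4), ncol = 4, byrow = TRUE))
  lab <- classify_pools(tab, model, margin_nm = 10)
  expect_equal(lab$pool, c("lumenal", "pericentriolar", "pericentriolar",
                           "pericentriolar"))
  # labels invariant under joint rigid motion
  set.seed(202)
  tf <- random_rigid()
  lab2 <- classify_pools(transform_particles(tab, tf),
                         transform_model(model, tf), margin_nm = 10)
  expect_equal(lab2$pool, lab$pool)
})

test_that("signed distances carry the pool sign convention", {
  model <- simulate_centriole()
  seg <- centriole_mtt_segments(model)
  q_seg <- as.numeric(seg[1, c("qw", "qx", "qy", "qz")])
  ctr <- as.numeric(seg[1, c("x_nm", "y_nm", "z_nm")])
  inward <- rotate_vector(q_seg, c(1, 0, 0))
  tab <- particle_table(
    c("lum", "pcm"), "t1",
    rbind(ctr + 75 * inward, ctr - 85 * inward),
    matrix(rep(c(1, 0, 0, 0), 2), ncol = 4, byrow = TRUE))
  lab <- classify_pools(tab, model)
  res <- signed_mtt_distances(lab, model)
  expect_equal(res$distance_nm, c(-75, 85), tolerance = 1e-6)
  expect_error(signed_mtt_distances(tab, model), "classify_pools")
  # magnitudes invariant under joint rigid motion
  set.seed(203)
  tf <- random_rigid()
  res2 <- signed_mtt_distances(
    classify_pools(transform_particles(tab, tf), transform_model(model, tf)),
    transform_model(model, tf))
  expect_equal(res2$distance_nm, res$distance_nm, tolerance = 1e-9)
})

test_that("nearest-neighbor distances match enumeration and the O(n^2) oracle", {
  id <- function(n) matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  tab <- particle_table(c("a", "b", "c"), "t1",
                        cbind(c(0, 25, 60), 0, 0), id(3))
  nn <- nearest_neighbor_distances(tab, within_pool = FALSE)
  expect_equal(nn$nn_nm, c(25, 25, 35))
  # square lattice spacing 25
  g <- expand.grid(x = (0:3) * 25, y = (0:3) * 25)
  tab2 <- particle_table(sprintf("g%02d", 1:16), "t1",
                         cbind(g$x, g$y, 0), id(16))
  expect_equal(nearest_neighbor_distances(tab2, FALSE)$nn_nm, rep(25, 16))
  # randomized set vs brute force, grouped per tomogram
  set.seed(204)
  P <- matrix(runif(150, 0, 200), ncol = 3)
  tomo <- rep(c("t1", "t2"), c(20, 30))
  tab3 <- particle_table(sprintf("r%02d", 1:50), tomo, P, id(50))
  nn3 <- nearest_neighbor_distances(tab3, FALSE)
  for (tm in c("t1", "t2")) {
    idx <- which(tomo == tm)
    D <- as.matrix(dist(P[idx, ])); diag(D) <- Inf
    expect_equal(nn3$nn_nm[nn3$tomo_id == tm], unname(apply(D, 1, min)),
                 tolerance = 1e-12)
  }
  # singleton group excluded with a warning
  tab4 <- particle_table(c("a", "b", "c"), c("t1", "t1", "t2"),
                         matrix(runif(9), 3), id(3))
  expect_warning(nn4 <- nearest_neighbor_distances(tab4, FALSE), "singleton")
  expect_equal(nrow(nn4), 2L)
})

test_that("radial-axial profiles localize planted radii", {
  ax <- structure(list(point = c(0, 0, 0), direction = c(0, 0, 1)),
                  class = "axis3d")
  prof <- radial_axial_profile(rbind(c(0, 0, 10), c(35, 0, 50)), ax)
  expect_equal(prof$coords$r, c(0, 35))
  expect_equal(prof$coords$s, c(10, 50))
  expect_equal(sum(prof$counts), 2L)
  # cylinder sample: histogram mode bin contains the planted radius
  set.seed(205)
  th <- runif(400, 0, 2 * pi)
  pts <- cbind(35 * cos(th), 35 * sin(th), runif(400, 0, 300)) +
    matrix(rnorm(1200, 0, 2), ncol = 3)
  prof2 <- radial_axial_profile(pts, ax, breaks = seq(0, 100, 5))
  mode_bin <- which.max(prof2$counts)
  expect_true(prof2$breaks[mode_bin] <= 35 && 35 <= prof2$breaks[mode_bin + 1])
  expect_equal(sum(prof2$counts), 400L)
})

test_that("distribution summaries use type-8 percentiles throughout", {
  s <- summarize_distribution(1:100)
  expect_equal(s$median, 50.5)
  # closed-form type-8 on the integer ramp: value = h
  h <- function(p) min(max(p * (100 + 1 / 3) + 1 / 3, 1), 100)
  expect_equal(s$interval_90, c(h(0.05), h(0.95)))
  expect_equal(s$interval_95, c(h(0.025), h(0.975)))
  cs <- summarize_distribution(rep(7, 12))
  expect_equal(cs$median, 7)
  expect_equal(cs$interval_90, c(7, 7))
  # Gaussian interval close to +-1.645 sigma at n = 1000
  set.seed(206)
  g <- rnorm(1000, 0, 10)
  sg <- summarize_distribution(g)
  expect_lt(abs(sg$interval_90[2] - 16.45), 0.05 * 16.45 + 1)
  expect_lt(abs(sg$interval_90[1] + 16.45), 0.05 * 16.45 + 1)
  expect_error(summarize_distribution(numeric(0)), "empty")
})
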