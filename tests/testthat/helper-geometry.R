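# shared fixtures: random rotations/transforms and small point sets

random_rigid <- function() {
  rigid_transform(random_quaternions(1)[1, ], stats::rnorm(3, 0, 50))
}

unit_tetrahedron <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

# a chiral 4-point set (no symmetry plane)
chiral_points <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0.3, 0.1, 3))
}

# apply a rigid transform to a particle or segment table (positions and
# quaternions jointly), for invariance tests
transform_particles <- function(tab, tf) {
  P <- as.matrix(tab[, c("x_nm", "y_nm", "z_nm")])
  tab[, c("x_nm", "y_nm", "z_nm")] <- apply_rigid(tf, P)
  Q <- as.matrix(tab[, c("qw", "qx", "qy", "qz")])
  Qn <- t(apply(Q, 1, function(q) quat_canonicalize(quat_multiply(tf$rotation, q))))
  tab[, c("qw", "qx", "qy", "qz")] <- Qn
  if (all(c("ax", "ay", "az") %in% names(tab))) {
    A <- as.matrix(tab[, c("ax", "ay", "az")])
    tab[, c("ax", "ay", "az")] <- rotate_vector(tf$rotation, A)
  }
  tab
}

transform_model <- function(model, tf) {
  model$mtt_lines <- lapply(model$mtt_lines, function(l) {
    polyline(apply_rigid(tf, l$vertices))
  })
  model$axis <- structure(list(
    point = apply_rigid(tf, model$axis$point),
    direction = rotate_vector(tf$rotation, model$axis$direction)),
    class = "axis3d")
  model
}

# constructed localization fixture with known filter outcomes:
#  trace a: 5 valid rows, one with high EFO -> survives with 4 rows
#  trace b: 4 valid rows, one with high EFO -> trace dropped (3 < 4)
#  trace c: 4 valid rows, all clean         -> survives with 4 rows
#  trace d: 6 rows at iteration 5           -> all dropped (iteration)
filter_fixture <- function() {
  mk <- function(tid, n, it, efo) {
    localization_table(rep(tid, n), "S1", rep(it, n),
                       cbind(seq_len(n), 0, 10), efo)
  }
  validate_localization_table(rbind(
    mk("a", 5, 9, c(50, 50, 120, 50, 50)),
    mk("b", 4, 9, c(50, 120, 50, 50)),
    mk("c", 4, 9, rep(50, 4)),
    mk("d", 6, 5, rep(50, 6))))
}
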