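# a 3-site collinear rule for the hand-worked cost example
line_rule <- function() {
  sites <- data.frame(x = c(0, 10, 20), y = 0, z = 0,
                      role = c("char_bit", "pos_bit", "marker_filled"),
                      logical_bit = c(1L, 2L, NA))
  pattern_rule("line3", sites, 1L, 1L, pitch = 10)
}

test_that("cost_2d reproduces the hand-worked example", {
  rule <- line_rule()
  A <- rbind(c(1, 0), c(10, 0))
  out <- cost_2d(A, c(1, 1), rule, transform_2d(),
                 alignment_config(W_O = 2))
  expect_equal(out$D, 1L) # the marker at (20, 0) is nearest to no centroid
  expect_equal(out$cost, sqrt(2) / 2 * 1, tolerance = 1e-12)
  expect_equal(out$assignment, c(1L, 2L))

  # quadratic in the cluster sizes
  out2 <- cost_2d(A, c(2, 2), rule, transform_2d(), alignment_config(W_O = 2))
  expect_equal(out2$cost, 4 * out$cost, tolerance = 1e-12)

  # perfect match with all markers assigned costs zero
  out0 <- cost_2d(rbind(c(0, 0), c(10, 0), c(20, 0)), c(5, 5, 5), rule,
                  transform_2d(), alignment_config(W_O = 2))
  expect_equal(out0$cost, 0)
  expect_equal(out0$D, 0L)

  expect_error(cost_2d(A, c(1, 1), rule, transform_2d(sx = 0.2)),
               "degenerate")
})

test_that("cost_2d matches the brute-force oracle on random instances", {
  rule <- rule_rro12()
  marker <- rule$sites$role == "marker_filled"
  set.seed(31)
  for (i in 1:300) {
    n <- sample(3:14, 1)
    A <- matrix(runif(2 * n, -50, 50), ncol = 2)
    S <- sample(1:60, n, replace = TRUE)
    tr <- transform_2d(runif(1, 0, 360), runif(1, 0.7, 1.3),
                       runif(1, 0.7, 1.3), runif(1, -20, 20),
                       runif(1, -20, 20))
    WO <- runif(1, 1.01, 3)
    got <- cost_2d(A, S, rule, tr, alignment_config(W_O = WO,
                                                    scale_bounds = c(0.7, 1.3)))
    Tt <- apply_transform_2d(tr, as.matrix(rule$sites[, c("x", "y")]))
    want <- oracle_cost_2d(A, S, Tt, marker, WO)
    expect_equal(got$cost, want$cost, tolerance = 1e-9)
    expect_equal(got$assignment, want$assignment)
    expect_equal(got$D, want$D)
  }
})

test_that("cost_3d matches its oracle and the stated examples", {
  rule <- rule_cuboctahedron()
  Tt <- as.matrix(rule$sites[, c("x", "y", "z")])
  expect_equal(cost_3d(Tt, rule)$cost, 0)

  shifted <- Tt
  shifted[1, ] <- shifted[1, ] + c(3, 0, 0) # one centroid displaced by d
  expect_equal(cost_3d(shifted, rule)$cost, 9, tolerance = 1e-9)

  set.seed(32)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    A <- matrix(runif(3 * n, -60, 60), ncol = 3)
    tr <- transform_3d(z_scale = runif(1, 1, 4), phi = runif(1, 0, 360),
                       tx = runif(1, -10, 10), ty = runif(1, -10, 10))
    got <- cost_3d(A, rule, tr)
    Tm <- paintcrypt:::transformed_template_3d(tr, rule)
    expect_equal(got$cost, oracle_cost_3d(A, Tm), tolerance = 1e-9)
  }
})

test_that("align_2d recovers planted transforms on noiseless centroids", {
  rule <- rule_rro48()
  pat <- encode_message("AU", rule, default_map_6bit())[[2]]
  set.seed(33)
  cfg <- alignment_config()
  for (i in 1:30) {
    theta <- runif(1, 0, 360)
    sx <- runif(1, 0.95, 1.05); sy <- runif(1, 0.95, 1.05)
    tv <- runif(2, -40, 40)
    A <- planted_centroids(rule, pat$occupied, theta, sx, sy, tv[1], tv[2])
    res <- align_2d(A, rep(30, nrow(A)), rule, cfg)
    expect_lt(ang_diff(res$transform$theta, theta), cfg$rot_step)
    expect_lt(abs(res$transform$sx - sx), 0.02)
    expect_lt(abs(res$transform$sy - sy), 0.02)
    expect_lt(res$cost, 1)
    expect_equal(res$D, 0L)
    # shear angle from the fitted linear map matches the planted one
    planted_alpha <- paintcrypt:::shear_angle_deg(
      diag(c(sx, sy)) %*% rot2d(theta))
    expect_lt(abs(res$alpha - planted_alpha), 1)
  }
})

test_that("centroids equal to the template give the identity transform", {
  rule <- rule_rro48()
  A <- as.matrix(rule$sites[, c("x", "y")])
  res <- align_2d(A, rep(30, nrow(A)), rule)
  expect_lt(res$cost, 1)
  expect_lt(min(ang_diff(res$transform$theta, 0),
                ang_diff(res$transform$theta, 180)), 2)
  # the full grid is 180-degree symmetric as a point set, so theta is only
  # identified modulo 180; scales and translation must still be clean
  expect_lt(abs(res$transform$sx - 1), 0.02)
  expect_lt(abs(res$transform$tx), 2)
})

test_that("marker machinery resolves 180-degree flips on sparse patterns", {
  rule <- rule_rro12()
  blind <- rule
  blind$sites$role[blind$sites$role == "marker_filled"] <- "marker_empty"
  pat <- encode_message("N", rule, default_map_3bit())[[1]]
  xy <- planted_centroids(rule, pat$occupied, 0)
  count_flips <- function(r) {
    set.seed(5)
    flips <- 0
    for (i in 1:60) {
      th <- runif(1, 0, 360)
      A <- planted_centroids(rule, pat$occupied, th) +
        matrix(rnorm(2 * nrow(xy), 0, 1), ncol = 2)
      res <- align_2d(A, rep(30, nrow(A)), r)
      flips <- flips + (ang_diff(res$transform$theta, th) > 90)
    }
    flips
  }
  with_markers <- count_flips(rule)
  marker_blind <- count_flips(blind)
  expect_lt(with_markers, marker_blind) # strictly fewer misorientations
  expect_lte(with_markers, 3)
})

test_that("minimal cost is invariant under a global rigid motion", {
  rule <- rule_rro48()
  pat <- encode_message("S", rule, default_map_6bit())[[1]]
  set.seed(34)
  A <- planted_centroids(rule, pat$occupied, 25, 1.02, 0.98, 10, -5) +
    matrix(rnorm(2 * sum(pat$occupied), 0, 1), ncol = 2)
  base <- align_2d(A, rep(30, nrow(A)), rule)
  R <- rot2d(73)
  A2 <- A %*% t(R)
  A2[, 1] <- A2[, 1] + 15; A2[, 2] <- A2[, 2] - 8
  moved <- align_2d(A2, rep(30, nrow(A2)), rule)
  expect_equal(moved$cost, base$cost, tolerance = 0.15)
  expect_equal(sort(moved$assignment), sort(base$assignment))
})

test_that("global mode agrees with the two-stage optimizer", {
  rule <- rule_rro48()
  pat <- encode_message("U", rule, default_map_6bit())[[1]]
  set.seed(35)
  A <- planted_centroids(rule, pat$occupied, 111, 1.03, 0.97, 5, 12) +
    matrix(rnorm(2 * sum(pat$occupied), 0, 0.8), ncol = 2)
  two <- align_2d(A, rep(30, nrow(A)), rule, alignment_config(mode = "two_stage"))
  glb <- align_2d(A, rep(30, nrow(A)), rule,
                  alignment_config(mode = "global", n_starts = 60, seed = 2))
  expect_lt(ang_diff(glb$transform$theta, two$transform$theta), 3)
  expect_lt(abs(glb$cost - two$cost) / max(two$cost, 1), 0.3)
})

test_that("align_3d recovers a planted z compression and z rotation", {
  rule <- rule_cuboctahedron()
  pat <- encode_message("7", rule, digit_map(4))[[1]] # asymmetric subset
  occ <- which(pat$occupied)
  xyz <- as.matrix(rule$sites[occ, c("x", "y", "z")])
  cfg <- alignment_config()
  set.seed(36)
  for (i in 1:8) {
    phi <- runif(1, 0, 360)
    A <- xyz
    A[, 3] <- A[, 3] / 3.3
    R <- diag(3); R[1:2, 1:2] <- rot2d(phi)
    A <- A %*% t(R)
    res <- align_3d(A, rule, cfg)
    expect_lte(abs(res$transform$z_scale - 3.3), 0.1 + 1e-9) # grid resolution
    expect_lte(ang_diff(res$transform$phi, phi), cfg$phi_step + 1e-9)
    expect_true(res$accepted)
    expect_equal(sort(unique(res$assignment)), occ)
  }
})

test_that("3D cost grows monotonically with centroid noise", {
  rule <- rule_cuboctahedron()
  pat <- encode_message("7", rule, digit_map(4))[[1]]
  xyz <- as.matrix(rule$sites[pat$occupied, c("x", "y", "z")])
  cfg <- alignment_config(phi_step = 6, trans_step_3d = 4, trans_range_3d = 8,
                          z_scale_grid = seq(1, 2, 0.25))
  med_cost <- vapply(c(0.5, 2, 5), function(sig) {
    set.seed(37)
    median(vapply(1:25, function(i) {
      A <- xyz + matrix(rnorm(length(xyz), 0, sig), ncol = 3)
      align_3d(A, rule, cfg)$cost
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_cost) > 0))
})

test_that("the marker check accepts and rejects by marker assignment", {
  rule <- rule_cuboctahedron()
  filled <- filled_marker_sites(rule)
  empty <- empty_marker_sites(rule)
  res <- list(dim = 3L, assignment = c(filled, 9L))
  expect_true(marker_check(res, rule))
  expect_false(marker_check(list(dim = 3L, assignment = filled[-1]), rule))
  expect_false(marker_check(list(dim = 3L,
                                 assignment = c(filled, empty[1])), rule))
  # 2D rules always pass: markers act through the cost instead
  expect_true(marker_check(list(dim = 2L, assignment = 1L), rule_rro12()))
})

test_that("SVD superposition recovers rigid motions and z scales", {
  A <- as.matrix(rule_cuboctahedron()$sites[, c("x", "y", "z")])
  same <- superpose_with_z_scale(A, A, z_scale_grid = c(0.5, 1, 2))
  expect_equal(same$z_scale, 1)
  expect_lt(same$rmsd, 1e-9)

  R <- diag(3); R[1:2, 1:2] <- rot2d(30)
  B <- A %*% t(R)
  rot <- superpose_with_z_scale(A, B, z_scale_grid = 1)
  expect_lt(rot$rmsd, 1e-9)
  expect_equal(rot$rotation, R, tolerance = 1e-9)

  set.seed(38)
  errs <- vapply(1:20, function(i) {
    n <- 64
    cloud <- cbind(runif(n, -50, 50), runif(n, -50, 50), runif(n, -50, 50))
    comp <- cloud
    comp[, 3] <- comp[, 3] * 0.3
    comp <- comp + matrix(rnorm(3 * n, 0, 1), ncol = 3)
    f <- superpose_with_z_scale(comp, cloud, seq(1, 5, 0.05))
    abs(f$z_scale - 1 / 0.3) / (1 / 0.3)
  }, numeric(1))
  expect_true(all(errs <= 0.06))

  expect_error(superpose_with_z_scale(matrix(0, 2, 3), matrix(0, 2, 3)),
               "non-collinear")
})
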