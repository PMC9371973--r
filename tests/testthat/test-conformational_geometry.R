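test_that("Kabsch superposition recovers planted transforms", {
  set.seed(11)
  X <- matrix(rnorm(150, sd = 8), ncol = 3)
  t_id <- kabsch_superpose(X, X)
  expect_equal(t_id$rotation, diag(3), tolerance = 1e-10)
  expect_lt(t_id$rmsd, 1e-10)

  R90 <- rotation_matrix(c(0, 0, 1), 90)
  t90 <- kabsch_superpose(X %*% t(R90), X)
  expect_equal(rotation_angle(t90)$angle, 90, tolerance = 1e-9)
  expect_lt(t90$rmsd, 1e-9)

  expect_error(kabsch_superpose(X, X[1:10, ]), "differ in length")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("noisy superposition agrees with an independent implementation", {
  set.seed(23)
  X <- matrix(rnorm(150, sd = 8), ncol = 3)
  R <- rotation_matrix(c(1, 2, 3), 37)
  Y <- X %*% t(R) + matrix(rnorm(150, sd = 0.2), ncol = 3) +
    matrix(5, nrow(X), 3)
  t_pkg <- kabsch_superpose(X, Y)
  # cross-check against bio3d's least-squares fit
  xyz_fixed <- as.vector(t(X))
  xyz_mob <- as.vector(t(Y))
  fitted <- matrix(as.numeric(suppressWarnings(
    bio3d::fit.xyz(fixed = xyz_fixed, mobile = xyz_mob))),
    ncol = 3, byrow = TRUE)
  rmsd_bio3d <- sqrt(mean(rowSums((fitted - X)^2)))
  expect_equal(t_pkg$rmsd, rmsd_bio3d, tolerance = 1e-6)
  # applying the transform reproduces the reported rmsd
  expect_equal(sqrt(mean(rowSums((apply_transform(t_pkg, Y) - X)^2))),
               t_pkg$rmsd, tolerance = 1e-12)
})

test_that("axis-angle decomposition matches the quaternion oracle", {
  expect_equal(rotation_angle(diag(3))$angle, 0)
  expect_false(rotation_angle(diag(3))$axis_defined)

  r126 <- rotation_matrix(c(2, -1, 0.5), 126)
  d <- rotation_angle(r126)
  expect_equal(d$angle, 126, tolerance = 1e-9)
  expect_equal(abs(sum(d$axis * c(2, -1, 0.5) / sqrt(5.25))), 1,
               tolerance = 1e-9)

  set.seed(5)
  for (i in 1:50) {
    R <- random_rotation()
    expect_equal(rotation_angle(R)$angle, quat_angle_deg(R),
                 tolerance = 1e-9)
  }
  # near-180 rotations: axis from eigen-decomposition stays finite
  r179 <- rotation_matrix(c(0, 1, 0), 179.9999)
  d179 <- rotation_angle(r179)
  expect_equal(d179$angle, 179.9999, tolerance = 1e-4)
  expect_equal(abs(d179$axis[2]), 1, tolerance = 1e-4)
})

test_that("helix axis fitting recovers direction for ideal and rotated helices", {
  h <- make_helix(12)
  sel <- select_atoms(h, domain_definition("h", "A", c(1, 12)), "CA")
  ax <- fit_helix_axis(sel)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1 - cos(0.5 * pi / 180))
  expect_lt(kink_angle(ax$direction, c(0, 0, 1)), 0.5)

  R <- rotation_matrix(c(1, 1, 0), 70)
  rot <- sel$coords %*% t(R)
  ax_rot <- fit_helix_axis(rot)
  expect_lt(kink_angle(ax_rot$direction, as.vector(R %*% c(0, 0, 1))), 0.5)

  expect_error(fit_helix_axis(sel$coords[1:5, ]), ">= 6")
})

test_that("helix axis is robust to coordinate noise", {
  errs <- vapply(1:100, function(s) {
    h <- make_helix(12, noise_sd = 0.3, seed = s)
    sel <- select_atoms(h, domain_definition("h", "A", c(1, 12)), "CA")
    kink_angle(fit_helix_axis(sel)$direction, c(0, 0, 1))
  }, numeric(1))
  expect_lt(mean(errs), 3)
})

test_that("kink angles read 0 / 60 / 180 for constructed axis pairs", {
  expect_equal(kink_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  v60 <- as.vector(rotation_matrix(c(1, 0, 0), 60) %*% c(0, 0, 1))
  expect_equal(kink_angle(c(0, 0, 1), v60), 60, tolerance = 1e-9)
  expect_equal(kink_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  # symmetry and invariance under a global rigid motion
  set.seed(9)
  R <- random_rotation()
  a <- c(0.2, -0.5, 1); b <- c(1, 0.3, -0.2)
  expect_equal(kink_angle(a, b), kink_angle(b, a))
  expect_equal(kink_angle(as.vector(R %*% a), as.vector(R %*% b)),
               kink_angle(a, b), tolerance = 1e-9)
})

test_that("hinge opening recovers a planted bend and is antisymmetric", {
  straight <- make_helix(24, label = "open")
  bent <- make_helix(24, kink_deg = 126, kink_pos = 12, label = "closed")
  segs <- prex1_hinge_segments("A", n_half = c(1, 12), c_half = c(13, 24))
  opening <- hinge_opening(bent, straight, segs$seg1, segs$seg2)
  expect_equal(as.numeric(opening), 126, tolerance = 1)
  expect_equal(as.numeric(hinge_opening(straight, bent, segs$seg1,
                                        segs$seg2)),
               -as.numeric(opening), tolerance = 1e-9)
  expect_equal(as.numeric(hinge_opening(bent, bent, segs$seg1, segs$seg2)),
               0, tolerance = 1e-9)
  short <- make_helix(8)
  suppressWarnings(
    expect_error(hinge_opening(short, short, segs$seg1, segs$seg2),
                 "unresolved"))
})

test_that("domain rotation recovers planted rigid-body motions", {
  td0 <- make_two_domain(angle_deg = 0)
  d0 <- domain_rotation(td0$conformer1, td0$conformer2, td0$domain_a,
                        td0$domain_b)
  expect_lt(d0$angle, 1e-6)

  td45 <- make_two_domain(angle_deg = 45, axis = c(0, 1, 1),
                          translation = c(2, 0, 0))
  d45 <- domain_rotation(td45$conformer1, td45$conformer2, td45$domain_a,
                         td45$domain_b)
  expect_equal(d45$angle, 45, tolerance = 1e-6)
  expect_lt(kink_angle(d45$axis, td45$planted$axis), 1)

  td_err <- make_two_domain(n_res = 5L)
  expect_error(domain_rotation(td_err$conformer1, td_err$conformer2,
                               td_err$domain_a, td_err$domain_b),
               ">= 10 common")
})

test_that("domain rotation stays within 2 degrees under 0.2 A noise", {
  errs <- vapply(1:50, function(s) {
    td <- make_two_domain(angle_deg = 70, axis = c(1, 0, 2),
                          noise_sd = 0.2, seed = s)
    abs(domain_rotation(td$conformer1, td$conformer2, td$domain_a,
                        td$domain_b)$angle - 70)
  }, numeric(1))
  expect_lt(max(errs), 2)
})

test_that("angles are finite, clamped to [0, 180], and never NaN", {
  set.seed(31)
  for (i in 1:20) {
    R <- random_rotation()
    a <- rotation_angle(R)$angle
    expect_false(is.nan(a))
    expect_gte(a, 0)
    expect_lte(a, 180)
  }
})
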