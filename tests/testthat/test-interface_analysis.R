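one_atom <- function(el = "C", x = 0, y = 0, z = 0, resno = 1L,
                     resid = "LIG") {
  data.frame(elety = paste0(el, "1"), resid = resid, chain = "A",
             resno = resno, x = x, y = y, z = z, elesy = el,
             stringsAsFactors = FALSE)
}

test_that("an isolated carbon matches the analytic sphere area", {
  m <- structure_model(one_atom("C"))
  s <- sasa(m)
  analytic <- 4 * pi * (1.70 + 1.40)^2
  expect_equal(s$total, analytic, tolerance = 0.005)
  expect_equal(s$residue_area$area, s$total)
  expect_equal(s$n_sphere_points, 960L)
})

test_that("well-separated atoms each keep their isolated-sphere area", {
  at <- rbind(one_atom("C"), one_atom("C", x = 10, resno = 2L))
  s <- sasa(structure_model(at))
  iso <- 4 * pi * 3.10^2
  expect_equal(s$atom_area, rep(iso, 2), tolerance = 0.005)
})

test_that("an overlapping pair matches the spherical-cap closed form", {
  for (d in c(2.0, 3.5, 5.0)) {
    at <- rbind(one_atom("C"), one_atom("O", x = d, resno = 2L))
    s <- sasa(structure_model(at))
    r1 <- 1.70 + 1.40; r2 <- 1.52 + 1.40
    expect_equal(s$atom_area[1], cap_exposed_area(r1, r2, d),
                 tolerance = 0.01)
    expect_equal(s$atom_area[2], cap_exposed_area(r2, r1, d),
                 tolerance = 0.01)
  }
})

test_that("SASA is rotation invariant and monotone under atom addition", {
  h <- make_helix(10)
  s0 <- sasa(h, n_points = 1920L)
  R <- rotation_matrix(c(3, 1, 2), 77)
  h_rot <- h
  h_rot$atoms[, c("x", "y", "z")] <-
    as.matrix(h$atoms[, c("x", "y", "z")]) %*% t(R)
  expect_equal(sasa(h_rot, n_points = 1920L)$total, s0$total,
               tolerance = 0.001)
  s0 <- sasa(h)

  # adding an atom can only shade existing atoms
  h_plus <- structure_model(rbind(h$atoms[, names(one_atom())],
                                  one_atom("C", x = 2.5, y = 0, z = 7,
                                           resno = 99L)))
  s1 <- sasa(h_plus)
  n <- nrow(h$atoms)
  expect_true(all(s1$atom_area[seq_len(n)] <= s0$atom_area + 1e-9))
})

test_that("per-residue sums equal their atoms and refine stably", {
  h <- make_helix(8)
  s <- sasa(h)
  key <- paste(s$atoms$chain, s$atoms$resno)
  sums <- tapply(s$atom_area, key, sum)
  expect_equal(sort(as.numeric(sums)), sort(s$residue_area$area))
  # doubling the quadrature changes per-residue areas by < 1%
  s2 <- sasa(h, n_points = 1920L)
  expect_equal(s2$residue_area$area, s$residue_area$area,
               tolerance = 0.01)
})

test_that("unknown elements without a radius raise an error", {
  m <- structure_model(one_atom("XX"))
  expect_error(sasa(m), "no radius")
  r_extra <- default_radii(extra = c(XX = 2.0))
  expect_equal(sasa(m, radii = r_extra)$total, 4 * pi * 3.4^2,
               tolerance = 0.005)
})

test_that("buried area is zero far from the interface and positive at it", {
  # component A: one residue; component B: a 3-atom slab nearby or far
  slab <- function(x0, resno0) do.call(rbind, lapply(0:2, function(i)
    one_atom("C", x = x0, y = (i - 1) * 2.5, resno = resno0 + i,
             resid = "ALA")))
  far <- structure_model(rbind(one_atom("C", resno = 1L, resid = "ALA"),
                               slab(30, 10L)))
  ca <- domain_definition("a", "A", c(1, 1))
  cb <- domain_definition("b", "A", c(10, 12))
  res <- data.frame(chain = "A", resno = 1L)
  b_far <- buried_area(far, ca, cb, res)
  expect_lt(b_far$combined, 1)

  near <- structure_model(rbind(one_atom("C", resno = 1L, resid = "ALA"),
                                slab(4, 10L)))
  b_near <- buried_area(near, ca, cb, res)
  expect_gt(b_near$combined, 10)
  expect_true(all(b_near$per_residue$bsa >= 0))
  # refinement: doubled quadrature agrees within 2%
  b_fine <- buried_area(near, ca, cb, res, n_points = 1920L)
  expect_equal(b_fine$combined, b_near$combined, tolerance = 0.02)
})

test_that("buried area validates component membership and disjointness", {
  m <- make_helix(10)
  ca <- domain_definition("a", "A", c(1, 5))
  cb <- domain_definition("b", "A", c(4, 10))
  expect_error(buried_area(m, ca, cb, data.frame(chain = "A", resno = 1L)),
               "overlap")
  cb2 <- domain_definition("b", "A", c(6, 10))
  expect_error(buried_area(m, ca, cb2,
                           data.frame(chain = "A", resno = 99L)),
               "outside both components")
})

test_that("hydrogen bonds are detected by distance and rejected beyond it", {
  at <- rbind(
    data.frame(elety = "OG1", resid = "THR", chain = "A", resno = 240L,
               x = 0, y = 0, z = 0, elesy = "O", stringsAsFactors = FALSE),
    data.frame(elety = "O", resid = "CYS", chain = "A", resno = 234L,
               x = 2.9, y = 0, z = 0, elesy = "O", stringsAsFactors = FALSE),
    data.frame(elety = "O", resid = "ILE", chain = "A", resno = 237L,
               x = 0, y = 4.0, z = 0, elesy = "O", stringsAsFactors = FALSE))
  m <- structure_model(at)
  don <- data.frame(chain = "A", resno = 240L, elety = "OG1")
  acc <- data.frame(chain = "A", resno = c(234L, 237L), elety = "O")
  hb <- hydrogen_bonds(m, don, acc)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$acceptor_resno, 234L)
  expect_equal(hb$distance, 2.9)
  expect_error(hydrogen_bonds(m, don[0, ], acc), "empty")
})

test_that("the D-H...A angle filter applies when hydrogens are present", {
  base <- data.frame(elety = c("N", "HN"), resid = "ALA", chain = "A",
                     resno = 1L, x = c(0, 1.0), y = 0, z = 0,
                     elesy = c("N", "H"), stringsAsFactors = FALSE)
  don <- data.frame(chain = "A", resno = 1L, elety = "N")
  acc <- data.frame(chain = "A", resno = 2L, elety = "O")
  # acceptor in line with the hydrogen: angle 180, accepted
  lin <- structure_model(rbind(base, data.frame(
    elety = "O", resid = "ALA", chain = "A", resno = 2L, x = 2.9, y = 0,
    z = 0, elesy = "O", stringsAsFactors = FALSE)))
  hb1 <- hydrogen_bonds(lin, don, acc, require_angle = TRUE)
  expect_equal(nrow(hb1), 1L)
  expect_gt(hb1$angle, 179)
  # acceptor behind the donor: D-H...A angle ~37 degrees, rejected
  back <- structure_model(rbind(base, data.frame(
    elety = "O", resid = "ALA", chain = "A", resno = 2L, x = -1, y = 2.5,
    z = 0, elesy = "O", stringsAsFactors = FALSE)))
  expect_equal(nrow(hydrogen_bonds(back, don, acc, require_angle = TRUE)),
               0L)
})
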