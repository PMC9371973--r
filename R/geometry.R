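as_coord_matrix <- function(x) {
  if (inherits(x, "atom_selection")) x <- x$coords
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinate sets, by singular value decomposition of the
#' covariance matrix with the standard determinant correction that
#' excludes reflections.
#'
#' @param reference n x 3 matrix (or `atom_selection`), angstrom.
#' @param mobile n x 3 matrix paired row-by-row with `reference`.
#' @return List of class `rigid_transform`: `rotation` (3 x 3, applied to
#'   centered mobile coordinates), `translation`, `rmsd` (angstrom).
#'   Applying the transform maps `mobile` onto `reference`.
#' @export
kabsch_superpose <- function(reference, mobile) {
  X <- as_coord_matrix(reference); Y <- as_coord_matrix(mobile)
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in length (",
                               nrow(X), " vs ", nrow(Y), ")")
  if (nrow(X) < 3L) stop("need at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # degeneracy: all points collinear leaves the rotation underdetermined
  if (qr(Xc)$rank < 2L || qr(Yc)$rank < 2L) {
    stop("degenerate (collinear) coordinates: superposition underdetermined")
  }
  H <- crossprod(Yc, Xc)        # covariance, mobile -> reference
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Xc)^2)))
  structure(list(rotation = R, translation = cx - as.vector(R %*% cy),
                 rmsd = rmsd, center_mobile = cy, center_reference = cx),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param t a `rigid_transform`.
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(t, coords) {
  X <- as_coord_matrix(coords)
  sweep(X %*% t(t$rotation), 2, t$translation, `+`)
}

#' Axis-angle decomposition of a rotation
#'
#' Reads a rigid transform as a single rotation: the angle from the trace
#' formula `theta = acos((tr(R) - 1) / 2)` (argument clamped to [-1, 1]),
#' and the axis from the antisymmetric part of the rotation matrix, or --
#' for angles near 180 degrees, where the antisymmetric part cancels --
#' from the eigenvector of `R` with eigenvalue +1.  The screw translation
#' is the component of the translation along the axis.
#'
#' @param t a `rigid_transform` (or bare 3 x 3 rotation matrix).
#' @return List of class `rotation_decomposition`: `angle` (degrees, in
#'   [0, 180]), `axis` (unit 3-vector; NA with `axis_defined = FALSE` when
#'   the angle is below 1e-3 degrees), `screw_translation` (angstrom).
#' @export
rotation_angle <- function(t) {
  R <- if (is.matrix(t)) t else t$rotation
  tr <- sum(diag(R))
  cos_theta <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cos_theta) * 180 / pi
  axis <- c(NA_real_, NA_real_, NA_real_)
  axis_defined <- angle >= 1e-3
  if (axis_defined) {
    if (angle < 179) {
      v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      axis <- v / sqrt(sum(v^2))
    } else {
      ev <- eigen(R)
      k <- which.min(abs(ev$values - 1))
      axis <- Re(ev$vectors[, k])
      axis <- axis / sqrt(sum(axis^2))
      # orient consistently with the (possibly tiny) antisymmetric part
      v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      if (sum(v * axis) < 0) axis <- -axis
    }
  }
  screw <- if (axis_defined && !is.matrix(t) && !is.null(t$translation)) {
    sum(t$translation * axis)
  } else NA_real_
  structure(list(angle = angle, axis = axis, axis_defined = axis_defined,
                 screw_translation = screw),
            class = "rotation_decomposition")
}

#' Build a rotation matrix from axis and angle
#'
#' Rodrigues' formula; utility for constructing planted rotations.
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Fit the axis of an alpha-helix from C-alpha coordinates
#'
#' Cylinder fit: the helix axis is the line about which the C-alpha radial
#' distances are most nearly constant.  The dominant principal component
#' of the centered coordinates provides the starting direction, which is
#' then refined (together with the axis position) by minimizing the
#' variance of the point-to-axis distances.  Unlike the raw principal
#' component -- whose direction is biased by the incomplete final helix
#' turn -- the refined axis is exact for an ideal helix of any length.
#' The sign is fixed so the direction points from the N terminus toward
#' the C terminus (positive dot product with the last-minus-first
#' displacement).  Requires six or more residues.
#'
#' @param ca_coords ordered (N to C) n x 3 C-alpha matrix or
#'   `atom_selection`.
#' @param residue_range optional `c(start, end)` annotation.
#' @return List of class `helix_axis`: `direction` (unit 3-vector, N to C),
#'   `centroid`, `residue_range`, `n_atoms`.
#' @export
fit_helix_axis <- function(ca_coords, residue_range = NULL) {
  X <- as_coord_matrix(ca_coords)
  if (nrow(X) < 6L) stop("need >= 6 C-alpha positions to fit a helix axis")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  pc <- svd(Xc, nu = 0, nv = 1)
  v0 <- as.vector(pc$v[, 1L])
  # refine: axis direction (polar angles) and in-plane axis offset that
  # minimize the variance of radial distances
  radial_var <- function(p) {
    u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    D <- sweep(X, 2, ctr + p[3] * e1 + p[4] * e2)
    proj <- D - outer(as.vector(D %*% u), u)
    stats::var(sqrt(rowSums(proj^2)))
  }
  fit <- stats::optim(c(acos(max(-1, min(1, v0[3]))), atan2(v0[2], v0[1]),
                        0, 0),
                      radial_var, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  p <- fit$par
  dir <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
  disp <- X[nrow(X), ] - X[1L, ]
  if (sum(dir * disp) < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  structure(list(direction = dir, centroid = ctr,
                 residue_range = residue_range, n_atoms = nrow(X)),
            class = "helix_axis")
}

#' Angle between two helix axes
#'
#' Inter-axis (kink) angle in degrees, in [0, 180]; both axes must be N-to-C
#' oriented so that a straight continuous helix reads near zero and an
#' antiparallel helix-turn-helix reads near 180.
#'
#' @param a,b `helix_axis` objects (or bare unit 3-vectors).
#' @return Angle in degrees.
#' @export
kink_angle <- function(a, b) {
  va <- if (inherits(a, "helix_axis")) a$direction else a / sqrt(sum(a^2))
  vb <- if (inherits(b, "helix_axis")) b$direction else b / sqrt(sum(b^2))
  acos(max(-1, min(1, sum(va * vb)))) * 180 / pi
}

segment_kink <- function(model, seg1, seg2) {
  s1 <- select_atoms(model, seg1, "CA")
  s2 <- select_atoms(model, seg2, "CA")
  if (nrow(s1$coords) < 6L || nrow(s2$coords) < 6L) {
    stop("segment(s) unresolved in model '", model$label,
         "': need >= 6 C-alpha atoms per half (have ",
         nrow(s1$coords), " and ", nrow(s2$coords), ")")
  }
  kink_angle(fit_helix_axis(s1$coords), fit_helix_axis(s2$coords))
}

#' Hinge opening angle between two conformers
#'
#' Measures how far a broken (helix-turn-helix) hinge straightens between
#' conformations: the kink angle between the two helix-half axes in the
#' closed model minus the same kink angle in the open model.  For the DH
#' hinge helix the packaged split is at Ile237 (N-half up to 236, C-half
#' from 238; see [prex1_hinge_segments()]): the closed conformer's bent
#' hinge against the open conformer's continuous helix yields an opening
#' of about 126 degrees.
#'
#' @param closed,open `structure_model`s of the two conformers.
#' @param seg1,seg2 `domain_definition`s for the N-terminal and C-terminal
#'   helix halves (same numbering in both models).
#' @return Signed opening angle in degrees (positive when `closed` is more
#'   bent than `open`); per-model kink angles attached as attribute
#'   `"kinks"`.
#' @export
hinge_opening <- function(closed, open, seg1, seg2) {
  k_closed <- segment_kink(closed, seg1, seg2)
  k_open <- segment_kink(open, seg1, seg2)
  structure(k_closed - k_open,
            kinks = c(closed = k_closed, open = k_open))
}

common_ca <- function(model_a, model_b, domain) {
  sa <- select_atoms(model_a, domain, "CA")
  sb <- select_atoms(model_b, domain, "CA")
  key <- function(s) paste(s$refs$chain, s$refs$resno, s$refs$insert)
  ka <- key(sa); kb <- key(sb)
  common <- intersect(ka, kb)
  list(a = sa$coords[match(common, ka), , drop = FALSE],
       b = sb$coords[match(common, kb), , drop = FALSE],
       n = length(common))
}

#' Rigid-body rotation of a mobile domain between two conformers
#'
#' Superposes the two models on a fixed anchor domain (C-alpha atoms of
#' residues common to both), then decomposes the residual best-fit
#' transform of the mobile domain into an axis and angle.  This is the
#' standard two-step reading of a domain motion: e.g. anchoring on the PH
#' domain and measuring how far the DH domain flips away.
#'
#' @param model_a,model_b `structure_model`s of the two conformers.
#' @param anchor `domain_definition` held fixed.
#' @param mobile `domain_definition` whose rotation is measured.
#' @return A `rotation_decomposition` (see [rotation_angle()]) with the
#'   anchor-fit and mobile-fit RMSDs attached as attribute `"rmsd"`.
#' @export
domain_rotation <- function(model_a, model_b, anchor, mobile) {
  anc <- common_ca(model_a, model_b, anchor)
  mob <- common_ca(model_a, model_b, mobile)
  if (anc$n < 10L || mob$n < 10L) {
    stop("need >= 10 common C-alpha residues in anchor and mobile (have ",
         anc$n, " and ", mob$n, ")")
  }
  t_anchor <- kabsch_superpose(anc$a, anc$b)
  mob_b_fitted <- apply_transform(t_anchor, mob$b)
  # residual transform carrying conformer-a mobile onto conformer-b mobile
  t_mobile <- kabsch_superpose(mob_b_fitted, mob$a)
  dec <- rotation_angle(t_mobile)
  attr(dec, "rmsd") <- c(anchor = t_anchor$rmsd, mobile = t_mobile$rmsd)
  dec
}
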