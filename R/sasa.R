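#' Default van der Waals radii set
#'
#' Element-keyed radii in angstrom with the probe radius, following the
#' common NACCESS-like convention: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
#' probe 1.40.  Reported in every surface-area result so the convention is
#' explicit.
#'
#' @param probe_radius solvent probe radius in angstrom (default 1.40).
#' @param extra named numeric vector of additional element radii.
#' @return List of class `radii_set`: `radii` (named numeric),
#'   `probe_radius`, `default_radius` used for unlisted elements (NA means
#'   unlisted elements are an error).
#' @export
default_radii <- function(probe_radius = 1.40, extra = NULL) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  if (!is.null(extra)) radii[names(extra)] <- extra
  stopifnot(all(radii > 0), probe_radius >= 0)
  structure(list(radii = radii, probe_radius = probe_radius,
                 default_radius = NA_real_),
            class = "radii_set")
}

# deterministic quasi-uniform unit-sphere points (golden-section spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atoms_for_sasa <- function(x, exclude_hydrogen = TRUE, exclude_water = TRUE) {
  at <- if (inherits(x, "structure_model")) x$atoms else as.data.frame(x)
  if (exclude_water) at <- at[!(at$resid %in% WATER_NAMES), , drop = FALSE]
  if (exclude_hydrogen) at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  collapse_altloc(at)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, places `n_points` quasi-uniform points on a sphere of
#' radius (vdW radius + probe radius) and counts the fraction not buried
#' inside any neighboring atom's expanded sphere; the accessible area is
#' that fraction times the expanded-sphere area `4*pi*(r + probe)^2`.
#' Hydrogens and waters are excluded by default.
#'
#' @param x a `structure_model` or atom data.frame (columns `elesy`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`).
#' @param radii a `radii_set` (default [default_radii()]).
#' @param n_points test points per atom (default 960).
#' @param exclude_hydrogen,exclude_water filters applied before the
#'   calculation.
#' @return List of class `sasa_result`: `atom_area` (per atom, angstrom^2),
#'   `atoms` (the atom table used), `residue_area` (per-residue sums with
#'   chain/resno/insert/resid), `total`, `n_sphere_points`, `radii`.
#' @export
sasa <- function(x, radii = default_radii(), n_points = 960L,
                 exclude_hydrogen = TRUE, exclude_water = TRUE) {
  at <- atoms_for_sasa(x, exclude_hydrogen, exclude_water)
  if (nrow(at) == 0L) stop("no atoms to compute surface for")
  el <- toupper(at$elesy)
  r <- unname(radii$radii[el])
  if (anyNA(r)) {
    if (is.na(radii$default_radius)) {
      bad <- unique(el[is.na(r)])
      stop("no radius for element(s): ", paste(bad, collapse = ", "))
    }
    r[is.na(r)] <- radii$default_radius
  }
  R <- r + radii$probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbor cutoff: spheres can only intersect within R_i + R_j
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)   # n_points x 3 on sphere i
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(p[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      exposed[exposed] <- dj2 >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  res_key <- residue_keys(at)
  res_area <- tapply(area, res_key, sum)
  first <- !duplicated(res_key)
  residue_area <- data.frame(at[first, c("chain", "resno", "insert", "resid")],
                             area = as.numeric(res_area[res_key[first]]),
                             stringsAsFactors = FALSE)
  structure(list(atom_area = area, atoms = at, residue_area = residue_area,
                 total = sum(area), n_sphere_points = n_points,
                 radii = radii),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              length(x$atom_area), x$total, x$radii$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

domain_atoms <- function(model, domain, exclude_hydrogen = TRUE,
                         exclude_water = TRUE) {
  at <- atoms_for_sasa(model, exclude_hydrogen, exclude_water)
  at[in_domain(at$resno, at$chain, domain), , drop = FALSE]
}

#' Buried surface area of residues across an interface
#'
#' For each listed residue, the buried surface area (BSA) is its
#' solvent-accessible area computed within its own component alone, minus
#' its accessible area within the union of both components; the combined
#' BSA is the sum over listed residues.  Used e.g. to quantify how much
#' surface the DH-domain latch residues Leu177/Leu178 (and, on the other
#' side, linker residues Met401/Met408) bury against the opposing
#' component.
#'
#' @param model a `structure_model`.
#' @param comp_a,comp_b disjoint `domain_definition`s for the two
#'   components.
#' @param residues data.frame with columns `chain` and `resno` (optional
#'   `insert`) naming the residues to report.
#' @param radii,n_points passed to [sasa()].
#' @return List of class `bsa_result`: `per_residue` (data.frame with
#'   isolated-component area, complex area and `bsa`), `combined`
#'   (angstrom^2), plus the parameters used.
#' @export
buried_area <- function(model, comp_a, comp_b, residues,
                        radii = default_radii(), n_points = 960L) {
  at_a <- domain_atoms(model, comp_a)
  at_b <- domain_atoms(model, comp_b)
  if (nrow(at_a) == 0L || nrow(at_b) == 0L) stop("empty component selection")
  key_a <- unique(residue_keys(at_a)); key_b <- unique(residue_keys(at_b))
  if (length(intersect(key_a, key_b)) > 0L) {
    stop("components overlap: ",
         paste(head(intersect(key_a, key_b)), collapse = ", "))
  }
  if (is.null(residues$insert)) residues$insert <- ""
  rkeys <- paste(residues$chain, residues$resno, residues$insert, sep = "|")
  comp_of <- ifelse(rkeys %in% key_a, "a", ifelse(rkeys %in% key_b, "b", NA))
  if (anyNA(comp_of)) {
    stop("residue(s) outside both components: ",
         paste(rkeys[is.na(comp_of)], collapse = ", "))
  }
  s_a <- sasa(at_a, radii, n_points)
  s_b <- sasa(at_b, radii, n_points)
  s_ab <- sasa(rbind(at_a, at_b), radii, n_points)
  res_lookup <- function(s, key) {
    keys <- paste(s$residue_area$chain, s$residue_area$resno,
                  s$residue_area$insert, sep = "|")
    out <- s$residue_area$area[match(key, keys)]
    ifelse(is.na(out), 0, out)
  }
  alone <- ifelse(comp_of == "a", res_lookup(s_a, rkeys),
                  res_lookup(s_b, rkeys))
  complexed <- res_lookup(s_ab, rkeys)
  per <- data.frame(residues[, c("chain", "resno", "insert")],
                    component = comp_of, sasa_alone = alone,
                    sasa_complex = complexed,
                    bsa = pmax(alone - complexed, 0),
                    stringsAsFactors = FALSE)
  structure(list(per_residue = per, combined = sum(per$bsa),
                 n_sphere_points = n_points, radii = radii,
                 comp_a = comp_a$name, comp_b = comp_b$name),
            class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("<bsa_result> %s vs %s: combined BSA %.1f A^2 over %d residue(s)\n",
              x$comp_a, x$comp_b, x$combined, nrow(x$per_residue)))
  print(x$per_residue, row.names = FALSE)
  invisible(x)
}

#' Geometric hydrogen-bond detection
#'
#' Reports donor/acceptor heavy-atom pairs within a distance cutoff
#' (default 3.5 angstrom), excluding pairs within the same residue.  When
#' explicit hydrogens are present and `require_angle = TRUE`, a
#' donor-hydrogen-acceptor angle of at least `min_angle` degrees is
#' additionally required (the hydrogen bonded to the donor is taken as any
#' H atom within 1.3 angstrom of it).
#'
#' @param model a `structure_model`.
#' @param donors,acceptors data.frames selecting heavy atoms, columns
#'   `chain`, `resno`, `elety` (optional `insert`).
#' @param d_max donor-acceptor heavy-atom distance cutoff, angstrom.
#' @param require_angle require the D-H...A angle test.
#' @param min_angle minimum D-H...A angle in degrees (default 120).
#' @return data.frame with one row per detected bond: donor and acceptor
#'   identities, `distance` and `angle` (NA unless computed).
#' @export
hydrogen_bonds <- function(model, donors, acceptors, d_max = 3.5,
                           require_angle = FALSE, min_angle = 120) {
  pick <- function(selspec) {
    if (nrow(selspec) == 0L) return(model$atoms[0, , drop = FALSE])
    if (is.null(selspec$insert)) selspec$insert <- ""
    at <- model$atoms
    idx <- integer(0)
    for (i in seq_len(nrow(selspec))) {
      idx <- c(idx, which(at$chain == selspec$chain[i] &
                            at$resno == selspec$resno[i] &
                            at$insert == selspec$insert[i] &
                            at$elety == selspec$elety[i]))
    }
    collapse_altloc(at[idx, , drop = FALSE])
  }
  don <- pick(donors); acc <- pick(acceptors)
  if (nrow(don) == 0L || nrow(acc) == 0L) {
    stop("empty donor or acceptor selection")
  }
  hyd <- model$atoms[model$atoms$elesy %in% c("H", "D"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(don))) {
    for (j in seq_len(nrow(acc))) {
      same_res <- don$chain[i] == acc$chain[j] &&
        don$resno[i] == acc$resno[j] && don$insert[i] == acc$insert[j]
      if (same_res) next
      d <- sqrt(sum((c(don$x[i], don$y[i], don$z[i]) -
                       c(acc$x[j], acc$y[j], acc$z[j]))^2))
      if (d > d_max) next
      ang <- NA_real_
      if (require_angle && nrow(hyd) > 0L) {
        dh <- sqrt((hyd$x - don$x[i])^2 + (hyd$y - don$y[i])^2 +
                     (hyd$z - don$z[i])^2)
        hs <- which(dh < 1.3)
        if (length(hs) > 0L) {
          angs <- vapply(hs, function(h) {
            v1 <- c(don$x[i] - hyd$x[h], don$y[i] - hyd$y[h],
                    don$z[i] - hyd$z[h])
            v2 <- c(acc$x[j] - hyd$x[h], acc$y[j] - hyd$y[h],
                    acc$z[j] - hyd$z[h])
            acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          }, numeric(1))
          ang <- max(angs)
          if (ang < min_angle) next
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = don$chain[i], donor_resno = don$resno[i],
        donor_resid = don$resid[i], donor_atom = don$elety[i],
        acceptor_chain = acc$chain[j], acceptor_resno = acc$resno[j],
        acceptor_resid = acc$resid[j], acceptor_atom = acc$elety[j],
        distance = d, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resid = character(0),
                      acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0)))
  }
  do.call(rbind, out)
}
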