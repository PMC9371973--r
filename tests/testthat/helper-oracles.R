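# Independent oracles used to check package computations.

# rotation angle via quaternion magnitudes (atan2 form, stable near 0/180)
quat_angle_deg <- function(R) {
  tr <- sum(diag(R))
  2 * atan2(sqrt(max(0, 3 - tr)), sqrt(max(0, 1 + tr))) * 180 / pi
}

# brute-force frequency-weighted model FDR: plain loop over links
brute_force_fdr <- function(status, counts) {
  num <- 0; den <- 0
  for (i in seq_along(status)) {
    if (status[i] == "unmapped") next
    den <- den + counts[i]
    if (status[i] == "violated") num <- num + counts[i]
  }
  num / den
}

# exposed area of sphere 1 (radius r1) overlapped by sphere 2 (radius r2)
# at center distance d: full sphere minus the buried spherical cap
cap_exposed_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- r1 - a
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small hand-built model: n residues with one CA each along x, 3.8 A apart
toy_ca_model <- function(n = 10, chain = "A", resnos = seq_len(n)) {
  structure_model(data.frame(
    elety = "CA", resid = "ALA", chain = chain, resno = resnos,
    x = 3.8 * seq_along(resnos), y = 0, z = 0, elesy = "C",
    stringsAsFactors = FALSE), label = "toy")
}

# two lysine CB atoms a given distance apart (plus CA so residues are valid)
two_lys_model <- function(distance, resnos = c(100L, 250L)) {
  structure_model(data.frame(
    elety = rep(c("CA", "CB"), 2),
    resid = "LYS", chain = "A", resno = rep(resnos, each = 2),
    x = c(0, 0, 0, distance), y = c(1, 0, 1, 0), z = 0,
    elesy = "C", stringsAsFactors = FALSE), label = "two_lys")
}

xl_row <- function(pos_a, pos_b, count = 1L, e_value = 1e-6,
                   n_repeats = 2L, res_a = "K", res_b = "K") {
  data.frame(pos_a = pos_a, pos_b = pos_b, res_a = res_a, res_b = res_b,
             spectral_count = count, e_value = e_value,
             n_repeats = n_repeats, sample_label = "t",
             stringsAsFactors = FALSE)
}

withr_tempfile <- function(ext = ".pdb") tempfile(fileext = ext)
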