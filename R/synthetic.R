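#' Build an ideal (optionally kinked) alpha-helix model
#'
#' Generates a poly-alanine-like C-alpha/C-beta trace of an ideal
#' alpha-helix: rise 1.5 angstrom per residue, 100 degree twist, 2.3
#' angstrom radius, built along +z starting at the origin.  C-beta atoms
#' are placed 1.53 angstrom from each C-alpha along the outward radial
#' direction tilted toward the ideal tetrahedral geometry -- sufficient
#' for C-beta distance restraints and axis fitting, with no side-chain
#' chemistry.  An optional kink rigidly rotates the C-terminal segment
#' about an axis through the split residue's C-alpha, perpendicular to
#' the helix axis, by the requested angle.
#'
#' @param n_res number of residues.
#' @param rise,twist_deg,radius helix parameters (angstrom, degrees,
#'   angstrom).
#' @param kink_deg kink angle in degrees (0 = straight).
#' @param kink_pos residue at which the helix breaks (the C-terminal
#'   segment starts at `kink_pos + 1`); required when `kink_deg != 0`.
#' @param noise_sd isotropic Gaussian coordinate noise, angstrom.
#' @param seed RNG seed used when `noise_sd > 0` (local to this call).
#' @param chain,res_name chain id and 3-letter residue name (use `"LYS"`
#'   for crosslink fixtures).
#' @param label model label.
#' @return A `structure_model` with CA and CB atoms per residue.
#' @export
make_helix <- function(n_res, rise = 1.5, twist_deg = 100, radius = 2.3,
                       kink_deg = 0, kink_pos = NULL, noise_sd = 0,
                       seed = 1L, chain = "A", res_name = "ALA",
                       label = "helix") {
  stopifnot(n_res >= 2)
  i <- seq_len(n_res)
  th <- (i - 1) * twist_deg * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), (i - 1) * rise)
  # radial-outward CB, tilted along -z by half the tetrahedral angle
  out_dir <- cbind(cos(th), sin(th), 0)
  tilt <- 54.75 * pi / 180
  cb_dir <- out_dir * cos(tilt)
  cb_dir[, 3] <- -sin(tilt)
  cb <- ca + 1.53 * cb_dir
  if (kink_deg != 0) {
    if (is.null(kink_pos) || kink_pos < 1 || kink_pos > n_res) {
      stop("kink_pos must name a residue inside the chain")
    }
    pivot <- ca[kink_pos, ]
    R <- rotation_matrix(c(1, 0, 0), kink_deg)
    rot <- function(x) sweep(sweep(x, 2, pivot) %*% t(R), 2, pivot, `+`)
    idx <- i > kink_pos
    ca[idx, ] <- rot(ca[idx, , drop = FALSE])
    cb[idx, ] <- rot(cb[idx, , drop = FALSE])
  }
  if (noise_sd > 0) {
    withr_seed(seed, {
      ca <- ca + matrix(stats::rnorm(3 * n_res, sd = noise_sd), ncol = 3)
      cb <- cb + matrix(stats::rnorm(3 * n_res, sd = noise_sd), ncol = 3)
    })
  }
  atoms <- data.frame(
    elety = rep(c("CA", "CB"), n_res),
    resid = res_name, chain = chain,
    resno = rep(i, each = 2L),
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    elesy = "C", stringsAsFactors = FALSE
  )
  structure_model(atoms, label = label, source = "synthetic")
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# compact pseudo-globular domain: residues wound onto three parallel
# helical segments offset in the xy plane, so the domain has comparable
# extent along all axes (a bare single helix is nearly degenerate about
# its own axis and is a poor stand-in for a rigid domain)
make_bundle <- function(n_res, chain, label) {
  m <- ceiling(n_res / 3)
  seg <- (seq_len(n_res) - 1L) %/% m
  j <- (seq_len(n_res) - 1L) %% m
  offs <- rbind(c(0, 0), c(7, 0), c(3.5, 6))
  th <- j * 100 * pi / 180
  ca <- cbind(offs[seg + 1L, 1L] + 2.3 * cos(th),
              offs[seg + 1L, 2L] + 2.3 * sin(th),
              j * 1.5)
  out_dir <- cbind(cos(th), sin(th), 0)
  tilt <- 54.75 * pi / 180
  cb_dir <- out_dir * cos(tilt); cb_dir[, 3] <- -sin(tilt)
  cb <- ca + 1.53 * cb_dir
  atoms <- data.frame(
    elety = rep(c("CA", "CB"), n_res), resid = "ALA", chain = chain,
    resno = rep(seq_len(n_res), each = 2L),
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    elesy = "C", stringsAsFactors = FALSE)
  structure_model(atoms, label = label, source = "synthetic")
}

#' Build a two-domain toy system with a planted rigid motion
#'
#' Two compact helical-bundle domains on separate chains; in the second
#' conformer, domain B is rotated by a planted angle about a given axis
#' through its centroid (plus an optional translation) while domain A
#' stays fixed.  The planted transform is returned alongside the models so
#' recovery can be checked.
#'
#' @param n_res residues per domain.
#' @param angle_deg planted rotation of domain B.
#' @param axis rotation axis (3-vector).
#' @param translation translation of domain B after rotation, angstrom.
#' @param separation offset of domain B from domain A along x, angstrom.
#' @param noise_sd coordinate noise added independently to both conformers.
#' @param seed RNG seed for the noise.
#' @return List: `conformer1`, `conformer2` (`structure_model`s with
#'   chains A and B), `domain_a`, `domain_b` (`domain_definition`s),
#'   `planted` (list with `angle`, `axis`, `translation`).
#' @export
make_two_domain <- function(n_res = 50L, angle_deg = 45,
                            axis = c(0, 0, 1), translation = c(0, 0, 0),
                            separation = 25, noise_sd = 0, seed = 1L) {
  dom_a <- make_bundle(n_res, chain = "A", label = "domA")
  dom_b0 <- make_bundle(n_res, chain = "B", label = "domB")
  dom_b0$atoms[, c("x")] <- dom_b0$atoms[, c("x")] + separation
  bind_models <- function(a, b, label) {
    structure_model(rbind(a$atoms, b$atoms), label = label,
                    source = "synthetic")
  }
  conf1 <- bind_models(dom_a, dom_b0, "conformer1")
  dom_b1 <- dom_b0
  xyz <- as.matrix(dom_b1$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  R <- rotation_matrix(axis, angle_deg)
  xyz2 <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + translation, `+`)
  dom_b1$atoms[, c("x", "y", "z")] <- xyz2
  conf2 <- bind_models(dom_a, dom_b1, "conformer2")
  if (noise_sd > 0) {
    withr_seed(seed, {
      for (nm in c("conf1", "conf2")) {
        m <- get(nm)
        m$atoms[, c("x", "y", "z")] <-
          as.matrix(m$atoms[, c("x", "y", "z")]) +
          matrix(stats::rnorm(3 * nrow(m$atoms), sd = noise_sd), ncol = 3)
        assign(nm, m)
      }
    })
  }
  list(conformer1 = conf1, conformer2 = conf2,
       domain_a = domain_definition("domA", "A", c(1, n_res)),
       domain_b = domain_definition("domB", "B", c(1, n_res)),
       planted = list(angle = angle_deg,
                      axis = axis / sqrt(sum(axis^2)),
                      translation = translation))
}

#' Simulate a crosslink identification table with planted violations
#'
#' Samples lysine-pair crosslinks on a model so that a chosen
#' frequency-weighted fraction of the observed spectra is geometrically
#' violated (C-beta distance at or beyond the cutoff).  Residue pairs are
#' drawn from the model's satisfied (< cutoff) and violated pools;
#' spectral counts are drawn from a geometric-plus-one distribution
#' unless `equal_counts = TRUE`, in which case every link has count 1 and
#' the planted link fraction equals the planted frequency fraction
#' exactly.  The realized frequency-weighted violated fraction is
#' attached as attribute `"planted_fdr"`.
#'
#' @param model a `structure_model` whose lysine (or surrogate) residues
#'   carry CB atoms.
#' @param n_links number of unique residue-pair links.
#' @param violated_fraction target fraction of links drawn from the
#'   violated pool (exact count: `round(violated_fraction * n_links)`).
#' @param cutoff compatible span, angstrom (default 30).
#' @param equal_counts give every link spectral count 1.
#' @param count_mean mean spectral count when counts are drawn.
#' @param e_value,n_repeats values written into every row (passing the
#'   default identification filters).
#' @param seed RNG seed (sampling is local to this call).
#' @return data.frame in the package's canonical crosslink CSV dialect
#'   (`pos_a`, `pos_b`, `res_a`, `res_b`, `spectral_count`, `e_value`,
#'   `n_repeats`, `sample_label`), with attributes `planted_fdr` and
#'   `planted_status`.
#' @export
simulate_crosslinks <- function(model, n_links = 20L,
                                violated_fraction = 0.25, cutoff = 30,
                                equal_counts = FALSE, count_mean = 4,
                                e_value = 1e-6, n_repeats = 2L,
                                seed = 1L) {
  stopifnot(violated_fraction >= 0, violated_fraction <= 1)
  at <- model$atoms
  cb <- at[at$elety == "CB", , drop = FALSE]
  if (nrow(cb) < 4L) stop("model must carry CB atoms on >= 4 residues")
  xyz <- as.matrix(cb[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[pairs]
  sat_pool <- which(d < cutoff)
  vio_pool <- which(d >= cutoff)
  n_vio <- round(violated_fraction * n_links)
  n_sat <- n_links - n_vio
  if (length(sat_pool) < n_sat || length(vio_pool) < n_vio) {
    stop("model geometry cannot supply ", n_sat, " satisfied and ", n_vio,
         " violated pairs at cutoff ", cutoff)
  }
  withr_seed(seed, {
    take_sat <- sample(sat_pool, n_sat)
    take_vio <- sample(vio_pool, n_vio)
    idx <- c(take_sat, take_vio)
    counts <- if (equal_counts) rep(1L, n_links)
              else 1L + stats::rgeom(n_links, 1 / count_mean)
  })
  status <- c(rep("satisfied", n_sat), rep("violated", n_vio))
  tab <- data.frame(
    pos_a = cb$resno[pairs[idx, 1L]], pos_b = cb$resno[pairs[idx, 2L]],
    res_a = "K", res_b = "K", spectral_count = counts,
    e_value = e_value, n_repeats = n_repeats,
    sample_label = "synthetic", stringsAsFactors = FALSE
  )
  ord <- order(tab$pos_a, tab$pos_b)
  tab <- tab[ord, ]; status <- status[ord]
  rownames(tab) <- NULL
  attr(tab, "planted_fdr") <-
    sum(tab$spectral_count[status == "violated"]) / sum(tab$spectral_count)
  attr(tab, "planted_status") <- status
  tab
}

#' Simulate mant-GDP exchange time courses
#'
#' Emulates the plate-reader assay design: a pre-addition baseline of
#' `baseline_cycles` cycles followed by `n_cycles` measurement cycles at a
#' fixed `interval` (default 32 s), with the exchange reaction following a
#' one-phase association from `y0` toward `plateau` at rate `k_per_min`
#' and the buffer control staying flat.  Each sample trace is the mean of
#' `n_duplicates` wells carrying independent Gaussian noise of standard
#' deviation `sigma` (on the normalized scale), mirroring the usual
#' duplicate-well plate layout; the control is generated noise-free by
#' default -- it stands for an averaged buffer reference -- with
#' `control_sigma` available to make it noisy.  Raw traces are scaled to
#' a plate-reader-like fluorescence level.
#'
#' @param k_per_min true exchange rate constant, per minute.
#' @param sigma relative Gaussian noise s.d. of a single well.
#' @param n_duplicates wells per sample averaged into each returned trace
#'   (default 2, the usual duplicate-well design; trace noise is
#'   `sigma / sqrt(n_duplicates)`).
#' @param control_sigma relative noise s.d. of the buffer control
#'   (default 0).
#' @param n_cycles post-addition cycles (default 240).
#' @param interval cycle time in seconds (default 32).
#' @param baseline_cycles pre-addition cycles (default 10).
#' @param y0,plateau normalized start and end levels of the sample trace.
#' @param f0 raw baseline fluorescence level, arbitrary units.
#' @param n_replicates replicate traces to generate.
#' @param label sample label.
#' @param seed RNG seed (local).
#' @return List: `samples` (list of raw `time_course`), `control` (buffer
#'   `time_course`), and `truth` (list echoing the planted parameters).
#' @export
simulate_exchange <- function(k_per_min = 0.5, sigma = 0.01,
                              n_duplicates = 2L, control_sigma = 0,
                              n_cycles = 240L, interval = 32,
                              baseline_cycles = 10L, y0 = 1,
                              plateau = 0.4, f0 = 1000,
                              n_replicates = 1L, label = "variant",
                              seed = 1L) {
  n_tot <- baseline_cycles + n_cycles
  times <- seq_len(n_tot) * interval
  t_post_min <- (seq_len(n_cycles) * interval) / 60
  clean <- c(rep(y0, baseline_cycles),
             y0 + (plateau - y0) * (1 - exp(-k_per_min * t_post_min)))
  withr_seed(seed, {
    samples <- lapply(seq_len(n_replicates), function(r) {
      wells <- vapply(seq_len(n_duplicates), function(w)
        clean + stats::rnorm(n_tot, sd = sigma), numeric(n_tot))
      time_course(times, f0 * rowMeans(wells), label = label,
                  replicate = r)
    })
    control <- time_course(times,
                           f0 * (1 + stats::rnorm(n_tot, sd = control_sigma)),
                           label = "buffer", replicate = 1L)
  })
  list(samples = samples, control = control,
       truth = list(k_per_min = k_per_min, sigma = sigma, y0 = y0,
                    plateau = plateau, interval = interval,
                    baseline_cycles = baseline_cycles, rng = "Mersenne-Twister"))
}
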