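#' Build a construct-to-full-length numbering map
#'
#' Engineered constructs (N-terminal truncations, internal deletions,
#' foreign inserts such as a T4 lysozyme fusion) renumber residues relative
#' to the wild-type full-length sequence.  A `numbering_map` records, for
#' each interval of construct positions, either the constant offset to
#' full-length numbering or a flag that the interval is a foreign insert
#' with no full-length equivalent.
#'
#' @param segments data.frame with columns `cstart`, `cend` (inclusive
#'   construct-position interval), `offset` (full-length = construct +
#'   offset; ignored for inserts) and `insert` (logical).
#' @param label map name.
#' @return A `numbering_map`.
#' @export
numbering_map <- function(segments, label = "map") {
  segments <- segments[order(segments$cstart), , drop = FALSE]
  stopifnot(all(segments$cstart <= segments$cend))
  if (nrow(segments) > 1L &&
      any(segments$cstart[-1] <= segments$cend[-nrow(segments)])) {
    stop("numbering map intervals overlap")
  }
  # injectivity on non-insert positions: full-length images must not overlap
  ni <- segments[!segments$insert, , drop = FALSE]
  if (nrow(ni) > 1L) {
    img <- data.frame(s = ni$cstart + ni$offset, e = ni$cend + ni$offset)
    img <- img[order(img$s), ]
    if (any(img$s[-1] <= img$e[-nrow(img)])) {
      stop("numbering map is not injective: full-length images overlap")
    }
  }
  structure(list(segments = segments, label = label), class = "numbering_map")
}

#' Identity numbering map
#' @param length construct length (default covers any reasonable protein).
#' @rdname numbering_map
#' @export
identity_numbering <- function(length = 100000L) {
  numbering_map(data.frame(cstart = 1L, cend = as.integer(length),
                           offset = 0L, insert = FALSE),
                label = "identity")
}

#' Map construct positions to full-length numbering
#'
#' @param nm a `numbering_map`.
#' @param construct_pos integer vector of construct positions (1-based).
#' @return Integer vector of full-length positions; `NA` where the position
#'   falls inside a foreign insert (see the `"insert"` attribute, a logical
#'   vector).  Positions outside the construct raise an error.
#' @export
map_position <- function(nm, construct_pos) {
  construct_pos <- as.integer(construct_pos)
  if (any(construct_pos < 1L)) stop("construct positions must be >= 1")
  seg <- nm$segments
  out <- rep(NA_integer_, length(construct_pos))
  ins <- rep(FALSE, length(construct_pos))
  covered <- rep(FALSE, length(construct_pos))
  for (i in seq_len(nrow(seg))) {
    hit <- construct_pos >= seg$cstart[i] & construct_pos <= seg$cend[i]
    covered <- covered | hit
    if (seg$insert[i]) ins[hit] <- TRUE
    else out[hit] <- construct_pos[hit] + seg$offset[i]
  }
  if (any(!covered)) {
    stop("position(s) beyond construct: ",
         paste(construct_pos[!covered], collapse = ", "))
  }
  attr(out, "insert") <- ins
  out
}

#' Map full-length positions back to construct numbering
#'
#' Inverse of [map_position()] on its range: full-length positions with no
#' construct equivalent (deleted or never-present regions) return `NA`.
#'
#' @param nm a `numbering_map`.
#' @param full_pos integer vector of full-length positions.
#' @return Integer vector of construct positions, `NA` where unrepresented.
#' @export
invert_position <- function(nm, full_pos) {
  full_pos <- as.integer(full_pos)
  seg <- nm$segments[!nm$segments$insert, , drop = FALSE]
  out <- rep(NA_integer_, length(full_pos))
  for (i in seq_len(nrow(seg))) {
    fs <- seg$cstart[i] + seg$offset[i]
    fe <- seg$cend[i] + seg$offset[i]
    hit <- !is.na(full_pos) & full_pos >= fs & full_pos <= fe
    out[hit] <- full_pos[hit] - seg$offset[i]
  }
  out
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf("<numbering_map> '%s' (%d segments)\n", x$label,
              nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Packaged P-Rex1 numbering maps
#'
#' Construct-to-full-length maps for the engineered P-Rex1 constructs used
#' in the autoinhibition structures: the N-terminal 40-residue truncation
#' (construct position 1 = full-length 41), the T4 lysozyme insertion that
#' replaces PH-domain loop residues 306-322 with 160 foreign residues (T4L
#' residues 2-161), and the 93-residue deletion of the IP4P intrinsically
#' disordered loop (full-length 1119-1211; construct position 1119 maps to
#' full-length 1212).  `"cryoem_construct"` combines all three, matching
#' the full-length cryo-EM construct.  Deposited models typically keep
#' full-length author numbering, in which case `"identity"` applies; maps
#' should be verified against residue names with [verify_numbering()]
#' rather than assumed.
#'
#' @param which map name: `"identity"`, `"dn40"`, `"d1119_1211"`,
#'   `"dn40_t4l"`, or `"cryoem_construct"`.
#' @return A `numbering_map`.
#' @export
prex1_numbering <- function(which = c("identity", "dn40", "d1119_1211",
                                      "dn40_t4l", "cryoem_construct")) {
  which <- match.arg(which)
  fl_len <- 1659L
  t4l_len <- 160L  # T4L residues 2-161
  switch(which,
    identity = identity_numbering(fl_len),
    dn40 = numbering_map(data.frame(
      cstart = 1L, cend = fl_len - 40L, offset = 40L, insert = FALSE),
      label = "dn40"),
    d1119_1211 = numbering_map(data.frame(
      cstart = c(1L, 1119L), cend = c(1118L, fl_len - 93L),
      offset = c(0L, 93L), insert = c(FALSE, FALSE)),
      label = "d1119_1211"),
    dn40_t4l = numbering_map(data.frame(
      # full-length 41-305 | T4L | full-length 323-502
      cstart = c(1L, 266L, 266L + t4l_len),
      cend = c(265L, 265L + t4l_len, 265L + t4l_len + 180L),
      offset = c(40L, 0L, 323L - (266L + t4l_len)), insert = c(FALSE, TRUE, FALSE)),
      label = "dn40_t4l"),
    cryoem_construct = numbering_map(data.frame(
      # full-length 41-305 | T4L | 323-1118 | 1212-1659
      cstart = c(1L, 266L, 426L, 1222L),
      cend = c(265L, 425L, 1221L, 1669L),
      offset = c(40L, 0L, -103L, -10L), insert = c(FALSE, TRUE, FALSE, FALSE)),
      label = "cryoem_construct")
  )
}

#' Verify a numbering map against a reference sequence
#'
#' Checks that residue names in a model, translated to full-length
#' numbering, agree with a reference full-length sequence (1-letter codes).
#'
#' @param model a `structure_model` in construct numbering.
#' @param nm a `numbering_map` (construct to full-length).
#' @param ref_seq character vector of 1-letter codes indexed by full-length
#'   position.
#' @param chain chain to check.
#' @return data.frame of mismatches (zero rows when the map verifies).
#' @export
verify_numbering <- function(model, nm, ref_seq, chain) {
  at <- model$atoms
  ca <- at[at$elety == "CA" & at$chain == chain, , drop = FALSE]
  fl <- map_position(nm, ca$resno)
  ins <- attr(fl, "insert")
  keep <- !ins & !is.na(fl) & fl <= length(ref_seq)
  obs <- bio3d::aa321(ca$resid[keep])
  exp <- ref_seq[fl[keep]]
  bad <- which(obs != exp & !is.na(exp))
  data.frame(construct_pos = ca$resno[keep][bad], full_pos = fl[keep][bad],
             model_res = obs[bad], ref_res = exp[bad])
}

#' Packaged P-Rex1 domain definitions
#'
#' Approximate author-numbering boundaries for the P-Rex1 domain layout
#' (DH, PH, PH-DEP1 linker helix, DEP1, DEP2, PDZ1, PDZ2, 4HB/IP4P) on a
#' given chain.  Boundaries are working presets for selections and
#' interface components and are user-adjustable; they are not deposited
#' annotations.
#'
#' @param chain chain id (default `"A"`).
#' @return Named list of `domain_definition`s.
#' @export
prex1_domains <- function(chain = "A") {
  mk <- function(name, s, e) domain_definition(name, chain, c(s, e))
  list(
    DH = mk("DH", 41, 252),
    PH = mk("PH", 263, 396),
    PH_DEP1_linker = mk("PH_DEP1_linker", 397, 420),
    DEP1 = mk("DEP1", 421, 502),
    DEP2 = mk("DEP2", 506, 594),
    PDZ1 = mk("PDZ1", 603, 682),
    PDZ2 = mk("PDZ2", 694, 773),
    IP4P = mk("IP4P", 790, 1659)
  )
}

#' Default hinge-helix segment bounds
#'
#' The final DH-domain helix (alpha-6) is broken at Ile237 in the closed
#' conformation; the packaged split uses an N-half ending at 236 and a
#' C-half starting at 238.  Exact helix termini are adjustable because they
#' are not fixed by the deposition.
#'
#' @param chain chain id.
#' @param n_half,c_half inclusive residue intervals for the two helix halves.
#' @return List with `domain_definition`s `seg1` (N-half) and `seg2` (C-half).
#' @export
prex1_hinge_segments <- function(chain = "A", n_half = c(225, 236),
                                 c_half = c(238, 249)) {
  list(seg1 = domain_definition("alpha6_N_half", chain, n_half),
       seg2 = domain_definition("alpha6_C_half", chain, c_half))
}

#' DEP1-latch interface components
#'
#' Component split used for buried-surface-area analysis of the DEP1 latch:
#' component A is the DH domain; component B is the PH-DEP1 linker helix
#' plus the DEP1 domain.
#'
#' @param chain chain id.
#' @return List with `comp_a` and `comp_b` `domain_definition`s.
#' @export
prex1_dep1_latch <- function(chain = "A") {
  list(comp_a = domain_definition("DH", chain, c(41, 252)),
       comp_b = domain_definition("linker_DEP1", chain, c(397, 502)))
}
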