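#' @importFrom stats sd setNames aggregate prcomp coef resid
#' @importFrom utils read.csv write.csv head tail
NULL

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a structure model from an atom table
#'
#' A `structure_model` is the package's container for an atomic model: a
#' flat atom table in author numbering plus a label and source path.  It is
#' deliberately light -- one data.frame with one row per atom -- so that
#' selections, distance measurements and surface calculations are plain
#' matrix operations.
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain`, `resno` (author residue number),
#'   `insert` (insertion code, `""` if none), `x`, `y`, `z` (angstrom),
#'   and optionally `alt` (alternate-location id), `o` (occupancy), `b`
#'   (B-factor), `elesy` (element symbol) and `type` (`"ATOM"`/`"HETATM"`).
#'   Missing optional columns are filled with defaults.
#' @param label character model label used in reports.
#' @param source path or description of where the model came from.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "model", source = NA_character_) {
  required <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("no atoms: model is empty")
  defaults <- list(insert = "", alt = "", o = 1, b = 0, type = "ATOM",
                   elesy = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(atoms$o < 0 | atoms$o > 1)) {
    stop("occupancies must lie in [0, 1]")
  }
  # infer element from atom name where the file carried none
  no_el <- is.na(atoms$elesy) | atoms$elesy == ""
  if (any(no_el)) atoms$elesy[no_el] <- guess_element(atoms$elety[no_el])
  structure(list(atoms = atoms, label = label, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  keys <- residue_keys(x$atoms)
  cat(sprintf("<structure_model> '%s': %d atoms, %d residues, chains: %s\n",
              x$label, nrow(x$atoms), length(unique(keys)),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

guess_element <- function(atom_names) {
  nm <- gsub("[^A-Za-z]", "", atom_names)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "CA") &
           nchar(atom_names) == 2 & atom_names == two,
         two, one)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses a coordinate file and returns a [structure_model()] in author
#' numbering.  Multi-model (NMR-style) files are reduced to model 1 with a
#' warning.  All atoms -- hydrogens, waters, heteroatoms, alternate
#' locations -- are retained here; downstream geometry excludes waters and
#' hydrogens by default and collapses alt-locs to the highest-occupancy
#' conformer.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (default; by extension).
#' @param label model label; defaults to the file name without extension.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in ", path)
  if (!is.null(parsed$xyz) && is.matrix(parsed$xyz) && nrow(parsed$xyz) > 1L) {
    warning("multi-model file: keeping model 1 only")
    xyz1 <- parsed$xyz[1L, ]
    at$x <- xyz1[seq(1, length(xyz1), 3)]
    at$y <- xyz1[seq(2, length(xyz1), 3)]
    at$z <- xyz1[seq(3, length(xyz1), 3)]
  }
  atoms <- data.frame(
    type = at$type, elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid, chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = if (!is.null(at$elesy)) at$elesy else NA_character_,
    stringsAsFactors = FALSE
  )
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  structure_model(atoms, label = label, source = path)
}

#' Write a structure model as PDB text
#'
#' Fixed-width PDB ATOM/HETATM records, coordinates to 3 decimals.  Intended
#' for fixtures and report output, not for deposition.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  name4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                  sprintf(" %-3s", at$elety))
  lines <- sprintf(
    "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$type == "HETATM", "HETATM", "ATOM"),
    seq_len(nrow(at)) %% 100000L, name4, substr(at$alt, 1, 1),
    at$resid, substr(at$chain, 1, 1), at$resno %% 10000L,
    substr(at$insert, 1, 1), at$x, at$y, at$z, at$o, at$b, at$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Define a domain as residue intervals on one chain
#'
#' @param name domain name.
#' @param chain_id chain identifier.
#' @param ranges list of inclusive `c(start, end)` author-number intervals
#'   (a single 2-vector is accepted).
#' @return A `domain_definition`.
#' @export
domain_definition <- function(name, chain_id, ranges) {
  if (is.numeric(ranges) && length(ranges) == 2L) ranges <- list(ranges)
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2]) stop("bad interval in domain '", name,
                                             "': need start <= end")
    r
  })
  ord <- order(vapply(ranges, `[`, integer(1), 1L))
  ranges <- ranges[ord]
  starts <- vapply(ranges, `[`, integer(1), 1L)
  ends <- vapply(ranges, `[`, integer(1), 2L)
  if (length(ranges) > 1L && any(starts[-1] <= ends[-length(ends)])) {
    stop("overlapping intervals in domain '", name, "'")
  }
  structure(list(name = name, chain_id = chain_id, ranges = ranges),
            class = "domain_definition")
}

in_domain <- function(resno, chain, domain) {
  hit <- rep(FALSE, length(resno))
  on_chain <- chain == domain$chain_id
  for (r in domain$ranges) {
    hit <- hit | (on_chain & resno >= r[1] & resno <= r[2])
  }
  hit
}

#' Select atoms by domain and atom name
#'
#' Returns atoms of the given names within the domain's chain/ranges, in
#' residue order.  Alternate locations are collapsed to the
#' highest-occupancy conformer (ties broken by lexicographically first
#' alt-loc id).  Residues in range that lack a requested atom are reported
#' in the `missing` attribute rather than silently dropped.
#'
#' @param model a `structure_model`.
#' @param domain a `domain_definition`.
#' @param atom_names character vector of atom names (e.g. `"CA"`, `"CB"`).
#' @param exclude_water drop water residues (default TRUE).
#' @param exclude_hydrogen drop hydrogens (default TRUE).
#' @return An `atom_selection`: list with `coords` (n x 3 matrix), `refs`
#'   (data.frame chain/resno/insert/resid/elety) and `missing` (data.frame
#'   of in-range residues lacking a requested atom).  Empty selections are
#'   returned with a warning, not an error.
#' @export
select_atoms <- function(model, domain, atom_names,
                         exclude_water = TRUE, exclude_hydrogen = TRUE) {
  at <- model$atoms
  if (!domain$chain_id %in% at$chain) {
    stop("chain '", domain$chain_id, "' not present in model '",
         model$label, "'")
  }
  keep <- in_domain(at$resno, at$chain, domain)
  if (exclude_water) keep <- keep & !(at$resid %in% WATER_NAMES)
  if (exclude_hydrogen) keep <- keep & !(at$elesy %in% c("H", "D"))
  inrange <- at[keep, , drop = FALSE]
  sel <- inrange[inrange$elety %in% atom_names, , drop = FALSE]
  sel <- collapse_altloc(sel)
  ord <- order(sel$resno, sel$insert, match(sel$elety, atom_names))
  sel <- sel[ord, , drop = FALSE]
  # residues in range missing a requested atom
  all_res <- unique(inrange[, c("chain", "resno", "insert", "resid")])
  have <- unique(sel[, c("chain", "resno", "insert")])
  have_key <- paste(have$chain, have$resno, have$insert)
  miss <- all_res[!paste(all_res$chain, all_res$resno, all_res$insert) %in%
                    have_key, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("empty selection for domain '", domain$name, "', atoms ",
            paste(atom_names, collapse = ","))
  }
  structure(list(
    coords = unname(as.matrix(sel[, c("x", "y", "z")])),
    refs = sel[, c("chain", "resno", "insert", "resid", "elety")],
    missing = miss
  ), class = "atom_selection")
}

# keep highest-occupancy alt-loc per (residue, atom name); ties -> first id
collapse_altloc <- function(sel) {
  if (nrow(sel) == 0L || all(sel$alt == "")) return(sel)
  key <- paste(residue_keys(sel), sel$elety)
  ord <- order(key, -sel$o, sel$alt)
  sel <- sel[ord, , drop = FALSE]
  sel[!duplicated(key[ord]), , drop = FALSE]
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> %d atoms (%d residues missing requested atoms)\n",
              nrow(x$coords), nrow(x$missing)))
  invisible(x)
}
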