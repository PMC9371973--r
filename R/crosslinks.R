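#' Parse and filter a crosslink identification table
#'
#' Reads a search-engine crosslink export (CSV) into a tidy record table,
#' applying the identification filters used for restraint analysis: an
#' E-value threshold (default: keep links with E-value below 1e-4), a
#' minimum number of experimental repeats (default 2), and removal of
#' self-links.  Duplicate rows for the same unordered residue pair are
#' merged with spectral counts summed (the pair's "frequency of
#' observation"), the minimum E-value and the maximum repeat count.
#'
#' @param table CSV path or a data.frame.
#' @param e_value_max keep records with `e_value < e_value_max`.
#' @param min_repeats keep records with `n_repeats >= min_repeats`.
#' @param cols named character vector mapping the canonical fields
#'   `pos_a`, `pos_b`, `res_a`, `res_b`, `spectral_count`, `e_value`,
#'   `n_repeats`, `sample_label` to the file's column names.  Fields
#'   `res_a`/`res_b`/`sample_label` are optional (default `"K"` / `""`);
#'   `n_repeats` defaults to `min_repeats` when absent.
#' @return data.frame of class `crosslink_records` with one row per unique
#'   unordered residue pair, ordered by (`pos_a`, `pos_b`) with
#'   `pos_a < pos_b`.
#' @export
parse_crosslinks <- function(table, e_value_max = 1e-4, min_repeats = 2L,
                             cols = c(pos_a = "pos_a", pos_b = "pos_b",
                                      res_a = "res_a", res_b = "res_b",
                                      spectral_count = "spectral_count",
                                      e_value = "e_value",
                                      n_repeats = "n_repeats",
                                      sample_label = "sample_label")) {
  df <- if (is.character(table)) read.csv(table, stringsAsFactors = FALSE)
        else as.data.frame(table)
  need <- c("pos_a", "pos_b", "spectral_count", "e_value")
  src <- cols[need]
  absent <- need[!src %in% names(df)]
  if (length(absent) > 0L) {
    stop("crosslink table missing required column(s) ",
         paste(cols[absent], collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "))
  }
  get_opt <- function(field, default) {
    nm <- cols[field]
    if (!is.na(nm) && nm %in% names(df)) df[[nm]] else default
  }
  rec <- data.frame(
    pos_a = as.integer(df[[cols["pos_a"]]]),
    pos_b = as.integer(df[[cols["pos_b"]]]),
    res_a = toupper(as.character(get_opt("res_a", "K"))),
    res_b = toupper(as.character(get_opt("res_b", "K"))),
    spectral_count = as.integer(df[[cols["spectral_count"]]]),
    e_value = as.numeric(df[[cols["e_value"]]]),
    n_repeats = as.integer(get_opt("n_repeats", min_repeats)),
    sample_label = as.character(get_opt("sample_label", "")),
    stringsAsFactors = FALSE
  )
  if (any(rec$spectral_count < 1L, na.rm = TRUE)) {
    stop("spectral counts must be >= 1")
  }
  self <- rec$pos_a == rec$pos_b
  if (any(self)) {
    warning(sum(self), " self-link(s) (pos_a == pos_b) excluded")
    rec <- rec[!self, , drop = FALSE]
  }
  rec <- rec[rec$e_value < e_value_max & rec$n_repeats >= min_repeats, ,
             drop = FALSE]
  # canonical unordered orientation, then merge duplicates
  flip <- rec$pos_a > rec$pos_b
  tmp_p <- rec$pos_a[flip]; rec$pos_a[flip] <- rec$pos_b[flip]
  rec$pos_b[flip] <- tmp_p
  tmp_r <- rec$res_a[flip]; rec$res_a[flip] <- rec$res_b[flip]
  rec$res_b[flip] <- tmp_r
  if (nrow(rec) > 0L) {
    key <- paste(rec$pos_a, rec$pos_b)
    merged <- lapply(split(rec, key), function(g) {
      g1 <- g[1L, , drop = FALSE]
      g1$spectral_count <- sum(g$spectral_count)
      g1$e_value <- min(g$e_value)
      g1$n_repeats <- max(g$n_repeats)
      g1$sample_label <- paste(unique(g$sample_label[g$sample_label != ""]),
                               collapse = ";")
      g1
    })
    rec <- do.call(rbind, merged)
    rec <- rec[order(rec$pos_a, rec$pos_b), , drop = FALSE]
    rownames(rec) <- NULL
  }
  class(rec) <- c("crosslink_records", "data.frame")
  rec
}

# full-length positions -> CB coordinates of lysines in the model,
# one row per chain copy holding that residue
cb_candidates <- function(model, full_pos, nm, check_identity = TRUE) {
  at <- model$atoms
  model_pos <- invert_position(nm, full_pos)
  if (is.na(model_pos)) return(NULL)  # deleted/unrepresented region
  rows <- at[at$resno == model_pos & at$insert == "" &
               !(at$resid %in% WATER_NAMES), , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)  # disordered / unbuilt
  if (check_identity && !any(rows$resid %in% c("LYS", "K"))) {
    stop("residue at model position ", model_pos, " (full-length ", full_pos,
         ") is ", rows$resid[1L],
         ", not lysine: numbering map suspect")
  }
  cb <- rows[rows$elety == "CB", , drop = FALSE]
  cb <- collapse_altloc(cb)
  if (nrow(cb) == 0L) return(NULL)
  cb
}

#' Map one crosslink onto a model as a C-beta distance restraint
#'
#' Projects an identified lysine-lysine crosslink onto an atomic model:
#' the restraint distance is the Euclidean distance between the two lysine
#' C-beta atoms, and the link is `satisfied` when strictly below the
#' maximum compatible crosslinker span (default 30 angstrom for BS3),
#' `violated` at or above it, and `unmapped` when either residue is absent
#' from the model (unbuilt, or removed by a construct deletion) or the
#' link involves non-lysine chemistry.  When several chains carry the
#' residue number, the minimum distance over chain assignments is used.
#'
#' @param model a `structure_model`.
#' @param rec one-row `crosslink_records` entry (or list with `pos_a`,
#'   `pos_b`, `res_a`, `res_b`, `spectral_count`).
#' @param nm a `numbering_map` translating model numbering to full-length
#'   numbering (default identity: model in full-length author numbering).
#' @param cutoff maximum compatible span in angstrom (default 30).
#' @param check_identity error if a mapped position is not lysine.
#' @return List of class `mapped_crosslink`: `record`, `distance` (NA when
#'   unmapped), `status`, `reason` (why a link is unmapped, else NA) and
#'   `atoms` (the C-beta pair used, or NULL).
#' @export
map_crosslink <- function(model, rec, nm = identity_numbering(),
                          cutoff = 30, check_identity = TRUE) {
  status <- "unmapped"; dist <- NA_real_; atoms <- NULL; reason <- NA_character_
  if (!all(c(rec$res_a, rec$res_b) %in% "K")) {
    reason <- "non-lysine chemistry"
  } else {
    cb_a <- cb_candidates(model, rec$pos_a, nm, check_identity)
    cb_b <- cb_candidates(model, rec$pos_b, nm, check_identity)
    if (!is.null(cb_a) && !is.null(cb_b)) {
      xa <- as.matrix(cb_a[, c("x", "y", "z")])
      xb <- as.matrix(cb_b[, c("x", "y", "z")])
      dmat <- outer(seq_len(nrow(xa)), seq_len(nrow(xb)),
                    Vectorize(function(i, j) sqrt(sum((xa[i, ] - xb[j, ])^2))))
      best <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
      dist <- min(dmat)
      status <- if (dist < cutoff) "satisfied" else "violated"
      atoms <- list(a = cb_a[best[1L], c("chain", "resno", "resid", "elety")],
                    b = cb_b[best[2L], c("chain", "resno", "resid", "elety")])
    }
  }
  structure(list(record = rec, distance = dist, status = status,
                 reason = reason, atoms = atoms, cutoff = cutoff),
            class = "mapped_crosslink")
}

#' Map a full crosslink set onto a model
#'
#' @param model a `structure_model`.
#' @param records a `crosslink_records` table.
#' @param nm,cutoff,check_identity as in [map_crosslink()].
#' @return data.frame of class `mapped_crosslinks` with one row per record:
#'   positions, spectral count, `distance` and `status`, plus a `model`
#'   label column.  Row order follows `records`.
#' @export
map_crosslinks <- function(model, records, nm = identity_numbering(),
                           cutoff = 30, check_identity = TRUE) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    m <- map_crosslink(model, records[i, ], nm, cutoff, check_identity)
    data.frame(model = model$label,
               pos_a = records$pos_a[i], pos_b = records$pos_b[i],
               spectral_count = records$spectral_count[i],
               distance = m$distance, status = m$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mapped_crosslinks", "data.frame")
  out
}

#' Frequency-weighted model FDR of a mapped crosslink set
#'
#' The model false discovery rate scores how well an atomic model explains
#' an observed crosslink set: the sum of forbidden (violated) crosslinks,
#' each multiplied by its frequency of observation (spectral count),
#' divided by the total of all observed crosslink frequencies.  It is a
#' model-quality statistic, not a search-engine identification FDR.
#' Unmapped links cannot be forbidden by the model; by default they are
#' excluded from both numerator and denominator and reported separately
#' (`denominator = "mapped"`); `denominator = "all_observed"` keeps them in
#' the denominator.
#'
#' @param mapped a `mapped_crosslinks` table.
#' @param denominator `"mapped"` (satisfied + violated, default) or
#'   `"all_observed"` (includes unmapped frequencies).
#' @return List of class `fdr_report`: model label, per-status link counts
#'   (`n_*`) and frequency sums (`freq_*`), `fdr` and the denominator mode.
#' @export
model_fdr <- function(mapped, denominator = c("mapped", "all_observed")) {
  denominator <- match.arg(denominator)
  if (nrow(mapped) == 0L) stop("empty crosslink set")
  freq <- function(s) sum(mapped$spectral_count[mapped$status == s])
  cnt <- function(s) sum(mapped$status == s)
  fv <- freq("violated"); fs <- freq("satisfied"); fu <- freq("unmapped")
  denom <- if (denominator == "mapped") fs + fv else fs + fv + fu
  if (fs + fv == 0) stop("no mappable restraints: all links unmapped")
  structure(list(
    model = mapped$model[1L],
    n_satisfied = cnt("satisfied"), n_violated = cnt("violated"),
    n_unmapped = cnt("unmapped"),
    freq_satisfied = fs, freq_violated = fv, freq_unmapped = fu,
    fdr = fv / denom, denominator = denominator
  ), class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf(
    "<fdr_report> model '%s': FDR %.1f%% (%s denominator)\n  links: %d satisfied, %d violated, %d unmapped; frequencies %d/%d/%d\n",
    x$model, 100 * x$fdr, x$denominator, x$n_satisfied, x$n_violated,
    x$n_unmapped, x$freq_satisfied, x$freq_violated, x$freq_unmapped))
  invisible(x)
}

#' Compare crosslink satisfaction across candidate conformers
#'
#' Maps a single crosslink set onto several models (e.g. a closed
#' autoinhibited conformer versus an open active one) and tabulates
#' per-model satisfied/violated/unmapped counts and model FDRs.  Because
#' extended conformations stretch many restraints beyond the compatible
#' span, the conformer actually sampled in solution shows the lower FDR.
#'
#' @param mapped_per_model named list of `mapped_crosslinks`, one per model
#'   label, all derived from the same record set in the same order.
#' @param denominator passed to [model_fdr()].
#' @return data.frame with one row per model (counts, frequency sums,
#'   `fdr`); the per-link status matrix (links x models) is attached as
#'   attribute `"status_matrix"`.
#' @export
compare_conformers <- function(mapped_per_model,
                               denominator = c("mapped", "all_observed")) {
  denominator <- match.arg(denominator)
  labels <- names(mapped_per_model)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stop("mapped_per_model must be a named list with unique labels")
  }
  n_links <- vapply(mapped_per_model, nrow, integer(1))
  if (length(unique(n_links)) != 1L) {
    stop("all models must map the same crosslink set")
  }
  rows <- lapply(labels, function(lb) {
    r <- model_fdr(mapped_per_model[[lb]], denominator)
    data.frame(model = lb, n_satisfied = r$n_satisfied,
               n_violated = r$n_violated, n_unmapped = r$n_unmapped,
               freq_satisfied = r$freq_satisfied,
               freq_violated = r$freq_violated,
               freq_unmapped = r$freq_unmapped, fdr = r$fdr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  status <- do.call(cbind, lapply(mapped_per_model, function(m) m$status))
  colnames(status) <- labels
  rownames(status) <- paste0(mapped_per_model[[1L]]$pos_a, "-",
                             mapped_per_model[[1L]]$pos_b)
  attr(out, "status_matrix") <- status
  out
}

#' Export mapped crosslinks as a Circos-style link table
#'
#' Long-format table suitable for circular link plots of a crosslink
#' network over the domain layout: one row per link with start/end residue
#' positions, spectral count as the value and the satisfaction status as
#' the color class.
#'
#' @param mapped a `mapped_crosslinks` table.
#' @param chrom segment name for all links (default the model label).
#' @return data.frame with columns `chrom`, `start`, `end`, `value`,
#'   `color`.
#' @export
circos_links <- function(mapped, chrom = NULL) {
  if (is.null(chrom)) chrom <- mapped$model[1L]
  color <- c(satisfied = "blue", violated = "red",
             unmapped = "grey")[mapped$status]
  data.frame(chrom = chrom, start = mapped$pos_a, end = mapped$pos_b,
             value = mapped$spectral_count, color = unname(color),
             stringsAsFactors = FALSE)
}
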