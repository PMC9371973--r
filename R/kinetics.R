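#' Construct a fluorescence time course
#'
#' @param times seconds, strictly increasing (plate-reader cycle times;
#'   default cycle interval in this assay family is 32 s).
#' @param signal fluorescence, arbitrary units; same length as `times`.
#' @param label sample label (variant name or `"buffer"`).
#' @param replicate replicate identifier.
#' @return A `time_course`.
#' @export
time_course <- function(times, signal, label = "sample", replicate = 1L) {
  stopifnot(length(times) == length(signal))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 label = label, replicate = replicate),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> '%s' rep %s: %d points, t = %.0f..%.0f s\n",
              x$label, x$replicate, length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}

#' Normalize a fluorescence time course (F/F0, relative to buffer control)
#'
#' Each trace is divided by the mean of its own pre-addition baseline (the
#' first `baseline_cycles` points, default 10), giving F/F0; the sample's
#' F/F0 is then divided pointwise by the buffer control's F/F0 at each
#' time point.  The returned trace keeps only post-baseline points, with
#' time re-zeroed to the moment of protein addition (end of the baseline)
#' so that downstream fitting can constrain the association to start at
#' x0 = 0.
#'
#' @param raw sample `time_course` (raw fluorescence).
#' @param buffer_control buffer-only `time_course` on the same time grid.
#' @param baseline_cycles number of pre-addition baseline cycles.
#' @return A normalized `time_course` (dimensionless signal).
#' @export
normalize_timecourse <- function(raw, buffer_control, baseline_cycles = 10L) {
  if (length(raw$times) != length(buffer_control$times) ||
      any(abs(raw$times - buffer_control$times) > 1e-9)) {
    stop("sample and buffer control are on different time grids")
  }
  if (length(raw$times) <= baseline_cycles) {
    stop("need more than ", baseline_cycles, " points")
  }
  f0 <- function(tc) mean(tc$signal[seq_len(baseline_cycles)])
  f0_raw <- f0(raw); f0_ctl <- f0(buffer_control)
  if (abs(f0_raw) < 1e-12 || abs(f0_ctl) < 1e-12) {
    stop("zero baseline mean: cannot form F/F0")
  }
  rel <- (raw$signal / f0_raw) / (buffer_control$signal / f0_ctl)
  post <- seq(baseline_cycles + 1L, length(raw$times))
  t_add <- raw$times[baseline_cycles]
  time_course(raw$times[post] - t_add, rel[post],
              label = raw$label, replicate = raw$replicate)
}

#' Fit a plateau-followed-by-one-phase-association model
#'
#' Least-squares fit of `y(t) = y0 + (plateau - y0) * (1 - exp(-k * t))`
#' with time measured in minutes from the moment of addition (x0
#' constrained to 0).  This is the standard reading of a
#' nucleotide-exchange fluorescence trace: `k_obs` (per minute) is the
#' observed exchange rate constant used to rank GEF variants.  Initial
#' guesses: y0 = first point, plateau = last point, k = 1 / (time at
#' half-rise); k is bounded to (0, 100] per minute.  Traces whose
#' amplitude is indistinguishable from noise leave k unidentifiable and
#' raise a flagged error rather than returning an arbitrary rate.
#'
#' @param tc a normalized `time_course` with times in seconds from
#'   addition (as produced by [normalize_timecourse()]).
#' @return List of class `exchange_fit`: `k_obs` (per minute), `y0`,
#'   `plateau`, `x0` (always 0), `rss`, `n`, `label`, `replicate`.
#' @export
fit_one_phase <- function(tc) {
  if (length(tc$times) < 10L) stop("need >= 10 post-addition points")
  t_min <- tc$times / 60
  y <- tc$signal
  amp <- y[length(y)] - y[1L]
  if (abs(amp) < 4 * sd_residual_linear(t_min, y) || abs(amp) < 1e-12) {
    stop(structure(class = c("xlgeom_unidentifiable", "error", "condition"),
                   list(message = paste0(
                     "flat trace for '", tc$label,
                     "': amplitude indistinguishable from noise, k unidentifiable"),
                     call = NULL)))
  }
  half <- y[1L] + amp / 2
  idx_half <- which(if (amp > 0) y >= half else y <= half)[1L]
  k0 <- 1 / max(t_min[idx_half], min(t_min[t_min > 0]))
  k0 <- min(max(k0, 1e-3), 100)
  start <- list(y0 = y[1L], plateau = y[length(y)], k = k0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + (plateau - y0) * (1 - exp(-k * t_min)),
                      start = start,
                      lower = c(y0 = -Inf, plateau = -Inf, k = 1e-6),
                      upper = c(y0 = Inf, plateau = Inf, k = 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("one-phase fit did not converge for '",
                             tc$label, "' (start: y0=", signif(start$y0, 4),
                             ", plateau=", signif(start$plateau, 4),
                             ", k=", signif(start$k, 4),
                             " /min, bounds k in (0,100]): ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- coef(fit)
  structure(list(k_obs = unname(cf["k"]), y0 = unname(cf["y0"]),
                 plateau = unname(cf["plateau"]), x0 = 0,
                 rss = sum(resid(fit)^2), n = length(y),
                 label = tc$label, replicate = tc$replicate),
            class = "exchange_fit")
}

# rough noise scale: sd of residuals from a straight-line fit
sd_residual_linear <- function(t, y) {
  r <- resid(stats::lm(y ~ t))
  stats::sd(r)
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> '%s' rep %s: k_obs %.4f /min (y0 %.3f -> plateau %.3f, n %d)\n",
              x$label, x$replicate, x$k_obs, x$y0, x$plateau, x$n))
  invisible(x)
}

#' Summarize fitted rate constants across replicates
#'
#' Per-variant mean, standard deviation and n of `k_obs`, preserving the
#' order in which variants first appear.  A single replicate yields an NA
#' standard deviation (flagged, not zero).
#'
#' @param fits list of `exchange_fit` objects, or a data.frame with
#'   columns `label` and `k_obs`.
#' @return data.frame with columns `label`, `mean_k`, `sd_k`, `n`.
#' @export
summarize_replicates <- function(fits) {
  df <- if (is.data.frame(fits)) fits else
    do.call(rbind, lapply(fits, function(f)
      data.frame(label = f$label, k_obs = f$k_obs,
                 stringsAsFactors = FALSE)))
  labels <- unique(df$label)
  out <- do.call(rbind, lapply(labels, function(lb) {
    k <- df$k_obs[df$label == lb]
    data.frame(label = lb, mean_k = mean(k),
               sd_k = if (length(k) > 1L) stats::sd(k) else NA_real_,
               n = length(k), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a plate of exchange time courses from wide CSV
#'
#' @param data_csv CSV with a time column (seconds) and one column per
#'   well.
#' @param plate_map_csv CSV with columns `well`, `label`, `replicate`,
#'   `is_control` (logical or 0/1).
#' @param time_col name of the time column.
#' @return Named list: `samples` (list of raw `time_course`) and
#'   `controls` (list of buffer `time_course`).
#' @export
read_plate <- function(data_csv, plate_map_csv, time_col = "time_s") {
  dat <- read.csv(data_csv, check.names = FALSE)
  pm <- read.csv(plate_map_csv, stringsAsFactors = FALSE)
  if (!time_col %in% names(dat)) stop("time column '", time_col, "' absent")
  need <- setdiff(c("well", "label", "replicate", "is_control"), names(pm))
  if (length(need) > 0L) stop("plate map missing: ",
                              paste(need, collapse = ", "))
  absent <- setdiff(pm$well, names(dat))
  if (length(absent) > 0L) stop("wells absent from data: ",
                                paste(absent, collapse = ", "))
  mk <- function(i) time_course(dat[[time_col]], dat[[pm$well[i]]],
                                label = pm$label[i],
                                replicate = pm$replicate[i])
  ctl <- as.logical(pm$is_control)
  list(samples = lapply(which(!ctl), mk), controls = lapply(which(ctl), mk))
}
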