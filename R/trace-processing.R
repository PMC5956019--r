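#' Construct an MST capillary trace
#'
#' One capillary's fluorescence time series together with the final
#' in-capillary titrant concentration and the IR-laser switching times.
#' A typical acquisition holds ~5 s of pre-laser baseline, 30 s of laser-on
#' thermophoresis and a short back-diffusion tail.
#'
#' @param capillary_id Identifier (coerced to character).
#' @param titrant_conc Final in-capillary titrant concentration (nM). The
#'   titrant is the antibody in saturation mode and the unlabeled drug in
#'   competition mode.
#' @param time_s Strictly increasing timestamps (s).
#' @param fluorescence Fluorescence counts, strictly positive, same length
#'   as `time_s`.
#' @param laser_on_s,laser_off_s IR laser on/off times (s),
#'   `laser_on_s < laser_off_s`. At least 3 samples are required before
#'   laser-on and 3 between laser-on and laser-off.
#' @return An object of class `mst_trace`.
#' @export
mst_trace <- function(capillary_id, titrant_conc, time_s, fluorescence,
                      laser_on_s = 5, laser_off_s = 35) {
  time_s <- as.numeric(time_s)
  fluorescence <- as.numeric(fluorescence)
  if (length(time_s) != length(fluorescence)) {
    stop("time_s and fluorescence must have equal length", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing",
                                   call. = FALSE)
  if (any(fluorescence <= 0)) stop("fluorescence must be strictly positive",
                                   call. = FALSE)
  if (!(laser_on_s < laser_off_s)) stop("laser_on_s must precede laser_off_s",
                                        call. = FALSE)
  if (sum(time_s < laser_on_s) < 3) {
    stop("need at least 3 samples before laser-on", call. = FALSE)
  }
  if (sum(time_s >= laser_on_s & time_s <= laser_off_s) < 3) {
    stop("need at least 3 samples during the laser-on phase", call. = FALSE)
  }
  structure(list(capillary_id = as.character(capillary_id),
                 titrant_conc = as.numeric(titrant_conc),
                 time_s = time_s, fluorescence = fluorescence,
                 laser_on_s = laser_on_s, laser_off_s = laser_off_s),
            class = "mst_trace")
}

#' @export
print.mst_trace <- function(x, ...) {
  cat(sprintf(
    "MST trace %s: titrant %g nM, %d samples over %.1f-%.1f s, laser %g-%g s\n",
    x$capillary_id, x$titrant_conc, length(x$time_s),
    min(x$time_s), max(x$time_s), x$laser_on_s, x$laser_off_s))
  invisible(x)
}

#' Define cold/hot analysis windows for F_norm
#'
#' The cold window must end at or before laser-on; the hot window must lie
#' strictly after laser-on and at or before laser-off.
#'
#' @param cold_window Closed interval `c(start, end)` in seconds.
#' @param hot_window Closed interval `c(start, end)` in seconds.
#' @param laser_on_s,laser_off_s Laser switching times used for validation.
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(cold_window, hot_window,
                             laser_on_s = 5, laser_off_s = 35) {
  stopifnot(length(cold_window) == 2, length(hot_window) == 2)
  if (cold_window[1] >= cold_window[2] || hot_window[1] >= hot_window[2]) {
    stop("windows must be non-degenerate intervals", call. = FALSE)
  }
  if (cold_window[2] > laser_on_s) {
    stop("cold window must end at or before laser-on", call. = FALSE)
  }
  if (hot_window[1] <= laser_on_s || hot_window[2] > laser_off_s) {
    stop("hot window must lie within (laser_on, laser_off]", call. = FALSE)
  }
  structure(list(cold_window = as.numeric(cold_window),
                 hot_window = as.numeric(hot_window)),
            class = "analysis_windows")
}

# default windows: 4.5 s of late pre-laser baseline, 1 s hot window ending
# 1 s before laser-off (leaves room for the hot-window grid search)
default_windows <- function(laser_on_s = 5, laser_off_s = 35) {
  analysis_windows(cold_window = c(laser_on_s - 4.5, laser_on_s - 0.5),
                   hot_window = c(laser_off_s - 2, laser_off_s - 1),
                   laser_on_s = laser_on_s, laser_off_s = laser_off_s)
}

window_mean <- function(trace, win) {
  sel <- trace$time_s >= win[1] & trace$time_s <= win[2]
  if (sum(sel) < 2) {
    stop(sprintf("window [%g, %g] s contains fewer than 2 samples",
                 win[1], win[2]), call. = FALSE)
  }
  v <- trace$fluorescence[sel]
  if (any(v <= 0)) stop("non-positive fluorescence inside analysis window",
                        call. = FALSE)
  mean(v)
}

#' Normalized fluorescence (F_norm) of one capillary
#'
#' F_norm is the mean hot-phase fluorescence divided by the mean cold-phase
#' (pre-laser) fluorescence, scaled to permille:
#' \deqn{F_{norm} = \frac{F_h}{F_c} \times 1000.}
#' Window means, not single samples, are used: the readout is the mean
#' steady-state fluorescence in each window.
#'
#' @param trace An [mst_trace()].
#' @param windows An [analysis_windows()]; defaults to a 4.5 s pre-laser
#'   cold window and a 1 s hot window ending 1 s before laser-off.
#' @return One-row data frame (class `fnorm_point`) with columns
#'   `capillary_id`, `titrant_conc`, `fnorm` (permille), `cold_mean`
#'   (counts) and `qc_flags` (empty string).
#' @export
compute_fnorm <- function(trace, windows = NULL) {
  stopifnot(inherits(trace, "mst_trace"))
  if (is.null(windows)) {
    windows <- default_windows(trace$laser_on_s, trace$laser_off_s)
  }
  stopifnot(inherits(windows, "analysis_windows"))
  if (windows$cold_window[1] < min(trace$time_s) ||
      windows$hot_window[2] > max(trace$time_s)) {
    stop("analysis window lies outside the trace time span", call. = FALSE)
  }
  fc <- window_mean(trace, windows$cold_window)
  fh <- window_mean(trace, windows$hot_window)
  out <- data.frame(capillary_id = trace$capillary_id,
                    titrant_conc = trace$titrant_conc,
                    fnorm = fh / fc * 1000,
                    cold_mean = fc,
                    qc_flags = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("fnorm_point", class(out))
  out
}

#' F_norm table for a set of capillaries
#'
#' Applies [compute_fnorm()] to each trace and row-binds the results,
#' ordered by titrant concentration.
#'
#' @param traces List of [mst_trace()] objects.
#' @param windows Shared [analysis_windows()], or `NULL` for defaults.
#' @return Data frame with one row per capillary.
#' @export
fnorm_table <- function(traces, windows = NULL) {
  pts <- do.call(rbind, lapply(traces, compute_fnorm, windows = windows))
  pts[order(pts$titrant_conc), , drop = FALSE]
}

#' Automated hot-window selection
#'
#' Scans a grid of candidate hot windows and, for each, computes the
#' F_norm series and a preliminary log-logistic fit of F_norm against
#' titrant concentration. The selected window maximizes
#' |response amplitude| / residual standard deviation — an automated
#' stand-in for the operator's choice of the time point with the best
#' signal-to-noise and K_d confidence. Ties are broken in favour of the
#' earliest window start, so repeated calls on identical input return the
#' identical window.
#'
#' @param traces List of >= 8 [mst_trace()] objects whose titrant
#'   concentrations span at least 3 decades.
#' @param windows_grid List of >= 2 candidate [analysis_windows()]. By
#'   default, 1-s windows at 1-s steps from laser-on + 1 s to laser-off.
#' @return The winning [analysis_windows()], with the achieved score in
#'   attribute `"score"`.
#' @export
select_hot_window <- function(traces, windows_grid = NULL) {
  stopifnot(length(traces) >= 8)
  concs <- vapply(traces, function(tr) tr$titrant_conc, numeric(1))
  pos <- concs[concs > 0]
  if (log10(max(pos) / min(pos)) < 3) {
    stop("titrant concentrations must span at least 3 decades", call. = FALSE)
  }
  if (is.null(windows_grid)) {
    on_s <- traces[[1]]$laser_on_s; off_s <- traces[[1]]$laser_off_s
    starts <- seq(on_s + 1, off_s - 1, by = 1)
    windows_grid <- lapply(starts, function(s)
      analysis_windows(c(on_s - 4.5, on_s - 0.5), c(s, s + 1), on_s, off_s))
  }
  if (length(windows_grid) < 2) {
    stop("need at least 2 candidate hot windows", call. = FALSE)
  }
  scores <- vapply(windows_grid, function(w) {
    pts <- fnorm_table(traces, windows = w)
    window_score(pts)
  }, numeric(1))
  if (all(!is.finite(scores) | scores <= 0)) {
    stop("zero response amplitude in every candidate window; ",
         "cannot select a hot window", call. = FALSE)
  }
  best <- which(scores == max(scores, na.rm = TRUE))[1]  # earliest wins ties
  w <- windows_grid[[best]]
  attr(w, "score") <- scores[best]
  w
}

# amplitude-to-residual score of a preliminary log-logistic fit of
# fnorm vs titrant concentration (covers both binding-curve directions)
window_score <- function(pts) {
  x <- pts$titrant_conc; y <- pts$fnorm
  amp <- diff(range(y))
  if (amp <= 0) return(-Inf)
  xpos <- x[x > 0]
  c50_grid <- exp(seq(log(min(xpos)), log(max(xpos)), length.out = 8))
  best <- NULL
  for (c50 in c50_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ u + (b - u) * x / (c50f + x),
        start = list(u = y[which.min(x)], b = y[which.max(x)],
                     c50f = c50),
        data = data.frame(x = x, y = y),
        lower = c(-Inf, -Inf, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) return(-Inf)
  cf <- stats::coef(best$fit)
  resid_sd <- sqrt(best$rss / max(length(y) - 3, 1))
  if (resid_sd == 0) resid_sd <- .Machine$double.eps * max(abs(y), 1)
  abs(cf[["b"]] - cf[["u"]]) / resid_sd
}

#' Capillary-level quality control of an F_norm table
#'
#' Annotates, without altering any F_norm value:
#' * `BASELINE_OUTLIER` — cold-phase mean deviates from the series median
#'   by more than `baseline_tol` (relative);
#' * `BLEACHING` — |least-squares slope of cold-phase fluorescence vs
#'   time| exceeds `bleach_tol` (expressed as a fraction of the capillary's
#'   cold mean, per second);
#' * `EXCLUDED_TOP_POINT` — the highest titrant concentration, when
#'   `exclude_top = TRUE` (used when the top point of a serum titration is
#'   known to distort baseline fluorescence and bleaching).
#'
#' Flagged points are retained in the table; fitting functions exclude
#' them.
#'
#' @param points F_norm table from [fnorm_table()] (>= 4 rows).
#' @param traces The matching list of [mst_trace()] objects (needed for
#'   the bleaching slope); may be `NULL` to skip the bleaching check.
#' @param baseline_tol Relative deviation of `cold_mean` from the series
#'   median that triggers `BASELINE_OUTLIER`. Default 0.10.
#' @param bleach_tol Cold-phase slope threshold as a fraction of the cold
#'   mean per second. Default 0.01 (1 %/s).
#' @param exclude_top Flag the highest titrant point. Default `FALSE`.
#' @return The table with updated `qc_flags` (semicolon-joined).
#' @export
qc_capillaries <- function(points, traces = NULL, baseline_tol = 0.10,
                           bleach_tol = 0.01, exclude_top = FALSE) {
  stopifnot(nrow(points) >= 4)
  flags <- strsplit(points$qc_flags, ";", fixed = TRUE)
  flags <- lapply(flags, function(f) f[nzchar(f)])
  med <- stats::median(points$cold_mean)
  dev <- abs(points$cold_mean - med) / med
  for (i in which(dev > baseline_tol)) {
    flags[[i]] <- union(flags[[i]], "BASELINE_OUTLIER")
  }
  if (!is.null(traces)) {
    ids <- vapply(traces, function(tr) tr$capillary_id, character(1))
    for (i in seq_len(nrow(points))) {
      tr <- traces[[match(points$capillary_id[i], ids)]]
      if (is.null(tr)) next
      sel <- tr$time_s < tr$laser_on_s
      if (sum(sel) >= 3) {
        slope <- stats::cov(tr$time_s[sel], tr$fluorescence[sel]) /
          stats::var(tr$time_s[sel])
        if (abs(slope) > bleach_tol * points$cold_mean[i]) {
          flags[[i]] <- union(flags[[i]], "BLEACHING")
        }
      }
    }
  }
  if (isTRUE(exclude_top)) {
    i <- which.max(points$titrant_conc)
    flags[[i]] <- union(flags[[i]], "EXCLUDED_TOP_POINT")
  }
  points$qc_flags <- vapply(flags, paste, character(1), collapse = ";")
  points
}

#' Fraction bound from an F_norm value
#'
#' Linear rescaling of an F_norm reading between the unbound and bound
#' plateaus:
#' \deqn{\mathrm{fraction\ bound} = \frac{x - F_{norm,Unbound}}
#'   {F_{norm,Bound} - F_{norm,Unbound}}.}
#' Noisy values may fall slightly outside \[0, 1\]; they are deliberately
#' not clipped, since clipping before least squares would bias fits.
#'
#' @param x F_norm value(s), permille.
#' @param fnorm_unbound,fnorm_bound Plateau F_norm values (permille); must
#'   differ.
#' @return Fraction bound (dimensionless), vectorised over `x`.
#' @export
fraction_bound <- function(x, fnorm_unbound, fnorm_bound) {
  amp <- fnorm_bound - fnorm_unbound
  if (amp == 0) stop("zero response amplitude: bound and unbound plateaus ",
                     "coincide", call. = FALSE)
  (x - fnorm_unbound) / amp
}
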