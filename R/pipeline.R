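#' Read a long-format MST trace CSV
#'
#' Expects UTF-8 with header columns `capillary_id`, `titrant_conc_nM`,
#' `time_s`, `fluorescence`; one file per titration run.
#'
#' @param path CSV path.
#' @param laser_on_s,laser_off_s Laser switching times (s) for the run.
#' @return List of [mst_trace()] objects, one per capillary.
#' @export
read_trace_csv <- function(path, laser_on_s = 5, laser_off_s = 35) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("capillary_id", "titrant_conc_nM", "time_s", "fluorescence")
  if (!all(need %in% names(d))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0) stop("trace CSV is empty: ", path, call. = FALSE)
  lapply(split(d, d$capillary_id), function(g) {
    g <- g[order(g$time_s), ]
    mst_trace(g$capillary_id[1], g$titrant_conc_nM[1], g$time_s,
              g$fluorescence, laser_on_s, laser_off_s)
  })
}

#' Write traces to the long-format trace CSV dialect
#'
#' @param traces List of [mst_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  d <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(capillary_id = tr$capillary_id,
               titrant_conc_nM = tr$titrant_conc,
               time_s = tr$time_s, fluorescence = tr$fluorescence)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an F_norm table CSV
#'
#' Columns: `titrant_conc_nM`, `fnorm_permille`, `cold_mean`, `qc_flags`
#' (semicolon-joined).
#'
#' @param points F_norm table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fnorm_csv <- function(points, path) {
  out <- data.frame(titrant_conc_nM = points$titrant_conc,
                    fnorm_permille = points$fnorm,
                    cold_mean = points$cold_mean,
                    qc_flags = points$qc_flags)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

binding_fit_report <- function(fit) {
  list(estimate_nM = fit$estimate, ci95 = fit$ci95,
       plateaus = c(unbound = fit$fnorm_unbound, bound = fit$fnorm_bound),
       r2 = fit$r2, n_used = fit$n_used, flags = fit$flags, mode = fit$mode)
}

run_manifest <- function(config, seed = NULL) {
  list(package = "mstbind",
       version = as.character(utils::packageVersion("mstbind")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, config = config)
}

write_report <- function(report, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, name)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Run the conventional MST workflow: traces to K_d
#'
#' Traces are converted to F_norm, QC-annotated (excluded points are
#' listed in the report with their flags), and fitted with the
#' depletion-corrected saturation model.
#'
#' @param config Named list: `trace_csv` (path) or `traces` (list of
#'   [mst_trace()]), `tracer_total` (nM, required), optional
#'   `exclude_top` (logical), `baseline_tol`, `bleach_tol`, `windows`
#'   (an [analysis_windows()]), `out_dir`.
#' @return Report list (invisibly written to
#'   `out_dir/conventional_report.json` when `out_dir` is set) with the
#'   fit, the F_norm table and a reproducibility manifest.
#' @export
run_conventional <- function(config) {
  if (is.null(config$tracer_total)) {
    stop("config error: tracer_total (nM) is required", call. = FALSE)
  }
  traces <- config$traces
  if (is.null(traces)) traces <- read_trace_csv(config$trace_csv)
  pts <- fnorm_table(traces, windows = config$windows)
  pts <- qc_capillaries(pts, traces,
                        baseline_tol = config$baseline_tol %||% 0.10,
                        bleach_tol = config$bleach_tol %||% 0.01,
                        exclude_top = isTRUE(config$exclude_top))
  series <- titration_series(pts, "SATURATION",
                             tracer_total = config$tracer_total)
  fit <- fit_saturation(series)
  excluded <- pts[nzchar(pts$qc_flags), c("titrant_conc", "qc_flags")]
  report <- list(workflow = "CONVENTIONAL", fit = binding_fit_report(fit),
                 excluded_points = excluded, fnorm = pts,
                 manifest = run_manifest(config[setdiff(names(config),
                                                        "traces")]))
  write_report(report, config$out_dir, "conventional_report.json")
  invisible(report)
}

#' Run the heterologous MST workflow: competition traces to K_i
#'
#' Fits the competition displacement curve for the IC50, then inverts
#' the exact ternary model for Ki. The Ki confidence interval is the
#' IC50 interval transformed endpoint-by-endpoint through the monotone
#' IC50-to-Ki map; endpoints beyond the identifiable range (IC50 > top
#' competitor concentration) are reported as `NA`.
#'
#' @param config Named list: `trace_csv` or `traces`; required design
#'   constants `tracer_kd` (nM), `antibody_sites` (nM, `i0`),
#'   `tracer_total` (nM, `t0`); optional QC options as in
#'   [run_conventional()].
#' @return Report list carrying the IC50 fit, the conversion inputs
#'   `(kd, i0, t0, l0, ic50)`, the Ki with CI, and a verdict
#'   (`"OK"` or `"UNIDENTIFIABLE"` when the IC50 lies outside the
#'   titrated range).
#' @export
run_heterologous <- function(config) {
  for (k in c("tracer_kd", "antibody_sites", "tracer_total")) {
    if (is.null(config[[k]])) {
      stop("config error: ", k, " is required for the heterologous workflow",
           call. = FALSE)
    }
  }
  traces <- config$traces
  if (is.null(traces)) traces <- read_trace_csv(config$trace_csv)
  pts <- fnorm_table(traces, windows = config$windows)
  pts <- qc_capillaries(pts, traces,
                        baseline_tol = config$baseline_tol %||% 0.10,
                        bleach_tol = config$bleach_tol %||% 0.01,
                        exclude_top = isTRUE(config$exclude_top))
  series <- titration_series(pts, "COMPETITION",
                             tracer_total = config$tracer_total,
                             antibody_sites = config$antibody_sites,
                             tracer_kd = config$tracer_kd)
  fit <- fit_competition(series)
  l0 <- max(used_points(series)$titrant_conc)
  inputs <- list(kd = config$tracer_kd, i0 = config$antibody_sites,
                 t0 = config$tracer_total, l0 = l0, ic50 = fit$estimate)
  ki_or_na <- function(ic) tryCatch(
    ki_from_ic50(ic, inputs$kd, inputs$i0, inputs$t0, l0),
    error = function(e) NA_real_)
  ki <- ki_or_na(fit$estimate)
  verdict <- if (is.na(ki)) "UNIDENTIFIABLE" else "OK"
  report <- list(workflow = "HETEROLOGOUS", fit = binding_fit_report(fit),
                 inputs = inputs, ki_nM = ki,
                 ki_ci95 = c(ki_or_na(fit$ci95[1]), ki_or_na(fit$ci95[2])),
                 verdict = verdict,
                 manifest = run_manifest(config[setdiff(names(config),
                                                        "traces")]))
  write_report(report, config$out_dir, "heterologous_report.json")
  invisible(report)
}

#' Run the equilibrium-dialysis workflow: binding sites and K_d
#'
#' The zero-competitor bound fraction feeds Mueller's equation for the
#' binding-site concentration (using the sample-chamber total tracer at
#' equilibrium implied by mass balance); the full competition series is
#' fitted for Kd with [estimate_kd_from_competition()].
#'
#' @param config Named list: `ed_csv` (columns `competitor_nM`,
#'   `b_measured`) or `measurements` (data frame `competitor`, `b`);
#'   `design` (a [dialysis_design()], default the 100/300 uL, 5 nM
#'   tracer setup); `ab_sites` (nM) for the forward-model fit.
#' @return Report list with `kd_nM`, `r2`, `ab_sites_nM` (Mueller
#'   estimate from the zero-competitor point) and the manifest.
#' @export
run_ed <- function(config) {
  meas <- config$measurements
  if (is.null(meas)) {
    d <- utils::read.csv(config$ed_csv, stringsAsFactors = FALSE)
    if (!all(c("competitor_nM", "b_measured") %in% names(d))) {
      stop("ED CSV must have columns competitor_nM, b_measured",
           call. = FALSE)
    }
    meas <- data.frame(competitor = d$competitor_nM, b = d$b_measured)
  }
  design <- config$design %||% dialysis_design()
  ab_sites <- config$ab_sites %||% design$ab_sites_in_sample
  if (!any(meas$competitor == 0)) {
    stop("config error: a zero-competitor measurement is required for the ",
         "binding-site estimate", call. = FALSE)
  }
  est <- estimate_kd_from_competition(meas, design, ab_sites = ab_sites)
  b0 <- meas$b[meas$competitor == 0][1]
  # sample-chamber total tracer at equilibrium from the mass balance
  vs <- design$v_sample; vb <- design$v_buffer
  tt <- design$tracer_total_in_sample * vs /
    ((1 - b0) * (vs + vb) + b0 * vs)
  sites <- mueller_binding_sites(b0, tt, est$kd)
  report <- list(workflow = "ED", kd_nM = est$kd, r2 = est$r2,
                 ab_sites_nM = sites, b_zero_competitor = b0,
                 manifest = run_manifest(config[setdiff(names(config),
                                                        c("measurements",
                                                          "design"))]))
  write_report(report, config$out_dir, "ed_report.json")
  invisible(report)
}

#' Run the degradation workflow over a multi-condition CSV
#'
#' Reads a degradation CSV (columns `condition`, `heroin_initial_nM`,
#' `ab_sites_nM`, `time_h`, `conc_nM`), analyses each
#' (condition, initial concentration) course with [analyze_course()] and
#' reports verdicts, half-life ranges and r-squared values.
#'
#' @param config Named list: `degradation_csv` or `courses` (list of
#'   [degradation_course()]); optional `r2_threshold`, `out_dir`.
#' @return Report list with one entry per course.
#' @export
run_degradation <- function(config) {
  courses <- config$courses
  if (is.null(courses)) {
    d <- utils::read.csv(config$degradation_csv, stringsAsFactors = FALSE)
    need <- c("condition", "heroin_initial_nM", "ab_sites_nM", "time_h",
              "conc_nM")
    if (!all(need %in% names(d))) {
      stop("degradation CSV must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    key <- interaction(d$condition, d$heroin_initial_nM, drop = TRUE)
    courses <- lapply(split(d, key), function(g) {
      g <- g[order(g$time_h), ]
      degradation_course(g$condition[1], g$heroin_initial_nM[1],
                         g$ab_sites_nM[1], g$time_h, g$conc_nM)
    })
  }
  results <- lapply(courses, function(cr) {
    a <- analyze_course(cr, r2_threshold = config$r2_threshold %||% 0.95)
    out <- list(condition = a$condition,
                heroin_initial_nM = cr$heroin_initial,
                verdict = a$verdict, r2 = a$r2, t_half_h = a$t_half)
    if (a$verdict == "FIRST_ORDER") {
      out$t_half_ci99_h <- a$fit$t_half_ci
    }
    out
  })
  report <- list(workflow = "DEGRADATION", courses = unname(results),
                 manifest = run_manifest(config[setdiff(names(config),
                                                        "courses")]))
  write_report(report, config$out_dir, "degradation_report.json")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
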