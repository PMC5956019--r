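#' Assemble a titration series for fitting
#'
#' Bundles an F_norm table with the design constants a fit needs. In
#' saturation (conventional) mode the varying axis is the antibody
#' binding-site concentration at fixed tracer; in competition
#' (heterologous) mode it is the unlabeled competitor at fixed
#' antibody:tracer complex.
#'
#' @param points F_norm table ([fnorm_table()] output, possibly annotated
#'   by [qc_capillaries()]). QC-flagged rows are retained but excluded
#'   from fitting; at least 8 unflagged points with strictly positive,
#'   distinct concentrations are required.
#' @param mode `"SATURATION"` or `"COMPETITION"`.
#' @param tracer_total Final in-capillary tracer concentration (nM).
#' @param antibody_sites Final binding-site concentration (nM); required
#'   for competition mode.
#' @param tracer_kd Tracer dissociation constant (nM); optional, carried
#'   along for downstream Ki conversion.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(points, mode = c("SATURATION", "COMPETITION"),
                             tracer_total, antibody_sites = NULL,
                             tracer_kd = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(points), tracer_total > 0)
  ok <- !nzchar(points$qc_flags)
  x <- points$titrant_conc[ok]
  if (sum(ok) < 8) stop("need at least 8 unflagged titration points",
                        call. = FALSE)
  if (any(x <= 0) || anyDuplicated(x)) {
    stop("titrant concentrations must be strictly positive and distinct",
         call. = FALSE)
  }
  if (mode == "COMPETITION" && is.null(antibody_sites)) {
    stop("competition mode requires antibody_sites", call. = FALSE)
  }
  structure(list(points = points, mode = mode,
                 tracer_total = tracer_total,
                 antibody_sites = antibody_sites,
                 tracer_kd = tracer_kd),
            class = "titration_series")
}

used_points <- function(series) {
  ok <- !nzchar(series$points$qc_flags)
  series$points[ok, , drop = FALSE]
}

new_binding_fit <- function(estimate, fnorm_unbound, fnorm_bound, ci95, r2,
                            n_used, converged, mode, flags = character(0),
                            fit = NULL) {
  structure(list(estimate = estimate, fnorm_unbound = fnorm_unbound,
                 fnorm_bound = fnorm_bound, ci95 = ci95, r2 = r2,
                 n_used = n_used, converged = converged, mode = mode,
                 flags = flags, fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  lab <- if (x$mode == "SATURATION") "Kd" else "IC50"
  cat(sprintf("%s binding fit: %s = %.4g nM (95%% CI %.4g-%.4g)\n",
              tolower(x$mode), lab, x$estimate, x$ci95[1], x$ci95[2]))
  cat(sprintf("  plateaus: unbound %.1f, bound %.1f permille; r2 = %.4f; n = %d\n",
              x$fnorm_unbound, x$fnorm_bound, x$r2, x$n_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

r2_of <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

# multi-start nlsLM over a log-scale grid for the nonlinear parameter;
# returns the converged fit with the lowest RSS, or NULL
multistart_nls <- function(formula, data, make_start, grid, lower = NULL) {
  best <- NULL
  for (g in grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = make_start(g),
                        lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < attr(best, "rss")) {
        attr(fit, "rss") <- rss
        best <- fit
      }
    }
  }
  best
}

# asymptotic 95% CI for exp(log-parameter) `name`
log_param_ci <- function(fit, name, level = 0.95) {
  sm <- summary(fit)
  est <- sm$coefficients[name, "Estimate"]
  se <- sm$coefficients[name, "Std. Error"]
  dfree <- sm$df[2]
  q <- stats::qt(1 - (1 - level) / 2, dfree)
  exp(c(est - q * se, est + q * se))
}

#' Fit a saturation (conventional MST) binding curve
#'
#' Models F_norm as an affine map of the depletion-corrected bound
#' fraction,
#' \deqn{F_{norm}(A) = U + (B - U)\, f(A; T_0, K_d),}
#' where \eqn{f} is [binary_bound_fraction()] — the exact 1:1 isotherm
#' with ligand depletion, required because tracer and K_d are of
#' comparable magnitude in these assays. `U` and `B` are the unbound and
#' bound F_norm plateaus. Least squares by Levenberg-Marquardt with
#' multi-start over a log K_d grid (0.01 to 1000 nM); K_d is parameterised
#' on the log scale, so the asymptotic 95% CI is computed on log K_d and
#' exponentiated.
#'
#' @param series A SATURATION-mode [titration_series()].
#' @return A `binding_fit` with the K_d estimate (nM), plateaus, 95% CI,
#'   r-squared, and the number of points used.
#' @export
fit_saturation <- function(series) {
  stopifnot(inherits(series, "titration_series"),
            series$mode == "SATURATION")
  pts <- used_points(series)
  d <- data.frame(A = pts$titrant_conc, y = pts$fnorm)
  if (diff(range(d$y)) == 0) {
    stop("flat curve: response amplitude indistinguishable from zero",
         call. = FALSE)
  }
  t0 <- series$tracer_total
  fit <- multistart_nls(
    y ~ u + (b - u) * binary_bound_fraction(A, t0, exp(lkd)),
    data = d,
    make_start = function(g) list(u = d$y[which.min(d$A)],
                                  b = d$y[which.max(d$A)], lkd = log(g)),
    grid = c(0.01, 0.1, 1, 10, 100, 1000))
  if (is.null(fit)) stop("saturation fit failed from every start",
                         call. = FALSE)
  cf <- stats::coef(fit)
  resid_sd <- sqrt(sum(stats::residuals(fit)^2) / max(nrow(d) - 3, 1))
  if (abs(cf[["b"]] - cf[["u"]]) < 3 * resid_sd) {
    stop("flat curve: response amplitude indistinguishable from zero",
         call. = FALSE)
  }
  new_binding_fit(estimate = exp(cf[["lkd"]]),
                  fnorm_unbound = cf[["u"]], fnorm_bound = cf[["b"]],
                  ci95 = log_param_ci(fit, "lkd"),
                  r2 = r2_of(d$y, stats::fitted(fit)),
                  n_used = nrow(d), converged = TRUE,
                  mode = "SATURATION", fit = fit)
}

#' Fit a competition (heterologous MST) displacement curve
#'
#' Models F_norm along the competitor axis with a monotone log-logistic
#' displacement curve,
#' \deqn{F_{norm}(L) = B + (U - B)\frac{(L/IC_{50})^s}{1 + (L/IC_{50})^s},}
#' running from the bound plateau `B` at zero competitor to the unbound
#' plateau `U` at full displacement. Although displacement is 1:1,
#' antibody depletion steepens the competition curve well beyond unit
#' slope whenever the competitor affinity is much tighter than the site
#' concentration, and a fixed unit slope then biases the fitted midpoint
#' low; conversely, for weak competitors the curve genuinely has unit
#' slope and estimating `s` only adds variance. The default
#' `slope = "auto"` therefore fits both the constrained (s = 1) and
#' variable-slope models and keeps the extra parameter only when the
#' extra-sum-of-squares F test supports it at `slope_alpha`. The fitted
#' IC50 is the half-displacement concentration on the total-competitor
#' axis and is converted to Ki separately via [ki_from_ic50()]; see
#' [fit_ki_direct()] for the one-step alternative.
#'
#' @param series A COMPETITION-mode [titration_series()].
#' @param slope `"auto"` (default), `"free"` or `"fixed"` (s = 1).
#' @param slope_alpha Significance level of the F test used by
#'   `slope = "auto"` (default 0.05).
#' @return A `binding_fit` with the IC50 estimate (nM). If the IC50 falls
#'   outside the titrated concentration range the result carries an
#'   `"EXTRAPOLATED_IC50"` flag.
#' @export
fit_competition <- function(series, slope = c("auto", "free", "fixed"),
                            slope_alpha = 0.05) {
  stopifnot(inherits(series, "titration_series"),
            series$mode == "COMPETITION")
  slope <- match.arg(slope)
  pts <- used_points(series)
  d <- data.frame(L = pts$titrant_conc, y = pts$fnorm)
  if (diff(range(d$y)) == 0) {
    stop("flat curve: response amplitude indistinguishable from zero",
         call. = FALSE)
  }
  grid <- exp(seq(log(min(d$L)), log(max(d$L)), length.out = 7))
  fit_fixed <- function() multistart_nls(
    y ~ b + (u - b) * L / (exp(lic) + L),
    data = d,
    make_start = function(g) list(b = d$y[which.min(d$L)],
                                  u = d$y[which.max(d$L)], lic = log(g)),
    grid = grid)
  fit_free <- function() multistart_nls(
    y ~ b + (u - b) * (L / exp(lic))^s / (1 + (L / exp(lic))^s),
    data = d,
    make_start = function(g) list(b = d$y[which.min(d$L)],
                                  u = d$y[which.max(d$L)], lic = log(g),
                                  s = 1),
    grid = grid,
    lower = c(-Inf, -Inf, -Inf, 0.2))
  if (slope == "fixed") {
    fit <- fit_fixed()
  } else if (slope == "free") {
    fit <- fit_free()
    # weakly identified slope (e.g. only one plateau sampled): fall back
    # to the constrained 1:1 displacement shape
    if (is.null(fit)) fit <- fit_fixed()
  } else {
    f0 <- fit_fixed(); f1 <- fit_free()
    if (is.null(f1)) {
      fit <- f0
    } else if (is.null(f0)) {
      fit <- f1
    } else {
      rss0 <- sum(stats::residuals(f0)^2)
      rss1 <- sum(stats::residuals(f1)^2)
      df1 <- nrow(d) - 4
      fstat <- (rss0 - rss1) / (rss1 / max(df1, 1))
      p <- stats::pf(fstat, 1, max(df1, 1), lower.tail = FALSE)
      fit <- if (is.finite(p) && p < slope_alpha || rss1 == 0) f1 else f0
    }
  }
  if (is.null(fit)) stop("competition fit failed from every start",
                         call. = FALSE)
  cf <- stats::coef(fit)
  npar <- length(cf)
  resid_sd <- sqrt(sum(stats::residuals(fit)^2) / max(nrow(d) - npar, 1))
  if (abs(cf[["u"]] - cf[["b"]]) < 3 * resid_sd) {
    stop("flat curve: response amplitude indistinguishable from zero",
         call. = FALSE)
  }
  ic50 <- exp(cf[["lic"]])
  flags <- character(0)
  if (ic50 < min(d$L) || ic50 > max(d$L)) flags <- "EXTRAPOLATED_IC50"
  new_binding_fit(estimate = ic50,
                  fnorm_unbound = cf[["u"]], fnorm_bound = cf[["b"]],
                  ci95 = log_param_ci(fit, "lic"),
                  r2 = r2_of(d$y, stats::fitted(fit)),
                  n_used = nrow(d), converged = TRUE,
                  mode = "COMPETITION", flags = flags, fit = fit)
}

#' Direct ternary-model competition fit
#'
#' One-step alternative to the IC50-then-convert route: fits
#' \deqn{F_{norm}(L) = U + (B - U)\,\frac{T_{bound}(L; I_0, T_0, K_d, K_i)}
#'   {T_0}}
#' with the bound-tracer concentration from the exact
#' [ternary_equilibrium()], estimating `(U, B, log Ki)` by least squares
#' with multi-start on the log Ki grid. Shape-exact, so it has no
#' displacement-curve model mismatch; useful as a cross-check on the
#' two-step route.
#'
#' @param series A COMPETITION-mode [titration_series()] whose
#'   `tracer_kd` is set.
#' @return A `binding_fit` whose `estimate` is Ki (nM).
#' @export
fit_ki_direct <- function(series) {
  stopifnot(inherits(series, "titration_series"),
            series$mode == "COMPETITION")
  if (is.null(series$tracer_kd)) {
    stop("direct ternary fit requires tracer_kd in the series", call. = FALSE)
  }
  pts <- used_points(series)
  d <- data.frame(L = pts$titrant_conc, y = pts$fnorm)
  if (diff(range(d$y)) == 0) {
    stop("flat curve: response amplitude indistinguishable from zero",
         call. = FALSE)
  }
  i0 <- series$antibody_sites; t0 <- series$tracer_total
  kd <- series$tracer_kd
  fb <- function(L, lki) {
    vapply(L, function(l) bound_tracer_at(l, i0, t0, kd, exp(lki)) / t0,
           numeric(1))
  }
  fit <- multistart_nls(
    y ~ u + (b - u) * fb(L, lki),
    data = d,
    make_start = function(g) list(u = d$y[which.max(d$L)],
                                  b = d$y[which.min(d$L)], lki = log(g)),
    grid = c(0.01, 0.1, 1, 10, 100, 1000, 1e4))
  if (is.null(fit)) stop("direct ternary fit failed from every start",
                         call. = FALSE)
  cf <- stats::coef(fit)
  resid_sd <- sqrt(sum(stats::residuals(fit)^2) / max(nrow(d) - 3, 1))
  if (abs(cf[["b"]] - cf[["u"]]) < 3 * resid_sd) {
    stop("flat curve: response amplitude indistinguishable from zero",
         call. = FALSE)
  }
  new_binding_fit(estimate = exp(cf[["lki"]]),
                  fnorm_unbound = cf[["u"]], fnorm_bound = cf[["b"]],
                  ci95 = log_param_ci(fit, "lki"),
                  r2 = r2_of(d$y, stats::fitted(fit)),
                  n_used = nrow(d), converged = TRUE,
                  mode = "COMPETITION", fit = fit)
}

#' Fit a one-phase exponential decay
#'
#' Fits \eqn{Y(t) = (Y_0 - P)\,e^{-kt} + P} by Levenberg-Marquardt least
#' squares. The plateau `P` is fixed at 0 by default (complete
#' degradation); set `plateau = "free"` to estimate it. The half-life is
#' \eqn{t_{1/2} = \ln 2 / k}; its 99% confidence interval is obtained by
#' transforming the asymptotic CI of `k` (a monotone map, so the interval
#' endpoints swap). If the lower CI bound of `k` is non-positive, the
#' upper half-life bound is `Inf`.
#'
#' @param times Time points (h), including t = 0; >= 4 points (>= 2 when
#'   `plateau` is fixed and only `k`, `Y0` are estimated).
#' @param values Measured concentrations or percentages, >= 0.
#' @param plateau `"zero"` (default) or `"free"`.
#' @param conf_level Confidence level for the half-life interval
#'   (default 0.99).
#' @return An object of class `decay_fit` with `k` (1/h), `t_half` (h),
#'   `t_half_ci` (h), `plateau` and `r2`.
#' @export
fit_one_phase_decay <- function(times, values, plateau = c("zero", "free"),
                                conf_level = 0.99) {
  plateau <- match.arg(plateau)
  stopifnot(length(times) == length(values), all(values >= 0))
  if (!any(times == 0)) stop("a t = 0 point is required", call. = FALSE)
  d <- data.frame(t = as.numeric(times), y = as.numeric(values))
  # log-linear start for k (guard against zeros)
  ypos <- pmax(d$y, max(d$y) * 1e-6 + .Machine$double.xmin)
  k0 <- -stats::cov(d$t, log(ypos)) / stats::var(d$t)
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.1
  if (plateau == "zero") {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y0 * exp(-k * t), data = d,
                        start = list(y0 = max(d$y), k = k0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    p_hat <- 0
  } else {
    if (length(times) < 4) stop("free-plateau fit needs >= 4 points",
                                call. = FALSE)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (y0 - p) * exp(-k * t) + p, data = d,
                        start = list(y0 = max(d$y), k = k0, p = min(d$y)),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  }
  if (is.null(fit)) stop("one-phase decay fit failed", call. = FALSE)
  cf <- stats::coef(fit)
  k <- cf[["k"]]
  if (!is.finite(k) || k <= 0) {
    stop("series is not decaying (fitted rate <= 0)", call. = FALSE)
  }
  if (plateau == "free") p_hat <- cf[["p"]]
  sm <- summary(fit)
  se_k <- sm$coefficients["k", "Std. Error"]
  if (is.finite(se_k) && sm$df[2] > 0) {
    q <- stats::qt(1 - (1 - conf_level) / 2, sm$df[2])
    k_ci <- c(k - q * se_k, k + q * se_k)
    t_half_ci <- c(log(2) / k_ci[2],
                   if (k_ci[1] > 0) log(2) / k_ci[1] else Inf)
  } else {
    t_half_ci <- c(NA_real_, NA_real_)  # saturated fit: no residual df
  }
  structure(list(k = k, t_half = log(2) / k, t_half_ci = t_half_ci,
                 conf_level = conf_level, plateau = p_hat,
                 y0 = cf[["y0"]],
                 r2 = r2_of(d$y, stats::fitted(fit)), fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("One-phase decay: k = %.4g /h, t1/2 = %.4g h (%.0f%% CI %.3g-%.3g h), r2 = %.4f\n",
              x$k, x$t_half, 100 * x$conf_level,
              x$t_half_ci[1], x$t_half_ci[2], x$r2))
  invisible(x)
}

#' Coefficient of determination
#'
#' \eqn{r^2 = 1 - \sum(obs - pred)^2 / \sum(obs - \bar{obs})^2}.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 3 values).
#' @return r-squared (can be negative for a fit worse than the mean).
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("r-squared undefined: observed values have zero variance",
                     call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}
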