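#' Fraction of tracer bound in a binary antibody-tracer equilibrium
#'
#' Solves the 1:1 law-of-mass-action equilibrium with explicit ligand
#' depletion. For total binding-site concentration \eqn{A}, total tracer
#' \eqn{T} and dissociation constant \eqn{K_d}, the bound fraction is the
#' physical root of the quadratic
#' \deqn{f = \frac{(A + T + K_d) - \sqrt{(A + T + K_d)^2 - 4AT}}{2T}.}
#' The implementation uses the algebraically equivalent form
#' \eqn{f = 2A / (A + T + K_d + \sqrt{(A+T+K_d)^2 - 4AT})}, which avoids
#' catastrophic cancellation when \eqn{A \ll K_d}.
#'
#' @param ab_total Total antibody binding-site concentration (nM). Note:
#'   sites, not IgG molecules; an intact IgG carries two sites.
#' @param tracer_total Total tracer concentration (nM); must be > 0.
#' @param kd Dissociation constant (nM); must be > 0.
#' @return Fraction of tracer bound, in \[0, 1\]. Vectorised over
#'   `ab_total`.
#' @examples
#' binary_bound_fraction(0, 0.25, 5)              # no antibody -> 0
#' binary_bound_fraction(5, 1e-9 * 5, 5)          # trace tracer at A = Kd -> 0.5
#' @export
binary_bound_fraction <- function(ab_total, tracer_total, kd) {
  stopifnot(is.numeric(ab_total), is.numeric(tracer_total), is.numeric(kd))
  if (any(tracer_total <= 0)) {
    stop("degenerate system: tracer_total must be > 0", call. = FALSE)
  }
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(ab_total < 0)) stop("ab_total must be >= 0", call. = FALSE)
  s <- ab_total + tracer_total + kd
  disc <- sqrt(pmax(s^2 - 4 * ab_total * tracer_total, 0))
  f <- 2 * ab_total / (s + disc)
  pmin(pmax(f, 0), 1)
}

#' Construct a ternary competitive-binding system
#'
#' Bundles the five quantities that define a one-site, two-ligand
#' competitive equilibrium: total antibody binding sites `i0`, total
#' labeled tracer `t0`, total unlabeled competitor `l0`, the tracer
#' dissociation constant `kd` and the competitor dissociation constant
#' `ki`. All concentrations are nM.
#'
#' @param i0,t0,l0 Total concentrations (nM), all >= 0.
#' @param kd,ki Dissociation constants (nM), both > 0.
#' @return An object of class `ternary_system`.
#' @export
ternary_system <- function(i0, t0, l0, kd, ki) {
  stopifnot(length(i0) == 1, length(t0) == 1, length(l0) == 1,
            length(kd) == 1, length(ki) == 1)
  if (i0 < 0 || t0 < 0 || l0 < 0) {
    stop("total concentrations must be >= 0", call. = FALSE)
  }
  if (kd <= 0 || ki <= 0) stop("kd and ki must be > 0", call. = FALSE)
  structure(list(i0 = i0, t0 = t0, l0 = l0, kd = kd, ki = ki),
            class = "ternary_system")
}

#' @export
print.ternary_system <- function(x, ...) {
  cat("Ternary competitive-binding system (nM):\n")
  cat(sprintf("  sites I0 = %g, tracer T0 = %g, competitor L0 = %g\n",
              x$i0, x$t0, x$l0))
  cat(sprintf("  Kd(tracer) = %g, Ki(competitor) = %g\n", x$kd, x$ki))
  invisible(x)
}

#' Exact equilibrium of a one-site, two-ligand competitive system
#'
#' Two ligands (tracer, competitor) compete for a single class of antibody
#' binding sites. Writing `F` for free sites, mass action gives free tracer
#' `t0 / (1 + F/kd)` and free competitor `l0 / (1 + F/ki)`, so the site
#' balance reduces to a single monotone equation in `F`:
#' \deqn{F + \frac{t_0 F}{K_d + F} + \frac{l_0 F}{K_i + F} = I_0,}
#' solved by bracketed root-finding on \[0, i0\] to a relative tolerance of
#' 1e-10. The left side is strictly increasing in `F`, so the physical root
#' is unique and bracketing cannot fail.
#'
#' @param sys A [ternary_system()].
#' @return A list of class `equilibrium_state` with components
#'   `free_sites`, `free_tracer`, `bound_tracer`, `free_competitor`,
#'   `bound_competitor` (all nM).
#' @export
ternary_equilibrium <- function(sys) {
  stopifnot(inherits(sys, "ternary_system"))
  i0 <- sys$i0; t0 <- sys$t0; l0 <- sys$l0; kd <- sys$kd; ki <- sys$ki
  if (i0 == 0) {
    fs <- 0
  } else {
    g <- function(f) f + t0 * f / (kd + f) + l0 * f / (ki + f) - i0
    fs <- stats::uniroot(g, lower = 0, upper = i0,
                         tol = max(1e-10 * i0, 1e-300),
                         maxiter = 1000L)$root
    # polish by one Newton step pair to push residual to machine precision
    for (it in 1:3) {
      gv <- g(fs)
      dg <- 1 + t0 * kd / (kd + fs)^2 + l0 * ki / (ki + fs)^2
      fs <- min(max(fs - gv / dg, 0), i0)
    }
  }
  # both species split in cancellation-free form: free + bound == total
  structure(list(
    free_sites = fs,
    free_tracer = t0 * kd / (kd + fs),
    bound_tracer = t0 * fs / (kd + fs),
    free_competitor = l0 * ki / (ki + fs),
    bound_competitor = l0 * fs / (ki + fs)
  ), class = "equilibrium_state")
}

# bound tracer (nM) as a function of total competitor, all else fixed
bound_tracer_at <- function(l0, i0, t0, kd, ki) {
  ternary_equilibrium(ternary_system(i0, t0, l0, kd, ki))$bound_tracer
}

#' Total competitor concentration at half-maximal tracer displacement
#'
#' The IC50 is defined on the total competitor concentration: it is the `L`
#' at which the bound-tracer concentration is midway between its
#' zero-competitor value and its infinite-competitor limit (zero bound
#' tracer for any finite `ki`). Bound tracer is strictly decreasing in `L`,
#' so the half-point is found by monotone bracketed root-finding on
#' `log L`.
#'
#' @param i0,t0 Total binding sites and tracer (nM), > 0.
#' @param kd Tracer dissociation constant (nM), > 0.
#' @param ki Competitor dissociation constant (nM), > 0.
#' @return The IC50 (nM, total competitor).
#' @seealso [ki_from_ic50()] for the inverse map.
#' @export
ic50_from_ki <- function(ki, kd, i0, t0) {
  stopifnot(ki > 0, kd > 0, i0 > 0, t0 > 0)
  b0 <- bound_tracer_at(0, i0, t0, kd, ki)
  if (b0 <= 0) stop("no tracer is bound at zero competitor; IC50 undefined",
                    call. = FALSE)
  target <- b0 / 2
  h <- function(logl) bound_tracer_at(exp(logl), i0, t0, kd, ki) - target
  # expand the upper bracket geometrically; displacement is monotone in L
  lo <- log(1e-9)
  hi <- log(max(ki, kd, i0, t0))
  while (h(hi) > 0 && hi < log(1e15)) hi <- hi + log(10)
  if (h(hi) > 0) stop("IC50 bracket expansion failed", call. = FALSE)
  r <- stats::uniroot(h, lower = lo, upper = hi, tol = 1e-12, maxiter = 1000L)
  exp(r$root)
}

#' Competitor dissociation constant from a measured IC50
#'
#' Inverts the exact ternary-equilibrium IC50 map: given the tracer
#' affinity `kd`, the assay's total site (`i0`) and tracer (`t0`)
#' concentrations, the top competitor concentration of the titration
#' (`l0`) and the fitted `ic50`, finds the unique `ki` such that
#' [ic50_from_ki()] reproduces the measurement. This mirrors the two-step
#' competition-MST workflow in which a fitted IC50 plus the assay design
#' constants yield the competitor affinity. Solved by root-finding on
#' `log ki` over \[1e-6, 1e9\] nM.
#'
#' @param ic50 Measured half-displacement concentration (nM, total
#'   competitor).
#' @param kd Tracer dissociation constant (nM).
#' @param i0,t0 Total binding sites and tracer (nM).
#' @param l0 Highest total competitor concentration in the titration (nM);
#'   the IC50 must lie inside the titrated range for `ki` to be
#'   identifiable.
#' @return The competitor dissociation constant `ki` (nM).
#' @export
ki_from_ic50 <- function(ic50, kd, i0, t0, l0) {
  stopifnot(ic50 > 0, kd > 0, i0 > 0, t0 > 0, l0 > 0)
  if (ic50 > l0) {
    stop("ic50 exceeds the highest titrated competitor concentration; ",
         "Ki is not identifiable from this design", call. = FALSE)
  }
  obj <- function(logki) log(ic50_from_ki(exp(logki), kd, i0, t0)) - log(ic50)
  lo <- log(1e-6); hi <- log(1e9)
  flo <- obj(lo); fhi <- obj(hi)
  if (flo > 0 || fhi < 0) {
    stop("no sign change in the Ki bracket [1e-6, 1e9] nM", call. = FALSE)
  }
  r <- stats::uniroot(obj, lower = lo, upper = hi, tol = 1e-10,
                      maxiter = 1000L)
  exp(r$root)
}

#' Antibody binding-site concentration from Mueller's equation
#'
#' Given the fraction `b` of tracer bound at equilibrium in the absence of
#' competitor, the total tracer concentration and the dissociation
#' constant, the total binding-site concentration is
#' \deqn{[Ab_t] = b\,[T_t] + \frac{b\,K_d}{1 - b}.}
#' This is the exact algebraic inverse of the 1:1 depletion isotherm: the
#' first term is the bound (site-occupying) tracer, the second is the free
#' site concentration implied by mass action.
#'
#' @param b Fraction of bound tracer, in \[0, 1).
#' @param tracer_total Total tracer concentration at equilibrium (nM).
#' @param kd Dissociation constant (nM).
#' @return Total binding-site concentration (nM).
#' @export
mueller_binding_sites <- function(b, tracer_total, kd) {
  stopifnot(is.numeric(b), is.numeric(tracer_total), is.numeric(kd))
  if (any(b < 0 | b >= 1)) {
    stop("b must lie in [0, 1)", call. = FALSE)
  }
  b * tracer_total + b * kd / (1 - b)
}

#' Average binding-site concentration across tracer estimates
#'
#' Polyclonal site concentrations are estimated independently with each
#' tracer (e.g. deuterated 6-AM and morphine) and averaged.
#'
#' @param estimates Numeric vector of binding-site concentrations (nM);
#'   must be non-empty.
#' @return Arithmetic mean (nM).
#' @export
average_binding_sites <- function(estimates) {
  if (length(estimates) == 0) stop("no binding-site estimates supplied",
                                   call. = FALSE)
  mean(as.numeric(estimates))
}
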