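# Independent brute-force oracles. These deliberately re-derive the
# equilibria from the coupled mass-action equations by bisection on a
# different unknown (free tracer) than the package solver uses (free
# sites), so agreement is a genuine cross-check.

# ternary competitive equilibrium: bisection on bound tracer Bt in
# [0, min(t0, i0))
oracle_ternary_bound_tracer <- function(i0, t0, l0, kd, ki, iters = 200) {
  if (i0 == 0 || t0 == 0) return(0)
  resid <- function(bt) {
    f <- kd * bt / (t0 - bt)              # free sites from tracer mass action
    bl <- l0 * f / (ki + f)               # bound competitor
    f + bt + bl - i0                      # site balance
  }
  lo <- 0; hi <- min(t0 * (1 - 1e-15), i0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# two-chamber dialysis without competitor: bisection on uniform free
# tracer concentration; masses in nM * uL
oracle_dialysis_b <- function(ab, kd, tracer0, vs, vb, iters = 200) {
  mt <- tracer0 * vs
  resid <- function(tf) {
    bound <- (mt - tf * (vs + vb)) / vs   # bound conc in sample chamber
    fsites <- ab - bound                  # site balance
    fsites * tf - kd * bound              # mass-action residual
  }
  lo <- 0; hi <- mt / (vs + vb)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  tf <- (lo + hi) / 2
  bound <- (mt - tf * (vs + vb)) / vs
  bound / (bound + tf)
}

# exact Cheng-Prusoff IC50 in the negligible-depletion limit
cheng_prusoff_ic50 <- function(ki, kd, t0) ki * (1 + t0 / kd)

# standard polyclonal competition design used across tests
standard_competition_design <- function(top_working = 16000) {
  titration_design(top_working_conc = top_working, tracer_final = 0.25,
                   antibody_sites_final = 10)
}

noiseless <- function(...) trace_noise_model(noise_cv = 0, ...)
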