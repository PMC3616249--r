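# Independent oracles: direct arithmetic evaluation of the circuit formulas,
# kept free of any package code so they can vouch for it.

# From-closed admittance change with T^2 = 1, SI units; returns c(dRe, dIm).
oracle_from_closed <- function(cv, gp, f = 1591) {
  a <- 2 * pi * f * cv
  if (is.infinite(gp)) return(c(0, a))
  if (gp == 0) return(c(0, 0))
  c(a^2 * gp / (gp^2 + a^2), a * gp^2 / (gp^2 + a^2))
}

# Two-state step: difference of two from-closed evaluations.
oracle_step <- function(cv, gp_pre, gp_open, f = 1591) {
  oracle_from_closed(cv, gp_open, f) - oracle_from_closed(cv, gp_pre, f)
}

# Circuit factor by direct complex arithmetic.
oracle_t2 <- function(ra, gm, cm, f) {
  1 / (1 + ra * gm + 1i * 2 * pi * f * cm * ra)^2
}

# Grid-search argmax of the real part over Gp (pS), 0.001 pS resolution.
oracle_re_argmax_pS <- function(cv, f = 1591, gp_max_pS = 1000) {
  gp <- seq(0.001, gp_max_pS, by = 0.001) * 1e-12
  a <- 2 * pi * f * cv
  dre <- a^2 * gp / (gp^2 + a^2)
  gp[which.max(dre)] / 1e-12
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.xmin),
            tol)
}
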