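test_that("T^2 factor matches direct complex evaluation and its limits", {
  # R_A = 0: identity, zero phase, regardless of the other constants
  p0 <- circuit_params(0, 1e-9, 5e-12, 1591)
  expect_identical(t_squared(p0), 1 + 0i)
  expect_identical(p0$theta, 0)

  # attenuated, rotated case vs an independent evaluation
  p <- circuit_params(10e6, 1e-9, 5e-12, 1591)
  ref <- oracle_t2(10e6, 1e-9, 5e-12, 1591)
  expect_rel_equal(Mod(t_squared(p)), Mod(ref), 1e-12)
  expect_rel_equal(p$theta, Arg(ref), 1e-12)
  expect_lte(Mod(t_squared(p)), 1)

  expect_error(circuit_params(-1), "access_resistance")
})

test_that("from-closed admittance change reproduces the forward model", {
  p <- circuit_params()  # T^2 = 1, 1591 Hz
  a <- p$omega * fF(0.5)

  # fully open limit: dRe = 0, dY = i omega Cv (~5 pS)
  d_open <- admittance_from_closed(fF(0.5), fully_open = TRUE, params = p)
  expect_identical(d_open$d_re, 0)
  expect_equal(d_open$d_im, a)
  expect_rel_equal(as_pS(d_open$d_im), 4.998274, 1e-6)

  # symmetry point Gp = omega Cv: both components = omega Cv / 2
  d_sym <- admittance_from_closed(fF(0.5), a, params = p)
  expect_equal(d_sym$d_re, a / 2, tolerance = 1e-12)
  expect_equal(d_sym$d_im, a / 2, tolerance = 1e-12)

  # incomplete opening at 30 pS vs frozen oracle values
  d30 <- admittance_from_closed(fF(0.5), pS(30), params = p)
  expect_rel_equal(as_pS(d30$d_re), 0.8102662, 1e-6)
  expect_rel_equal(as_pS(d30$d_im), 4.8632762, 1e-6)

  # Gp = 0: analytic limit, not a division
  d0 <- admittance_from_closed(fF(0.5), 0, params = p)
  expect_identical(c(d0$d_re, d0$d_im), c(0, 0))

  # numerical limit agreement at extreme conductances
  d_hi <- admittance_from_closed(fF(0.5), pS(1e6), params = p)
  expect_rel_equal(d_hi$d_im, a, 1e-6)
  expect_lt(abs(d_hi$d_re), 1e-5 * a)
  d_lo <- admittance_from_closed(fF(0.5), pS(1e-6), params = p)
  expect_lt(abs(d_lo$d_re), 1e-6 * a)
  expect_lt(abs(d_lo$d_im), 1e-6 * a)
})

test_that("dIm is monotone in Gp and dRe peaks at omega Cv", {
  p <- circuit_params()
  for (cv in fF(c(0.3, 1.2, 4))) {
    a <- p$omega * cv
    gp <- pS(seq(0.5, 200, by = 0.5))
    d <- sapply(gp, function(g) {
      x <- admittance_from_closed(cv, g, params = p)
      c(x$d_re, x$d_im)
    })
    expect_true(all(diff(d[2, ]) > 0))  # dIm strictly increasing
    below <- gp < a
    above <- gp > a
    expect_true(all(diff(d[1, below]) > 0))
    expect_true(all(diff(d[1, above]) < 0))
  }
})

test_that("argmax conductance is omega Cv, matching grid search and ~5 pS", {
  p <- circuit_params()
  expect_identical(re_argmax_conductance(fF(0.5), p), p$omega * fF(0.5))
  # printed small-vesicle anchor: ~5 pS at 0.5 fF, 1591 Hz
  expect_equal(as_pS(re_argmax_conductance(fF(0.5), p)), 5, tolerance = 5e-3)
  # independent grid-search oracle at another size
  expect_equal(as_pS(re_argmax_conductance(fF(1.2), p)),
               oracle_re_argmax_pS(fF(1.2)), tolerance = 1e-3)
})

test_that("two-state steps obey the (omega Cv)^2 vs Gp_pre*Gp_open sign rule", {
  p <- circuit_params()

  # identity: no conductance change, no step
  d_id <- step_between_states(pore_state(fF(1), pS(10), pS(10)), p)
  expect_identical(c(d_id$d_re, d_id$d_im), c(0, 0))

  # frozen two-state anchors: small vesicle decremental, large incremental
  d_small <- step_between_states(pore_state(fF(0.5), pS(5), pS(30)), p)
  expect_rel_equal(as_pS(d_small$d_re), -1.688871, 1e-6)
  expect_rel_equal(as_pS(d_small$d_im), 2.363276, 1e-6)
  d_big <- step_between_states(pore_state(fF(4), pS(5), pS(30)), p)
  expect_rel_equal(as_pS(d_big$d_re), 14.2722, 1e-5)
  expect_rel_equal(as_pS(d_big$d_im), 13.7858, 1e-5)

  # sign boundary across a parameter grid, vs the independent oracle
  for (cv in fF(c(0.2, 0.5, 1, 2, 4))) {
    for (pre in pS(c(1, 5, 10))) {
      for (open in pS(c(15, 30, 80))) {
        d <- step_between_states(pore_state(cv, pre, open), p)
        ref <- oracle_step(cv, pre, open)
        expect_rel_equal(d$d_re, ref[1], 1e-9)
        expect_rel_equal(d$d_im, ref[2], 1e-9)
        expect_identical(sign(d$d_re), sign((p$omega * cv)^2 - pre * open))
      }
    }
  }
})

test_that("a real rescaling of T^2 scales both step components identically", {
  # R_A * G_M = 1 with negligible capacitive term gives T^2 = 1/4, real
  p1 <- circuit_params()
  p4 <- circuit_params(access_resistance = 1e6, membrane_conductance = 1e-6,
                       membrane_capacitance = 0)
  expect_equal(t_squared(p4), 0.25 + 0i)
  for (gp in pS(c(3, 30, 300))) {
    d1 <- admittance_from_closed(fF(0.8), gp, params = p1)
    d4 <- admittance_from_closed(fF(0.8), gp, params = p4)
    expect_rel_equal(d4$d_re, 0.25 * d1$d_re, 1e-12)
    expect_rel_equal(d4$d_im, 0.25 * d1$d_im, 1e-12)
  }
})

test_that("admittance_curve tabulates and exports the Gp sweep", {
  tab <- admittance_curve(fF(c(0.5, 4)), gp = pS(c(5, 30)))
  expect_equal(nrow(tab), 4)
  ref <- oracle_from_closed(fF(0.5), pS(30))
  expect_rel_equal(tab$d_re_pS[tab$cv_fF == 0.5 & tab$gp_pS == 30],
                   as_pS(ref[1]), 1e-9)
  f <- tempfile(fileext = ".csv")
  admittance_curve(fF(0.5), gp = pS(c(5, 30)), file = f)
  expect_equal(utils::read.csv(f)$gp_pS, c(5, 30))
})
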