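test_that("the case rule follows the Re projection sign and floor", {
  w <- 2 * pi * 1591
  expect_identical(classify_event(admittance_delta(0, pS(3), w)), "I")
  expect_identical(classify_event(admittance_delta(pS(0.1), pS(3), w),
                                  epsilon_re = pS(0.2)), "I")
  expect_identical(classify_event(admittance_delta(pS(1), pS(3), w)), "II")
  expect_identical(classify_event(admittance_delta(-pS(1), pS(3), w)), "III")
  expect_error(classify_event(admittance_delta(pS(1), -pS(1), w)), "on-step")

  # forward-model sign oracle: same conductance change, opposite projections
  d_small <- step_between_states(pore_state(fF(0.5), pS(5), pS(30)))
  d_big <- step_between_states(pore_state(fF(4), pS(5), pS(30)))
  expect_identical(classify_event(d_small), "III")
  expect_identical(classify_event(d_big), "II")
})

test_that("summaries conserve counts and compute per-case correlations", {
  empty <- summarize_events(data.frame())
  expect_s3_class(empty, "summary_report")
  expect_equal(empty$n_events, 0)
  expect_true(all(is.na(empty$correlations$pearson_r)))

  # three collinear case II events: r exactly 1
  ev <- data.frame(case = "II", d_re_pS = c(1, 2, 3),
                   d_im_pS = c(2, 4, 6), cell_type = "lactotroph")
  rep1 <- summarize_events(ev)
  expect_equal(rep1$correlations$pearson_r[rep1$correlations$case == "II"], 1,
               tolerance = 1e-12)
  expect_equal(rep1$correlations$slope[rep1$correlations$case == "II"], 2,
               tolerance = 1e-12)
  expect_equal(sum(rep1$counts), rep1$n_events)

  # singleton groups report NA, never crash
  ev2 <- rbind(ev, data.frame(case = "III", d_re_pS = -1, d_im_pS = 1,
                              cell_type = "astrocyte"))
  rep2 <- summarize_events(ev2)
  expect_true(is.na(rep2$correlations$pearson_r[rep2$correlations$case == "III"]))
  expect_equal(sum(rep2$counts), 4)
})

test_that("case II events from a shared state change correlate tightly", {
  # one fixed opening (closed -> 30 pS); Cv varies below the dIm turnover
  # (omega Cv < Gp), where both components grow together with vesicle size
  set.seed(31)
  cv <- fF(exp(rnorm(40, log(1), 0.3)))
  d <- t(vapply(cv, function(x) {
    s <- step_between_states(pore_state(x, 0, pS(30)))
    c(s$d_re, s$d_im)
  }, numeric(2)))
  expect_true(all(d[, 1] > 0))
  expect_gt(cor(d[, 1], d[, 2]), 0.9)
})

test_that("incremental events correlate more tightly than decremental ones", {
  prof <- cell_profile("astrocyte")
  wins <- vapply(1:20, function(s) {
    r_of <- function(case, seed) {
      ps <- sample_pore_states(prof, 50, seed = seed, case = case)
      d <- t(vapply(ps, function(p) {
        x <- step_between_states(p)
        c(x$d_re, x$d_im)
      }, numeric(2)))
      stats::cor(d[, 1], d[, 2])
    }
    r_of("II", s) > r_of("III", s + 1000)
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("case III events are smaller vesicles than case II events", {
  # shared conductance ranges; only the vesicle size decides the sign
  prof <- cell_profile("custom", case_mix = c(0, 0.5, 0.5))
  ps <- sample_pore_states(prof, 250, seed = 13)
  cv <- vapply(ps, `[[`, numeric(1), "vesicle_capacitance")
  case <- vapply(ps, attr, character(1), "case")
  expect_gte(sum(case == "II"), 50)
  expect_gte(sum(case == "III"), 50)
  expect_lt(median(cv[case == "III"]), median(cv[case == "II"]))
})

test_that("the pipeline reproduces ground truth and is deterministic", {
  cfg <- sim_config(duration = 200, seed = 17)
  ev <- sample_cell_events(cell_profile("astrocyte"), 12, 200, seed = 17,
                           config = cfg)
  tr <- generate_trace(cfg, ev)
  res <- run_pipeline(tr, cell_type = "astrocyte")
  expect_equal(nrow(res$events), 12)
  expect_identical(res$events$case, tr$ground_truth$case)
  expect_equal(res$events$d_im_pS, tr$ground_truth$d_im_pS,
               tolerance = 1e-9)
  # Cv and Gp recovery holds where the inversion's from-closed assumption
  # does (gp_pre = 0); two-state (case III) estimates are knowingly biased
  # and flagged not applicable
  fc0 <- tr$ground_truth$gp_pre_pS == 0
  expect_equal(res$events$cv_fF[fc0], tr$ground_truth$cv_fF[fc0],
               tolerance = 1e-9)
  fc <- fc0 & is.finite(tr$ground_truth$gp_open_pS)
  expect_equal(res$events$gp_pS[fc], tr$ground_truth$gp_open_pS[fc],
               tolerance = 1e-6)
  expect_true(all(!res$events$applicable[res$events$case == "III"]))
  expect_equal(sum(res$report$counts), nrow(res$events))

  # rerun: identical outputs
  res2 <- run_pipeline(tr, cell_type = "astrocyte")
  expect_identical(res$events, res2$events)

  # file outputs are written and consistent
  prefix <- tempfile()
  paths <- write_pipeline_result(res, prefix)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(utils::read.csv(paths[1])), 12)
})

test_that("an eventless trace yields an empty, schema-valid report", {
  res <- run_pipeline(generate_trace(sim_config(duration = 30, seed = 1)))
  expect_equal(nrow(res$events), 0)
  expect_equal(res$report$n_events, 0)
  expect_named(res$events,
               c("event_id", "t_on", "t_off", "d_im_pS", "d_re_pS", "cv_fF",
                 "gp_pS", "fully_open", "applicable", "case", "cell_type"))
  # even without calibration pulses the pipeline degrades gracefully
  res2 <- run_pipeline(generate_trace(sim_config(duration = 8, seed = 1)))
  expect_equal(res2$report$n_events, 0)
  expect_identical(res2$provenance$theta, 0)
})
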