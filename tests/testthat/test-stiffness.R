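test_that("pairing indexes force at frame times and trims to the loading phase", {
  # frame rate equal to force rate -> identity pairing over the ramp
  f <- c(rep(0, 10), seq(0, 1000, by = 10), rep(1000, 5))
  tr <- force_trace(f, 1000, trigger_index = 11)
  el <- structure(list(values = seq_along(f[11:length(f)]) * 0.01 - 0.01,
                       status = rep(TRUE, length(f) - 10)),
                  class = "elongation_series")
  p <- pair_force_elongation(tr, el, frame_rate = 1000)
  i_peak <- which.max(f[11:length(f)])
  expect_equal(max(p$force), 1000)
  expect_equal(p$force, f[10 + (which(f[11:length(f)] >= 50)[1]):i_peak])
  # frames running past the record are rejected
  el_long <- structure(list(values = rep(0, length(f) + 5),
                            status = rep(TRUE, length(f) + 5)),
                       class = "elongation_series")
  expect_error(pair_force_elongation(tr, el_long, 1000), "past the end")
})

test_that("noise-free synthetic pairs lie on the generating curve", {
  s <- synth_tracked_trial(seed = 31, peak_moment = 70)
  e_true <- invert_curve(s$trial$force, 200, 500)
  expect_lt(max(abs(s$trial$elongation - e_true)), 0.02)
})

test_that("quadratic data are fitted exactly and white noise is excluded", {
  e <- seq(0, 3, length.out = 60)
  f <- 150 * e^2 + 600 * e
  tr <- fit_trial(fe_trial(f, e))
  expect_equal(tr$r2, 1, tolerance = 1e-6)
  expect_equal(unname(tr$fit[c("A", "B")]), c(150, 600), tolerance = 1e-3)
  expect_lt(abs(tr$fit[["C"]]), 0.5)
  expect_true(tr$included)

  noise <- fit_trial(fe_trial(seq(0, 3000, length.out = 80),
                              with_seed(5, stats::rnorm(80))))
  expect_lt(noise$r2, 0.5)
  expect_false(noise$included)
})

test_that("inclusion threshold is a strict lower bound at 0.90", {
  expect_true(trial_included(0.90))
  expect_false(trial_included(0.89))
  expect_true(trial_included(0.95))
  expect_false(trial_included(0.90 - 1e-12))
})

test_that("degenerate and undersized trials are rejected", {
  expect_error(fit_trial(fe_trial(rep(100, 20), seq(0, 1, length.out = 20))),
               "constant")
  expect_error(fit_trial(fe_trial(1:5, 1:5)), "at least 10")
})

test_that("common force is the lowest included peak across sessions", {
  expect_equal(common_force(c(3000, 3200), 3500), 3000)
  expect_equal(common_force(2500, 2500), 2500)
  expect_error(common_force(numeric(0), 3000), "no included trials")
})

test_that("mean curve averages fitted trials on the common-force grid", {
  e <- seq(0, 3, length.out = 50)
  t1 <- fit_trial(fe_trial(150 * e^2 + 600 * e, e))
  mc1 <- mean_curve(list(t1), 2000)
  # single trial: curve equals that trial's fit, i.e. F(e(F)) = F
  expect_equal(t1$fit[["A"]] * mc1$elongation^2 +
                 t1$fit[["B"]] * mc1$elongation + t1$fit[["C"]],
               mc1$force_grid, tolerance = 1e-6)
  # duplicated trial changes nothing
  mc2 <- mean_curve(list(t1, t1), 2000)
  expect_equal(mc2$elongation, mc1$elongation)
  expect_equal(mc2$n_trials, 2)
  # trials with symmetric noise average toward the truth
  set.seed(9)
  noisy <- lapply(1:40, function(i) {
    fit_trial(fe_trial(150 * e^2 + 600 * e, e + rnorm(50, 0, 0.05)))
  })
  mcn <- mean_curve(noisy, 2000)
  expect_lt(max(abs(mcn$elongation - mc1$elongation)), 0.02)
})

test_that("stiffness is the 60-100 % OLS slope, matching the dense oracle", {
  # linear law: slope equals b exactly
  e <- seq(0, 3, length.out = 50)
  lin <- fit_trial(fe_trial(1000 * e, e))
  st <- stiffness_slope(mean_curve(list(lin), 2500))
  expect_equal(st$stiffness, 1000, tolerance = 1e-6)
  expect_equal(st$analysis_range, c(1500, 2500))

  # stiffening law vs brute-force analytic oracle
  quad <- fit_trial(fe_trial(200 * e^2 + 500 * e, e))
  st2 <- stiffness_slope(mean_curve(list(quad), 2000))
  expect_equal(st2$stiffness, oracle_slope(200, 500, 2000), tolerance = 0.01)

  # scaling elongation by 2 halves the stiffness
  half <- fit_trial(fe_trial(200 * e^2 + 500 * e, 2 * e))
  st3 <- stiffness_slope(mean_curve(list(half), 2000))
  expect_equal(st3$stiffness, st2$stiffness / 2, tolerance = 1e-6)
})

test_that("stiffening curves are steeper over 60-100 % than the full chord", {
  e <- seq(0, 3, length.out = 80)
  quad <- fit_trial(fe_trial(300 * e^2 + 400 * e, e))
  mc <- mean_curve(list(quad), 2500)
  st <- stiffness_slope(mc)
  chord <- mc$common_force / mc$elongation[length(mc$elongation)]
  expect_gt(st$stiffness, chord)
})

test_that("raising the R2 threshold never admits more trials", {
  set.seed(12)
  e <- seq(0, 3, length.out = 60)
  trials <- lapply(1:20, function(i) {
    fe_trial(200 * e^2 + 500 * e + rnorm(60, 0, i * 30), e)
  })
  n_inc <- vapply(c(0.5, 0.8, 0.9, 0.99), function(th) {
    sum(vapply(trials, function(tr) fit_trial(tr, r2_min = th)$included,
               logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_inc) <= 0))
})

test_that("non-monotonic mean curves are flagged", {
  mc <- structure(list(force_grid = seq(0, 1000, length.out = 100),
                       elongation = sin(seq(0, 6 * pi, length.out = 100)),
                       common_force = 1000, n_trials = 1),
                  class = "mean_curve")
  expect_true(stiffness_slope(mc)$flagged)
})
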