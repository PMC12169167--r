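toy_2way <- function() {
  # n = 3 per group, values chosen by hand
  data.frame(
    participant = rep(sprintf("S%d", 1:6), each = 2),
    group = rep(c("OC", "OC", "OC", "NOC", "NOC", "NOC"), each = 2),
    time = rep(c("pre", "post"), times = 6),
    outcome = c(10, 14, 12, 15, 11, 16,   # OC
                9, 17, 13, 19, 12, 18))   # NOC
}

test_that("two-way mixed ANOVA matches the aov error-strata oracle", {
  d <- toy_2way()
  res <- mixed_anova_2way(d)
  o <- aov_oracle_2way(d)
  expect_equal(anova_stat(res, "group", "F"), o$F_group, tolerance = 1e-8)
  expect_equal(anova_stat(res, "time", "F"), o$F_time, tolerance = 1e-8)
  expect_equal(anova_stat(res, "time:group", "F"), o$F_tg, tolerance = 1e-8)
  expect_equal(anova_stat(res, "time", "p"), o$p_time, tolerance = 1e-8)
  expect_equal(anova_stat(res, "time", "ss"), o$ss_time, tolerance = 1e-8)
  expect_equal(anova_stat(res, "subjects_within_group", "ss"), o$ss_subj,
               tolerance = 1e-8)
  # partial eta squared definition
  expect_equal(anova_stat(res, "time", "partial_eta_squared"),
               o$ss_time / (o$ss_time + o$ss_werr), tolerance = 1e-10)
})

test_that("two-way ANOVA matches aov on unbalanced random cohorts", {
  for (seed in c(101, 202)) {
    d <- with_seed(seed, random_cohort_2way(seed, n1 = 6L, n2 = 9L))
    res <- mixed_anova_2way(d)
    o <- aov_oracle_2way(d)
    expect_equal(anova_stat(res, "group", "F"), o$F_group, tolerance = 1e-8)
    expect_equal(anova_stat(res, "time", "F"), o$F_time, tolerance = 1e-8)
    expect_equal(anova_stat(res, "time:group", "F"), o$F_tg, tolerance = 1e-8)
  }
})

test_that("three-way mixed ANOVA matches aov on balanced and unbalanced designs", {
  for (np in list(c(4L, 4L), c(4L, 6L))) {
    d <- generate_cohort(cohort_spec(
      n_per_group = np, training_effect = 4, interaction_effect = 2,
      sd_between = 6, sd_within = 3, n_locations = 3,
      location_offsets = c(2, 0, -2), seed = 7 + np[2]))
    res <- mixed_anova_3way(d)
    o <- aov_oracle_3way(d)
    expect_equal(anova_stat(res, "group", "F"), o$F_group, tolerance = 1e-8)
    expect_equal(anova_stat(res, "time", "F"), o$F_time, tolerance = 1e-8)
    expect_equal(anova_stat(res, "time:group", "F"), o$F_tg, tolerance = 1e-8)
    expect_equal(anova_stat(res, "location", "F"), o$F_loc, tolerance = 1e-8)
    expect_equal(anova_stat(res, "location:group", "F"), o$F_lg,
                 tolerance = 1e-8)
    expect_equal(anova_stat(res, "time:location", "F"), o$F_tl,
                 tolerance = 1e-8)
    expect_equal(anova_stat(res, "time:location:group", "F"), o$F_tlg,
                 tolerance = 1e-8)
  }
})

test_that("sums of squares are conserved over all strata", {
  for (seed in 1:50) {
    d <- with_seed(1000 + seed, random_cohort_2way(1000 + seed))
    res <- mixed_anova_2way(d)
    expect_equal(sum(res$table$ss), sum((d$outcome - mean(d$outcome))^2),
                 tolerance = 1e-8)
  }
  for (seed in 1:50) {
    d <- generate_cohort(cohort_spec(
      n_per_group = c(4, 5), training_effect = stats::runif(1, -3, 3),
      sd_between = 5, sd_within = 2, n_locations = 3,
      location_offsets = c(1, 0, -1), seed = 2000 + seed))
    res <- mixed_anova_3way(d)
    expect_equal(sum(res$table$ss), sum((d$outcome - mean(d$outcome))^2),
                 tolerance = 1e-8)
  }
})

test_that("programmed zero effects yield exactly zero SS components", {
  d <- generate_cohort(cohort_spec(n_per_group = c(4, 4), sd_between = 0,
                                   sd_within = 0, training_effect = 7,
                                   interaction_effect = 0, seed = 1))
  res <- mixed_anova_2way(d)
  expect_equal(anova_stat(res, "time:group", "ss"), 0, tolerance = 1e-18)
  expect_gt(anova_stat(res, "time", "ss"), 0)

  d3 <- generate_cohort(cohort_spec(n_per_group = c(4, 4), sd_between = 2,
                                    sd_within = 1, training_effect = 7,
                                    n_locations = 3,
                                    location_offsets = c(0, 0, 0), seed = 2))
  res3 <- mixed_anova_3way(d3)
  # no programmed location effect: SS_location stays at noise level,
  # far below the programmed training SS
  expect_lt(anova_stat(res3, "location", "ss"),
            anova_stat(res3, "time", "ss"))
})

test_that("all-equal outcomes are flagged rather than scored", {
  d <- toy_2way(); d$outcome <- 5
  res <- mixed_anova_2way(d)
  expect_true(res$flagged_zero_variance)
  expect_true(all(is.na(res$table$F[res$table$effect == "time"])))
})

test_that("incomplete participants are excluded and counted", {
  d <- toy_2way()
  d <- d[-2, ]  # S1 loses the post measurement
  res <- mixed_anova_2way(d)
  expect_equal(res$n_included, 5)
  expect_equal(res$n_excluded, 1)
})

test_that("a training effect confined to one location drives time:location", {
  base <- generate_cohort(cohort_spec(
    n_per_group = c(8, 8), training_effect = 0, sd_between = 3,
    sd_within = 1, n_locations = 3, seed = 11))
  sel <- base$time == "post" & base$location == "proximal"
  base$outcome[sel] <- base$outcome[sel] + 6   # large programmed effect
  res <- mixed_anova_3way(base)
  expect_lt(anova_stat(res, "time:location", "p"), 0.05)
  ph <- bonferroni_posthoc(base)
  expect_lt(ph$p_bonferroni[ph$level == "proximal"], 0.05)
  expect_gt(min(ph$p_bonferroni[ph$level != "proximal"]), 0.05)
})

test_that("Bonferroni adjustment multiplies and caps", {
  d <- generate_cohort(cohort_spec(n_per_group = c(5, 5), n_locations = 3,
                                   training_effect = 1, sd_between = 2,
                                   sd_within = 2, seed = 3))
  ph <- bonferroni_posthoc(d)
  expect_equal(ph$n_comparisons, rep(3, 3))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_raw * 3))
  expect_true(all(ph$p_bonferroni <= 1))
})
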