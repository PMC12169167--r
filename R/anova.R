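#' Mixed-design repeated-measures ANOVA
#'
#' Explicit sums-of-squares decompositions for the study's two designs:
#' a between-subject factor `group` (OC/NOC) crossed with the
#' within-subject factor `time` (pre/post), optionally also the
#' within-subject factor `location` (three tendon sites). Each
#' within-subject effect is tested against the error of its own stratum
#' (effect x subjects-within-group); the between-subject effect against
#' subjects-within-group. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error_of_stratum)`.
#'
#' Sums of squares are the classical weighted (sequential-by-stratum)
#' ones, which coincide with all types when the groups are balanced;
#' with unbalanced groups the design still has complete within-subject
#' cells, where type choices matter least. Participants with any missing
#' cell are excluded listwise and counted.
#'
#' @name mixed_anova
NULL

# Complete-case filter: keep participants with exactly one observation
# per within-subject cell. Returns the table plus exclusion count.
complete_cases_cohort <- function(table, within) {
  table$participant <- as.character(table$participant)
  g_per <- tapply(as.character(table$group), table$participant,
                  function(g) length(unique(g)))
  if (any(g_per > 1L)) stopf("a participant appears in more than one group")
  n_cells <- prod(vapply(within, function(v) length(unique(table[[v]])), 1L))
  key <- do.call(paste, c(table[within], sep = "\r"))
  cnt <- tapply(key, table$participant, function(k) {
    length(unique(k)) == n_cells && length(k) == n_cells
  })
  keep <- names(cnt)[cnt]
  list(table = table[table$participant %in% keep, , drop = FALSE],
       n_excluded = sum(!cnt))
}

anova_row <- function(effect, ss, df, ss_err, df_err, stratum) {
  ms <- ss / df; ms_err <- ss_err / df_err
  f <- if (ms_err > 0) ms / ms_err else NA_real_
  p <- if (is.finite(f)) stats::pf(f, df, df_err, lower.tail = FALSE) else NA_real_
  pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else NA_real_
  data.frame(effect = effect, ss = ss, df = df, ms = ms,
             F = f, p = p, partial_eta_squared = pes,
             stratum = stratum, stringsAsFactors = FALSE)
}

error_row <- function(effect, ss, df, stratum) {
  data.frame(effect = effect, ss = ss, df = df, ms = ss / df,
             F = NA_real_, p = NA_real_, partial_eta_squared = NA_real_,
             stratum = stratum, stringsAsFactors = FALSE)
}

#' @rdname mixed_anova
#' @param table long-format data.frame with columns `participant`,
#'   `group`, `time` (and `location` for the three-way design) and
#'   `outcome`.
#' @return an object of class `anova_result`: list with `table` (one
#'   row per effect and error stratum: SS, df, MS, F, p, partial eta
#'   squared), `n_included`, `n_excluded`, `flagged_zero_variance`.
#' @export
mixed_anova_2way <- function(table) {
  cc <- complete_cases_cohort(table, within = "time")
  d <- cc$table
  d$group <- droplevels(factor(d$group))
  d$time <- droplevels(factor(d$time))
  if (nlevels(d$group) != 2L || nlevels(d$time) != 2L) {
    stopf("two-way design needs 2 groups and 2 time points")
  }
  grp_of <- tapply(as.character(d$group), d$participant, `[`, 1L)
  if (min(table(grp_of)) < 2L) stopf("need at least 2 participants per group")
  y <- d$outcome
  k <- 2L
  grand <- mean(y)
  m_s <- tapply(y, d$participant, mean)
  n_g <- table(grp_of)[levels(d$group)]
  m_g <- tapply(y, d$group, mean)
  m_t <- tapply(y, d$time, mean)
  m_gt <- tapply(y, list(d$group, d$time), mean)
  N <- length(m_s)

  ss_group <- k * sum(n_g * (m_g - grand)^2)
  ss_subj <- k * sum((m_s - grand)^2) - ss_group
  df_subj <- N - 2L
  ss_time <- N * sum((m_t - grand)^2)
  dev_gt <- sweep(sweep(m_gt, 1, m_g), 2, m_t) + grand
  ss_tg <- sum(rep(n_g, k) * as.vector(dev_gt)^2)
  ss_total <- sum((y - grand)^2)
  ss_werr <- ss_total - ss_group - ss_subj - ss_time - ss_tg
  ss_werr <- max(ss_werr, 0)
  df_werr <- N - 2L

  tab <- rbind(
    anova_row("group", ss_group, 1L, ss_subj, df_subj, "between"),
    error_row("subjects_within_group", ss_subj, df_subj, "between"),
    anova_row("time", ss_time, 1L, ss_werr, df_werr, "time"),
    anova_row("time:group", ss_tg, 1L, ss_werr, df_werr, "time"),
    error_row("time_error", ss_werr, df_werr, "time"))
  structure(list(table = tab, n_included = N, n_excluded = cc$n_excluded,
                 flagged_zero_variance = ss_subj == 0 && ss_werr == 0),
            class = "anova_result")
}

#' @rdname mixed_anova
#' @export
mixed_anova_3way <- function(table) {
  cc <- complete_cases_cohort(table, within = c("time", "location"))
  d <- cc$table
  d$group <- droplevels(factor(d$group))
  d$time <- droplevels(factor(d$time))
  d$location <- droplevels(factor(d$location))
  kt <- nlevels(d$time); kl <- nlevels(d$location)
  if (nlevels(d$group) != 2L || kt != 2L || kl < 2L) {
    stopf("three-way design needs 2 groups, 2 time points, >= 2 locations")
  }
  grp_of <- tapply(as.character(d$group), d$participant, `[`, 1L)
  if (min(table(grp_of)) < 2L) stopf("need at least 2 participants per group")
  y <- d$outcome
  grand <- mean(y)
  N <- length(unique(d$participant))
  n_g <- table(grp_of)[levels(d$group)]
  m_s <- tapply(y, d$participant, mean)
  m_s <- stats::setNames(as.numeric(m_s), names(m_s))
  m_g <- tapply(y, d$group, mean)
  m_t <- tapply(y, d$time, mean)
  m_l <- tapply(y, d$location, mean)
  m_gt <- tapply(y, list(d$group, d$time), mean)
  m_gl <- tapply(y, list(d$group, d$location), mean)
  m_tl <- tapply(y, list(d$time, d$location), mean)
  m_gtl <- tapply(y, list(d$group, d$time, d$location), mean)
  m_st <- tapply(y, list(d$participant, d$time), mean)
  m_sl <- tapply(y, list(d$participant, d$location), mean)

  # between-subjects stratum
  ss_group <- kt * kl * sum(n_g * (m_g - grand)^2)
  ss_subj <- kt * kl * sum((m_s - grand)^2) - ss_group
  df_subj <- N - 2L

  # time stratum
  ss_time <- kl * N * sum((m_t - grand)^2)
  dev_gt <- sweep(sweep(m_gt, 1, m_g), 2, m_t) + grand
  ss_tg <- kl * sum(rep(n_g, kt) * as.vector(dev_gt)^2)
  tot_t <- kl * sum((m_st - m_s[rownames(m_st)])^2)
  ss_terr <- max(tot_t - ss_time - ss_tg, 0)
  df_terr <- (N - 2L) * (kt - 1L)

  # location stratum
  ss_loc <- kt * N * sum((m_l - grand)^2)
  dev_gl <- sweep(sweep(m_gl, 1, m_g), 2, m_l) + grand
  ss_lg <- kt * sum(rep(n_g, kl) * as.vector(dev_gl)^2)
  tot_l <- kt * sum((m_sl - m_s[rownames(m_sl)])^2)
  ss_lerr <- max(tot_l - ss_loc - ss_lg, 0)
  df_lerr <- (N - 2L) * (kl - 1L)

  # time x location stratum
  dev_tl <- sweep(sweep(m_tl, 1, m_t), 2, m_l) + grand
  ss_tl <- N * sum(dev_tl^2)
  dev_gtl <- m_gtl
  for (g in seq_len(2)) for (t in seq_len(kt)) for (l in seq_len(kl)) {
    dev_gtl[g, t, l] <- m_gtl[g, t, l] - m_gt[g, t] - m_gl[g, l] -
      m_tl[t, l] + m_g[g] + m_t[t] + m_l[l] - grand
  }
  ss_tlg <- sum(rep(n_g, kt * kl) * as.vector(dev_gtl)^2)
  part <- m_st[cbind(as.character(d$participant), as.character(d$time))] +
    m_sl[cbind(as.character(d$participant), as.character(d$location))] -
    m_s[as.character(d$participant)]
  tot_tl <- sum((y - part)^2)
  ss_tlerr <- max(tot_tl - ss_tl - ss_tlg, 0)
  df_tlerr <- (N - 2L) * (kt - 1L) * (kl - 1L)

  tab <- rbind(
    anova_row("group", ss_group, 1L, ss_subj, df_subj, "between"),
    error_row("subjects_within_group", ss_subj, df_subj, "between"),
    anova_row("time", ss_time, kt - 1L, ss_terr, df_terr, "time"),
    anova_row("time:group", ss_tg, kt - 1L, ss_terr, df_terr, "time"),
    error_row("time_error", ss_terr, df_terr, "time"),
    anova_row("location", ss_loc, kl - 1L, ss_lerr, df_lerr, "location"),
    anova_row("location:group", ss_lg, kl - 1L, ss_lerr, df_lerr, "location"),
    error_row("location_error", ss_lerr, df_lerr, "location"),
    anova_row("time:location", ss_tl, (kt - 1L) * (kl - 1L),
              ss_tlerr, df_tlerr, "time_location"),
    anova_row("time:location:group", ss_tlg, (kt - 1L) * (kl - 1L),
              ss_tlerr, df_tlerr, "time_location"),
    error_row("time_location_error", ss_tlerr, df_tlerr, "time_location"))
  structure(list(table = tab, n_included = N, n_excluded = cc$n_excluded,
                 flagged_zero_variance = all(tab$ss[tab$effect %in%
                   c("subjects_within_group", "time_error", "location_error",
                     "time_location_error")] == 0)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA: %d participants included, %d excluded\n",
              x$n_included, x$n_excluded))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected post hoc pre/post comparisons
#'
#' Paired t-tests of post versus pre within each level of `by`
#' (typically `location`, following a significant time x location
#' interaction); raw p-values are multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param table long-format cohort table (see [mixed_anova_3way()]).
#' @param by column holding the stratifying factor (default
#'   `"location"`).
#' @return data.frame with one row per level: mean difference, t, df,
#'   raw and Bonferroni-adjusted p, and the number of comparisons.
#' @export
bonferroni_posthoc <- function(table, by = "location") {
  cc <- complete_cases_cohort(table, within = c("time", by))
  d <- cc$table
  lv <- unique(as.character(d[[by]]))
  m <- length(lv)
  rows <- lapply(lv, function(l) {
    dl <- d[as.character(d[[by]]) == l, ]
    wide <- tapply(dl$outcome, list(dl$participant, as.character(dl$time)), mean)
    diffs <- wide[, "post"] - wide[, "pre"]
    tt <- stats::t.test(diffs)
    data.frame(level = l, mean_diff = mean(diffs),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m),
               n_comparisons = m, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
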