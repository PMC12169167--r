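#' Simulate a long-format pre/post cohort table
#'
#' Draws one outcome per participant x time (x location) cell according
#' to the additive model documented in [cohort_spec()]. The returned
#' table is the long format consumed by [mixed_anova_2way()] and
#' [mixed_anova_3way()].
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with columns `participant`, `group` (factor
#'   OC/NOC), `time` (factor pre/post), `location` (factor
#'   proximal/mid/distal, only when `n_locations == 3`) and `outcome`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- sum(spec$n_per_group)
  group <- rep(c("OC", "NOC"), times = spec$n_per_group)
  locs <- if (spec$n_locations == 3L) c("proximal", "mid", "distal") else NA_character_
  with_seed(spec$seed, {
    u <- stats::rnorm(n, 0, spec$sd_between)
    df <- expand.grid(location = seq_len(spec$n_locations),
                      time = c(0L, 1L),
                      participant = seq_len(n))
    g <- (group == "NOC")[df$participant]
    mu <- spec$mu_baseline + u[df$participant] +
      df$time * spec$training_effect +
      df$time * g * spec$interaction_effect +
      spec$location_offsets[df$location]
    out <- data.frame(
      participant = sprintf("P%02d", df$participant),
      group = factor(group[df$participant], levels = c("OC", "NOC")),
      time = factor(ifelse(df$time == 0L, "pre", "post"),
                    levels = c("pre", "post")),
      outcome = mu + stats::rnorm(nrow(df), 0, spec$sd_within),
      stringsAsFactors = FALSE)
    if (spec$n_locations == 3L) {
      out$location <- factor(locs[df$location], levels = locs)
      out <- out[, c("participant", "group", "time", "location", "outcome")]
    }
    rownames(out) <- NULL
    out
  })
}
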