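#!/usr/bin/env Rscript
# Test-retest reliability (familiarisation vs baseline) on simulated
# sub-samples with known variance components: ICC(3,1), typical error
# and CV for CSA-like, stiffness-like and SWV-like outcomes. The
# between/within SDs are chosen so the three outcomes span the
# excellent-to-moderate reliability range.

suppressPackageStartupMessages(library(tendonmech))

seed <- 20260930L
dir.create("results", showWarnings = FALSE)
set.seed(seed)

simulate_retest <- function(n, mu, sd_between, sd_within) {
  u <- rnorm(n, mu, sd_between)
  cbind(u + rnorm(n, 0, sd_within), u + rnorm(n, 0, sd_within))
}

cases <- list(
  csa_mm2       = list(n = 13, mu = 75,   sb = 9,   sw = 0.65),
  stiffness_Nmm = list(n = 13, mu = 2800, sb = 900, sw = 420),
  swv_ms        = list(n = 12, mu = 7.5,  sb = 1.6, sw = 1.4))

rows <- lapply(names(cases), function(nm) {
  cs <- cases[[nm]]
  tab <- simulate_retest(cs$n, cs$mu, cs$sb, cs$sw)
  s <- reliability_summary(tab, outcome = nm)
  s$true_icc <- cs$sb^2 / (cs$sb^2 + cs$sw^2)
  s
})
rel <- do.call(rbind, rows)
write_cohort(rel, "results/reliability.tsv")
print(rel, row.names = FALSE, digits = 3)
cat("\nsmall-sample ICCs scatter around the variance-component truth;\n")
cat("TE tracks the programmed within-subject SD\n")
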