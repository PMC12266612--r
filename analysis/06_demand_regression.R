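#!/usr/bin/env Rscript
# Stage 6: econometric validation of the five dimensions.
#
# Builds the doctor-week panel (demand in week t against dimension
# sentiments in week t-1), fits the two-way fixed-effects regression with
# doctor-clustered CR1 errors, translates coefficients into one-SD marginal
# effects on demand, traces the stepwise gain in explained variance as the
# dimensions enter one by one, checks robustness to censoring the top and
# bottom 10% of demand, and runs the 100-replicate coefficient-recovery
# study at 500 doctors x 20 weeks.

suppressPackageStartupMessages({
  library(readr)
  library(jsonlite)
  library(hsq5d)
})

dim_scores <- read_csv("results/dimension_scores.csv", show_col_types = FALSE)
demand <- read_csv("results/data/demand.csv", show_col_types = FALSE)

panel <- build_panel(dim_scores, demand, lag = 1)
fit <- fit_fe(panel, mode = "twoway_fe")
print(fit)

sds <- vapply(panel[DIMENSIONS], sd, numeric(1))
me <- marginal_effect(fit$coefficients$estimate, unname(sds),
                      dimension = fit$coefficients$term)
cat("\nOne-SD marginal effects on demand:\n")
print(as.data.frame(me), digits = 3, row.names = FALSE)

sw <- stepwise_r2(panel)
cat("\nStepwise variance explained as dimensions are added:\n")
print(as.data.frame(sw), digits = 4, row.names = FALSE)

cens <- censor_dependent(panel, 0.10)
fit_cens <- fit_fe(cens)
cat(sprintf("\nCensoring robustness (top/bottom 10%% of demand removed, N %d -> %d):\n",
            nrow(panel), nrow(cens)))
print(as.data.frame(fit_cens$coefficients), digits = 3, row.names = FALSE)

cat("\nCoefficient recovery at 500 doctors x 20 weeks, 100 replicates:\n")
rec <- coefficient_recovery(seeds = 1:100)
print(as.data.frame(rec$summary), digits = 4, row.names = FALSE)

write_json(list(
  fit = list(mode = fit$mode, r_squared = fit$r_squared, n = fit$n,
             coefficients = fit$coefficients),
  marginal_effects = me,
  stepwise_r2 = sw,
  censored = list(n = fit_cens$n, coefficients = fit_cens$coefficients),
  recovery = rec$summary
), "results/regression_results.json", auto_unbox = TRUE, digits = NA)
cat("\nResults written to results/regression_results.json\n")
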