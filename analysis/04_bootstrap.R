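#!/usr/bin/env Rscript
# Stage 4: parametric-bootstrap 95% uncertainty intervals for the fitted
# birth prevalence. Writes ui.csv (and replicates.csv when KEEP_REPLICATES
# is set). CHDPREV_REPS controls the replicate count (default 100 here;
# 1000 is the production setting).

suppressPackageStartupMessages({
  library(chdprev)
  library(dplyr)
})

seed <- as.integer(Sys.getenv("CHDPREV_SEED", "1"))
n_reps <- as.integer(Sys.getenv("CHDPREV_REPS", "100"))

survey <- read.csv("results/survey.csv")
rates <- read.csv("results/rates.csv")
obs <- bind_rows(
  survey_to_observations(survey),
  observations("csmr", rates$age_lo, rates$age_hi, rates$sex, rates$year,
               rates$value, rates$effective_n)
)
fit <- fit_map(obs)
boot <- bootstrap_fit(fit, obs, fit$config, n_reps = n_reps, seed = seed + 1)

ui <- birth_prevalence_ui(boot)
ui <- mutate(ui, across(c(estimate, lower, upper), ~ 1000 * .x))
write.csv(ui, "results/ui.csv", row.names = FALSE)
cat("birth prevalence per 1,000 with 95% UI:\n")
print(as.data.frame(ui), digits = 3)

if (nzchar(Sys.getenv("KEEP_REPLICATES"))) {
  reps <- bind_rows(lapply(names(boot$replicates), function(s) {
    tibble(sex = s, rep = seq_len(ncol(boot$replicates[[s]]$birth_prevalence)),
           birth_prev_per_1000 = 1000 * boot$replicates[[s]]$birth_prevalence[1, ])
  }))
  write.csv(reps, "results/replicates.csv", row.names = FALSE)
}
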