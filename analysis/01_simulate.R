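#!/usr/bin/env Rscript
# Stage 1: generate the three synthetic input streams with known truth.
#
# The default scenario mimics the magnitudes of the US recalled-CHD problem:
# birth prevalence 3.29/3.23 per 1,000 (m/f), an infant excess hazard of
# ~0.52/yr declining roughly threefold over the 1968-2010 death window, a
# survey window 1997-2011 with ~350 respondents per age/sex/year cell.
# Writes deaths.csv, survey.csv, population.csv under results/.

suppressPackageStartupMessages(library(chdprev))

seed <- as.integer(Sys.getenv("CHDPREV_SEED", "1"))
dir.create("results", showWarnings = FALSE)

truth <- make_truth(seed = seed)
print(truth)

deaths <- simulate_deaths(truth)
survey <- simulate_survey(truth)
population <- population_from_truth(truth, truth$death_years)

write.csv(deaths, "results/deaths.csv", row.names = FALSE)
write.csv(survey, "results/survey.csv", row.names = FALSE)
write.csv(population, "results/population.csv", row.names = FALSE)

cat(sprintf(
  "wrote %d death cells (%d CHD deaths), %d survey cells (%d positives), %d population cells\n",
  nrow(deaths), sum(deaths$deaths), nrow(survey), sum(survey$positives),
  nrow(population)
))
cat(sprintf(
  "true infant CSMR: %.0f (1968) -> %.0f (2010) per 100,000 PY\n",
  1e5 * truth$sexes$male$prevalence$values[1, 1] * truth$sexes$male$chi$values[1, 1],
  1e5 * truth$sexes$male$prevalence$values[1, 43] * truth$sexes$male$chi$values[1, 43]
))
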