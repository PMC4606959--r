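#!/usr/bin/env Rscript
# Stage 6: headline summary statistics, combining the published input
# figures (exact arithmetic) with the synthetic pipeline's own outputs from
# stages 3-5. Writes summary.csv.

suppressPackageStartupMessages({
  library(chdprev)
  library(dplyr)
})

report <- read.csv("results/fit_report.csv")
bands <- read.csv("results/projections.csv")
adult <- bands %>% filter(band == "20-64")

rows <- tribble(
  ~statistic, ~value,
  "csmr decline, all ages 1968-2010 (%), from published rates",
  percent_decline(4.9, 1.4),
  "csmr decline, 0-51 weeks 1968-2010 (%), from published rates",
  percent_decline(170, 53),
  "fold decrease, 0-51-week mortality, from published rates",
  fold_change(170, 53),
  "fold increase, adults 20-64 2010 vs 1968, from published counts",
  fold_change(273000, 118000),
  "share of deaths with CHD association (%), from published counts",
  share(288813, 92400000),
  "share with CHD as underlying cause (%), from published counts",
  share(212116, 288813),
  "fitted birth prevalence, male (per 1,000), synthetic scenario",
  report$birth_prev_per_1000[report$sex == "male"],
  "fitted birth prevalence, female (per 1,000), synthetic scenario",
  report$birth_prev_per_1000[report$sex == "female"],
  "adult growth fold 2010 vs 1968, synthetic scenario",
  fold_change(adult$count[adult$year == 2010], adult$count[adult$year == 1968]),
  "adult prevalence per 1,000 in 2050, synthetic scenario",
  round(adult$prev_per_1000[adult$year == 2050], 2)
)

# the "adolescents turning 20" style statistic computed in stage 5
if (file.exists("results/age20.csv")) {
  a20 <- read.csv("results/age20.csv")
  rows <- bind_rows(rows, tibble(
    statistic = "fold increase, 20-year-olds with CHD 2050 vs 2010, synthetic scenario",
    value = fold_change(a20$count[a20$year == 2050], a20$count[a20$year == 2010])
  ))
}

write.csv(rows, "results/summary.csv", row.names = FALSE)
print(as.data.frame(rows), right = FALSE)
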