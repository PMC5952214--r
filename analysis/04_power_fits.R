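#!/usr/bin/env Rscript
# Power-law characterization SE = a * n^b + c: fitted to the published
# daily summaries and to the simulated study of 01_simulate_study.R.
# Writes results/published/power_fits.csv

library(shoalSE)

out_dir <- "results/published"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

d <- published_daily_se()
fit_basal <- fit_power(d$n_fish, d$basal_mean, mode = "daily_means")
fit_resp <- fit_power(d$n_fish, d$event_se, mode = "daily_means")

message("Published daily summaries, basal state:")
print(fit_basal)
message("\nPublished daily summaries, response state:")
print(fit_resp)

row_of <- function(f, data, state) {
  data.frame(data = data, state = state,
             a = coef(f)[["a"]], b = coef(f)[["b"]], c = coef(f)[["c"]],
             sse = f$sse, r2 = f$r2, adj_r2 = f$adj_r2, rmse = f$rmse,
             n_points = f$n_points)
}
rows <- rbind(row_of(fit_basal, "published", "basal"),
              row_of(fit_resp, "published", "response"))

sim_path <- "results/sim_study/clip_records.csv"
if (file.exists(sim_path)) {
  recs <- read.csv(sim_path)
  basal <- grepl("^basal", recs$clip_type)
  fs <- fit_power(recs$n_fish[basal], recs$se[basal])
  fe <- fit_power(recs$n_fish[!basal], recs$se[!basal])
  message("\nSimulated study, basal state (per-clip points):")
  print(fs)
  rows <- rbind(rows, row_of(fs, "simulated", "basal"),
                row_of(fe, "simulated", "response"))
} else {
  message("\n(run analysis/01_simulate_study.R first to add simulated fits)")
}

write.csv(rows, file.path(out_dir, "power_fits.csv"), row.names = FALSE)
message("\nwritten to ", out_dir)
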