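#!/usr/bin/env Rscript
# Stage 3: within-season and within-year site-use metrics.
#
# Per shark-season residency summaries (visit counts, mean visit duration,
# cumulative days, arrival-to-departure span), hourly detection profiles
# by sex across mating seasons, monthly arrival/departure proportions,
# daily presence bins, and the weekly temperature climatology.

library(matesite)

data_dir <- "results/data"
registry <- load_registry(file.path(data_dir, "registry.csv"))
det <- load_detections(file.path(data_dir, "detections.csv"),
                       registry)$detections
visits <- utils::read.csv("results/visits.csv")
visits$start <- parse_instant(visits$start)
visits$end <- parse_instant(visits$end)
strings <- utils::read.csv("results/strings.csv")
strings$arrival <- parse_instant(strings$arrival)
strings$departure <- parse_instant(strings$departure)
temps <- load_temperature(file.path(data_dir, "temperature.csv"))

ss <- season_summaries(visits, strings, registry)
write_table(ss, "results/season_summaries.csv")
med <- function(sx, col) stats::median(ss[[col]][ss$sex == sx], na.rm = TRUE)
cat("within-season medians across shark-seasons (tagging years excluded):\n")
for (sx in c("M", "F"))
  cat(sprintf("  %s: %.1f visits of %.2f h (mean/season); %.2f cumulative days; %.2f-day span\n",
              sx, med(sx, "n_visits"), med(sx, "mean_visit_duration_h"),
              med(sx, "cumulative_days"), med(sx, "span_days")))

hp <- hourly_profile(det, registry)
write_table(hp, "results/hourly_profile.csv")
low <- do.call(rbind, lapply(split(hp, hp$sex), function(g)
  g[order(g$mean_proportion)[1:3], c("sex", "hour_of_day", "mean_proportion")]))
cat("lowest mean hourly detection proportions (afternoon heat suppression):\n")
print(low, row.names = FALSE)

mep <- monthly_event_proportions(strings, registry)
write_table(mep, "results/monthly_events.csv")
for (ev in c("arrival", "departure")) for (sx in c("M", "F")) {
  g <- mep[mep$event == ev & mep$sex == sx, ]
  cat(sprintf("modal %s month for %s: %s (%.0f%% of %d events)\n", ev, sx,
              month.name[g$month[which.max(g$proportion)]],
              100 * max(g$proportion), sum(g$n_events)))
}

db <- daily_detection_bins(det, registry)
write_table(db$monthly, "results/daily_bins_monthly.csv")
fem <- db$monthly[db$monthly$sex == "F", ]
cat(sprintf("female shark-days: Jun %d, Jul %d, Aug %d, Sep %d (August dip)\n",
            fem$shark_days[fem$month == 6], fem$shark_days[fem$month == 7],
            fem$shark_days[fem$month == 8], fem$shark_days[fem$month == 9]))

wt <- weekly_max_temperature(temps)
write_table(wt, "results/weekly_temp.csv")
cat(sprintf("warmest week: %d (mean daily max %.1f degC)\n",
            wt$week[which.max(wt$mean_daily_max)], max(wt$mean_daily_max)))
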