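#!/usr/bin/env Rscript
# Stage 5 — migration strategies and depth use.
#
# K-means (k = 3) on the southernmost latitude of each smoothed track,
# labels ordered a (shortest-range) to c (longest-range); agreement with
# the generating strategies; and per-strategy depth-use profiles over the
# eight standard daily-maximum-depth bins.

suppressMessages(library(basktrack))
co <- readRDS("scratch/cohort.rds")
best <- readr::read_csv("results/geolocation/best_daily_locations.csv",
                        show_col_types = FALSE)
dir.create("results/strategies", showWarnings = FALSE, recursive = TRUE)

lats <- dplyr::bind_rows(lapply(split(best, best$animal_id), function(b)
  tibble::tibble(animal_id = b$animal_id[1],
                 min_lat = southernmost_latitude(b))))
assign <- kmeans_strategies(lats, k = 3, seed = 2017)
assign$true_strategy <- unname(co$strategies[assign$animal_id])
readr::write_csv(assign, "results/strategies/assignments.csv")

depth <- dplyr::bind_rows(lapply(co$obs, function(o) {
  pr <- depth_bin_proportions(o$light$max_depth_m)
  tibble::tibble(animal_id = o$animal_id, bin = names(pr),
                 proportion = as.numeric(pr))
}))
depth$strategy <- assign$strategy[match(depth$animal_id, assign$animal_id)]
by_strategy <- dplyr::summarise(
  dplyr::group_by(depth, .data$strategy, .data$bin),
  mean_proportion = mean(.data$proportion), .groups = "drop")
readr::write_csv(by_strategy, "results/strategies/depth_bins_by_strategy.csv")

epi <- dplyr::bind_rows(lapply(co$obs, function(o)
  tibble::tibble(animal_id = o$animal_id,
                 epipelagic = epipelagic_fraction(o$light$max_depth_m))))
epi$strategy <- assign$strategy[match(epi$animal_id, assign$animal_id)]
readr::write_csv(epi, "results/strategies/epipelagic_fraction.csv")

cat(sprintf("Strategy recovery: %d of %d animals labelled as generated.\n",
            sum(assign$strategy == assign$true_strategy), nrow(assign)))
mu <- tapply(assign$min_lat, assign$strategy, mean)
cat("Mean southernmost latitude by strategy:",
    paste(sprintf("%s = %.1f", names(mu), mu), collapse = ", "), "\n")
cat(sprintf("Epipelagic (0-200 m) fraction: cohort mean %.0f%%;\n",
            100 * mean(epi$epipelagic)))
for (s in sort(unique(epi$strategy)))
  cat(sprintf("  strategy %s: %.0f%%\n", s,
              100 * mean(epi$epipelagic[epi$strategy == s])))
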