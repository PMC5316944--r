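#!/usr/bin/env Rscript
# Stage 4 — space use.
#
# Post-summer (from 1 October) utilisation distributions per animal,
# percentage volume contours at 50/75/95%, the 50-km-apothem hexagonal
# density surface averaged across animals, and occupancy of synthetic
# maritime zones (stand-ins for EEZ polygons, labelled synthetic because the
# real shapefiles are jurisdictional data this analysis does not ship).

suppressMessages(library(basktrack))
co <- readRDS("scratch/cohort.rds")
fits <- readRDS("scratch/fits.rds")
best <- readr::read_csv("results/geolocation/best_daily_locations.csv",
                        show_col_types = FALSE)
dir.create("results/space_use", showWarnings = FALSE, recursive = TRUE)

uds <- lapply(fits, sum_uds)   # post-summer by default
pvc_tab <- dplyr::bind_rows(lapply(c(50, 75, 95), function(q) {
  n_cells <- vapply(uds, function(u) sum(pvc(u, q)), 0L)
  area <- n_cells * mean((111.19 * 1)^2 * cos(fits[[1]]$grid$lat * pi / 180))
  tibble::tibble(q_percent = q, mean_n_cells = mean(n_cells),
                 mean_area_km2 = mean(area))
}))
readr::write_csv(pvc_tab, "results/space_use/pvc_summary.csv")

hg <- build_hex_grid(co$env$extent + c(-2, 2, -2, 2), apothem_km = 50)
dens <- hex_density(fits, hg)
readr::write_csv(head(dens, 200), "results/space_use/hex_density_top200.csv")

# synthetic maritime zones: three latitude bands over the domain
box <- function(x0, x1, y0, y1)
  cbind(lon = c(x0, x1, x1, x0, x0), lat = c(y0, y0, y1, y1, y0))
zones <- list(`Northern shelf seas` = box(-28, 2, 52, 64),
              `Biscay band` = box(-28, 2, 44, 52),
              `Iberia-Africa band` = box(-28, 2, 30, 44))
write_zones_geojson(zones, "results/space_use/zones_synthetic.geojson")
post <- best[best$date >= as.Date("2012-10-01"), ]
occ <- zone_occupancy(post, zones)
readr::write_csv(occ, "results/space_use/zone_occupancy.csv")

cat(sprintf("Hex grid: %d cells of %.0f km^2 (apothem %.0f km).\n",
            nrow(hg), attr(hg, "cell_area_km2"), attr(hg, "apothem_km")))
cat(sprintf("Mean 95%% PVC spans %.1f grid cells per animal.\n",
            pvc_tab$mean_n_cells[pvc_tab$q_percent == 95]))
cat("Post-summer zone occupancy (% of animal-days):\n")
for (k in seq_len(nrow(occ)))
  cat(sprintf("  %-20s %5.1f%%\n", occ$zone[k], occ$percent[k]))
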