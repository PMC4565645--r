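#!/usr/bin/env Rscript
# Geographic view of the forecast: per-city change in the scale-adjusted
# metric between 2010 and the predicted 2020, drawn as circles whose radius
# is |change| with a diverging azure (decrease) / red (increase) scale, and
# exported as GeoJSON. The synthetic system plants no spatial structure, so
# the map should show no clusters: it is the negative control for the
# rendering itself.

suppressPackageStartupMessages(library(urbansami))
pred <- read_sami_table("results/forecast_2020.csv")
tab <- read_sami_table("results/sami.csv")
coords <- read_coordinates("results/data/coordinates.csv")

ch <- sami_changes(pred, tab[tab$year == 2010, ])
readr::write_csv(ch, "results/predicted_changes.csv")

hom <- ch[ch$indicator == "homicides", ]
map <- render_change_map(hom, coords,
                         geojson_path = "results/changes_homicides.geojson")
ggplot2::ggsave("results/change_map_homicides.pdf", map,
                width = 9, height = 8)

inc <- mean(hom$delta > 0)
message(sprintf("homicides: %.0f%% of cities expected to rise relative to the law; mean |change| = %.3f",
                100 * inc, mean(abs(hom$delta))))
message("map and GeoJSON written under results/")
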