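#!/usr/bin/env Rscript
# Tile-grid co-localization of the EmyoT marker stains (MRTFA, SRF,
# IGFBP5): 45 x 34 = 1530 tiles sized to approximate one tumor cell,
# per-tile positivity by Otsu threshold, and double-positive overlays.

source("analysis/00_config.R")

ih <- simulate_ihc(width = 450, height = 340, n_cols = 45, n_rows = 34,
                   regions = list(
                     list(channels = c("MRTFA", "SRF"), cols = 10:14, rows = 8:10),
                     list(channels = c("MRTFA", "IGFBP5"), cols = 28:31, rows = 20:22),
                     list(channels = "SRF", cols = 40:42, rows = 30:31)),
                   seed = ATLAS_SEED + 4L)

pos <- lapply(ih$images, annotate_tiles, grid = ih$grid)
for (ch in names(pos))
  message(sprintf("%s: %d positive tiles (threshold %.3f)",
                  ch, sum(pos[[ch]]), attr(pos[[ch]], "threshold")))

ov_srf <- overlap_tiles(pos$MRTFA, pos$SRF, ih$grid)
ov_igf <- overlap_tiles(pos$MRTFA, pos$IGFBP5, ih$grid)
message(sprintf("MRTFA+SRF+ double-positive tiles: %d (truth %d)",
                ov_srf$count, sum(ih$truth[, "MRTFA"] & ih$truth[, "SRF"])))
message(sprintf("MRTFA+IGFBP5+ double-positive tiles: %d (truth %d)",
                ov_igf$count, sum(ih$truth[, "MRTFA"] & ih$truth[, "IGFBP5"])))

tile_table <- data.frame(ih$grid$tiles,
                         MRTFA = as.vector(pos$MRTFA),
                         SRF = as.vector(pos$SRF),
                         IGFBP5 = as.vector(pos$IGFBP5))
tile_table$double_MRTFA_SRF <- tile_table$MRTFA & tile_table$SRF
tile_table$double_MRTFA_IGFBP5 <- tile_table$MRTFA & tile_table$IGFBP5
tsv(tile_table, "ihc_tiles.tsv")

if (requireNamespace("png", quietly = TRUE)) {
  ov <- ov_srf$overlay / 3
  png::writePNG(ov, "results/ihc_overlay_mrtfa_srf.png")
  message("wrote results/ihc_overlay_mrtfa_srf.png")
}
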