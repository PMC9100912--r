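#!/usr/bin/env Rscript
# Exhaustive two-band screening: build NDSI, RSI and DSI over every ordered
# band pair (126 x 125 pairs each), correlate with nitrogen, and keep the
# most sensitive pair per index type (|r| > 0.45 floor).

source("analysis/00_config.R")

scene <- generate_scene(scene_cfg)
mask <- classify_pixels(scene$cube)
S <- roi_spectra_matrix(scene$cube, mask, scene$samples)
y <- scene$samples$n_pct

maps <- lapply(c(NDSI = "NDSI", RSI = "RSI", DSI = "DSI"), function(ty) {
  pairwise_correlation_map(S, scene$cube$wavelengths, y, index_type = ty)
})
for (m in maps) print(m)

pairs <- select_sensitive_pairs(maps, r_floor = 0.45, top_k = 5)
pairs$p_value <- correlation_p_value(pairs$r, n = length(y))
write.csv(pairs, file.path(RESULTS_DIR, "sensitive_pairs.csv"), row.names = FALSE)
cat("\nTop pairs per index type (|r| > 0.45):\n")
print(pairs[!duplicated(pairs$index_type), ], digits = 4)

# full correlation matrices are large; store under scratch/
for (ty in names(maps)) {
  write.csv(round(maps[[ty]]$r, 6),
            file.path(SCRATCH_DIR, sprintf("corr_map_%s.csv", ty)))
}
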