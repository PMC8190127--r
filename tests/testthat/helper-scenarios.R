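# Reduced-geometry scenario for fast unit tests: a 448 x 896 px tile with
# 0.5 mm channels coinciding over 1.6 mm (0.8 mm2 overlap). Same pixel
# size, nucleus scale and optical model as the full-size default.
SMALL_OVERLAP_MM2 <- 0.8

small_tile_scenario <- function(...) {
  args <- list(...)
  defaults <- list(tile_px = c(448L, 896L), channel_width_mm = 0.5,
                   overlap_length_mm = 1.6, coverage = 0.8,
                   n_nuclei = 400L)
  do.call(image_scenario, utils::modifyList(defaults, args))
}

# convenience: render + clean + mask for a small tile
small_tile_pipeline <- function(seed = 1L, ...) {
  rt <- render_device_tile(small_tile_scenario(...), seed = seed)
  cl <- clean_channel_edges(rt$image)
  mask <- extract_overlap_mask(cl, expected_area_mm2 = SMALL_OVERLAP_MM2)
  list(truth = rt$truth, raw = rt$image, cleaned = cl, mask = mask)
}
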