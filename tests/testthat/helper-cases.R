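# Shared fixtures, built in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# compact slide spec: 1.2 x 1.2 mm, one benign + one in-situ distractor,
# default density and rendering settings; per-nucleus properties match the
# full-extent defaults
small_spec <- function(seed = 1, ...) {
  args <- list(width_um = 1200, height_um = 1200, invasive_fraction = 0.72,
               hotspot_center_um = c(600, 800), benign_region_count = 1,
               insitu_region_count = 1, seed = seed)
  do.call(slide_spec, utils::modifyList(args, list(...)))
}

# 2 x 2 mm spec used for registration / VDS checks (large enough that frame
# clipping at the +/-300 um shift range cannot dominate the IoU)
reg_spec <- function(seed = 1, ...) {
  args <- list(width_um = 2000, height_um = 2000, invasive_fraction = 0.55,
               hotspot_center_um = c(1000, 1500), seed = seed)
  do.call(slide_spec, utils::modifyList(args, list(...)))
}

small_case_rendered <- function() {
  memo("small_case_rendered", function() simulate_case(small_spec(seed = 11)))
}

# epithelium rasters of a case's Ki67-frame and CK-frame layouts
case_masks <- function(spec, res = 4) {
  rg <- generate_regions(spec)
  ck <- render_ck_serial(NULL, rg, spec, render = FALSE)
  dims <- c(ceiling(spec$height_um / res), ceiling(spec$width_um / res))
  list(spec = spec, regions = rg, ck = ck,
       fixed = ki67hotspot:::epithelium_raster(rg, dims, res),
       moving = ki67hotspot:::epithelium_raster(ck$regions_ck, dims, res),
       res = res)
}

# uniform random cell table for hotspot-search oracle checks
random_cells <- function(n, extent = c(1000, 1000), p_positive = 0.5) {
  data.frame(id = seq_len(n),
             x_um = runif(n, 0, extent[1]),
             y_um = runif(n, 0, extent[2]),
             ki67_class = ifelse(runif(n) < p_positive, "positive", "negative"),
             stringsAsFactors = FALSE)
}

# a square cluster of cells centred at (cx, cy) with an exact positive count
cell_cluster <- function(n, cx, cy, half = 300, ratio = 0.5, id0 = 0) {
  npos <- round(n * ratio)
  data.frame(id = id0 + seq_len(n),
             x_um = runif(n, cx - half, cx + half),
             y_um = runif(n, cy - half, cy + half),
             ki67_class = c(rep("positive", npos), rep("negative", n - npos)),
             stringsAsFactors = FALSE)
}
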