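# Synthetic case generator: region layout, hard-core cell sampling, planted
# positivity gradient, rendering, and on-disk round trips.

test_that("degenerate distractor counts give exactly invasive + stroma", {
  sp <- small_spec(benign_region_count = 0, insitu_region_count = 0)
  rg <- generate_regions(sp)
  expect_length(rg, 2)
  expect_setequal(vapply(rg, `[[`, "", "region_class"),
                  c("invasive_tumour", "stroma"))
})

test_that("region polygons are simple, mutually disjoint and cover the slide", {
  sp <- small_spec(seed = 3)
  rg <- generate_regions(sp)
  expect_length(rg, 1 + 1 + 1 + 1)  # invasive + benign + in-situ + stroma
  areas <- vapply(rg, function(r) polygon_area(r$polygon), numeric(1))
  expect_true(all(areas > 0))
  # union = slide extent (areas partition the slide)
  expect_equal(sum(areas), sp$width_um * sp$height_um, tolerance = 1e-6)
  # pairwise raster intersection is empty
  for (i in seq_along(rg)) for (j in seq_len(i - 1)) {
    expect_equal(polygon_intersection_area(rg[[i]]$polygon, rg[[j]]$polygon), 0)
  }
  # invasive region covers >= 30% and contains the hotspot window
  inv <- rg[[which(vapply(rg, `[[`, "", "region_class") == "invasive_tumour")]]
  expect_gte(polygon_area(inv$polygon) / (sp$width_um * sp$height_um), 0.3)
  side <- hotspot_window_side()
  corners <- expand.grid(x = sp$hotspot_center_um[1] + c(-1, 1) * side / 2,
                         y = sp$hotspot_center_um[2] + c(-1, 1) * side / 2)
  expect_true(all(point_in_polygon(corners$x, corners$y, inv$polygon)))
})

test_that("a hotspot window that cannot fit raises a configuration error", {
  expect_error(slide_spec(width_um = 500, height_um = 500),
               class = "ki67_config_error")
  # corner-centred window exceeds the extent
  expect_error(generate_regions(small_spec(hotspot_center_um = c(10, 10))),
               class = "ki67_config_error")
  # window inside the slide but not inside the invasive band
  expect_error(generate_regions(small_spec(hotspot_center_um = c(600, 400))),
               class = "ki67_config_error")
})

test_that("cell sampling honours density, hard-core spacing and regions", {
  sp <- slide_spec(tumour_density_per_mm2 = 3000, seed = 5,
                   invasive_fraction = 0.4)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  inv <- cells[cells$region_class == "invasive_tumour", ]
  inv_area <- polygon_area(rg[[1]]$polygon) / 1e6
  expected <- inv_area * 3000
  expect_lt(abs(nrow(inv) - expected), 3 * sqrt(expected) + 0.01 * expected)
  # hard-core: no two centres closer than the maximum nucleus diameter
  sub <- inv[inv$x_um < 1500 & inv$y_um > 2000 & inv$y_um < 3500, ]
  d <- as.matrix(stats::dist(cbind(sub$x_um, sub$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), max(sp$nucleus_diameter_um))
  # no cells in stroma; each centroid lies inside a polygon of its own class
  # and in no polygon of any other class
  expect_false(any(cells$region_class == "stroma"))
  classes <- vapply(rg, `[[`, "", "region_class")
  inside <- sapply(rg, function(r) point_in_polygon(cells$x_um, cells$y_um,
                                                    r$polygon))
  for (rc in unique(cells$region_class)) {
    own <- inside[, classes == rc, drop = FALSE]
    other <- inside[, classes != rc & classes != "stroma", drop = FALSE]
    sel <- cells$region_class == rc
    expect_true(all(rowSums(own[sel, , drop = FALSE]) == 1))
    expect_true(all(rowSums(other[sel, , drop = FALSE]) == 0))
  }
})

test_that("zero-contrast field makes every invasive cell negative", {
  sp <- small_spec(baseline_positivity = 0, hotspot_peak_positivity = 0)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  inv <- cells[cells$region_class == "invasive_tumour", ]
  expect_true(all(inv$ki67_class == "negative"))
})

test_that("the planted positivity gradient is present across seeds", {
  hits <- vapply(1:40, function(s) {
    sp <- slide_spec(seed = s)   # full default extent: far zone >3 radii exists
    rg <- generate_regions(sp)
    cells <- sample_cells(sp, rg)
    inv <- cells[cells$region_class == "invasive_tumour", ]
    d <- sqrt((inv$x_um - sp$hotspot_center_um[1])^2 +
              (inv$y_um - sp$hotspot_center_um[2])^2)
    near <- inv$ki67_class[d <= sp$hotspot_radius_um] == "positive"
    far <- inv$ki67_class[d > 3 * sp$hotspot_radius_um] == "positive"
    mean(near) >= mean(far)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("planted window positivity matches its analytic mean", {
  side <- hotspot_window_side()
  for (s in 1:5) {
    sp <- small_spec(seed = s + 20)
    rg <- generate_regions(sp)
    cells <- sample_cells(sp, rg)
    x0 <- sp$hotspot_center_um[1] - side / 2
    y0 <- sp$hotspot_center_um[2] - side / 2
    inw <- cells$region_class == "invasive_tumour" &
      cells$x_um >= x0 & cells$x_um < x0 + side &
      cells$y_um >= y0 & cells$y_um < y0 + side
    p <- positivity_field(sp, cells$x_um[inw], cells$y_um[inw])
    emp <- mean(cells$ki67_class[inw] == "positive")
    expect_lt(abs(emp - mean(p)), 3 * sqrt(mean(p) * (1 - mean(p)) / sum(inw)))
  }
})

test_that("same seed reproduces a bit-identical case", {
  a <- simulate_case(small_spec(seed = 7))
  b <- simulate_case(small_spec(seed = 7))
  expect_identical(a$cells, b$cells)
  expect_identical(a$ki67_image$raster, b$ki67_image$raster)
  expect_identical(a$ck_image$raster, b$ck_image$raster)
  expect_identical(a$true_serial_transform, b$true_serial_transform)
})

test_that("rendered nuclei carry the expected optical densities", {
  sp <- small_spec(seed = 2)
  # zero cells: pure background, all ODs < 0.05
  empty <- sample_cells(sp, generate_regions(sp))[0, ]
  img <- render_ki67_image(empty, NULL, sp)
  od <- rgb_to_od(img)
  expect_lt(max(od), 0.05)
  # one positive nucleus: DAB OD > 0.3 inside the disc, < 0.05 outside
  one <- data.frame(id = 1L, x_um = 600, y_um = 600, diameter_um = 8,
                    ki67_class = "positive", region_class = "invasive_tumour")
  img1 <- render_ki67_image(one, NULL, sp)
  dab <- deconvolve(rgb_to_od(img1))$dab
  idx <- expand.grid(i = 1:nrow(dab), j = 1:ncol(dab))
  r2 <- (idx$j - 0.5 - 600)^2 + (idx$i - 0.5 - 600)^2
  expect_gt(mean(dab[r2 <= 3.5^2]), 0.3)
  expect_lt(mean(dab[r2 > 6^2]), 0.05)
  # determinism of the render
  expect_identical(img1$raster, render_ki67_image(one, NULL, sp)$raster)
})

test_that("disc centroids in the render match the table within one pixel", {
  case <- small_case_rendered()
  conc <- deconvolve(rgb_to_od(case$ki67_image))
  bw <- EBImage::gblur(conc$h + conc$dab, 1) > 0.3
  lab <- EBImage::bwlabel(bw)
  mom <- EBImage::computeFeatures.moment(lab)
  det <- data.frame(x = mom[, "m.cy"], y = mom[, "m.cx"])
  # match each isolated blob to the nearest ground-truth centroid
  nn <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((case$cells$x_um - det$x[i])^2 + (case$cells$y_um - det$y[i])^2))
  }, numeric(1))
  expect_lt(stats::median(nn), 1)
})

test_that("CK rendering recovers the epithelial layout under the transform", {
  res <- 4; dims <- c(300, 300)
  sp0 <- small_spec(seed = 9, serial_shift_um = c(0, 0),
                    serial_rotation_deg = 0, ck_jitter_um = 0)
  rg <- generate_regions(sp0)
  truth <- ki67hotspot:::epithelium_raster(rg, dims, res)
  ck0 <- render_ck_serial(NULL, rg, sp0)
  epi <- ki67hotspot:::downsample_any(ck_epithelium_mask(ck0$image), res)
  iou <- sum(epi & truth) / sum(epi | truth)
  expect_gte(iou, 0.99)
  # known shift: CK mask equals the shifted polygon raster
  sp1 <- small_spec(seed = 9, serial_shift_um = c(120, -80),
                    serial_rotation_deg = 0, ck_jitter_um = 0)
  ck1 <- render_ck_serial(NULL, rg, sp1)
  shifted <- ki67hotspot:::epithelium_raster(ck1$regions_ck, dims, res)
  epi1 <- ki67hotspot:::downsample_any(ck_epithelium_mask(ck1$image), res)
  expect_gte(sum(epi1 & shifted) / sum(epi1 | shifted), 0.98)
  expect_equal(ck1$transform$dx_um, 120)
  expect_equal(ck1$transform$theta_deg, 0)
})

test_that("a case round-trips through the on-disk format", {
  dir <- withr::local_tempdir()
  case <- small_case_rendered()
  man1 <- write_case(case, dir)
  back <- read_case(dir)
  # cell table identical row for row
  expect_equal(as.data.frame(back$cells), as.data.frame(case$cells),
               tolerance = 1e-12)
  # GeoJSON polygons within 1e-6 um
  for (i in seq_along(case$regions)) {
    expect_equal(back$regions[[i]]$region_class, case$regions[[i]]$region_class)
    expect_lt(max(abs(close_ring(back$regions[[i]]$polygon) -
                      close_ring(case$regions[[i]]$polygon))), 1e-6)
  }
  # images and resolution metadata
  expect_identical(back$ki67_image$raster, case$ki67_image$raster)
  expect_equal(back$ki67_image$resolution_um_per_px,
               case$spec$resolution_um_per_px, tolerance = 1e-6)
  expect_identical(back$true_serial_transform, case$true_serial_transform)
  # rewriting the identical case reproduces identical checksums
  dir2 <- withr::local_tempdir()
  man2 <- write_case(case, dir2)
  expect_identical(unname(unlist(man1)), unname(unlist(man2)))
})

test_that("excessive density triggers the hard-core generation error", {
  sp <- small_spec(tumour_density_per_mm2 = 12000)
  rg <- generate_regions(sp)
  expect_error(sample_cells(sp, rg), class = "ki67_generation_error")
})
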