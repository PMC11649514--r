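# Serial-section registration, the two masking arms, and cell filtering.

test_that("identity registration is recovered on identical layouts", {
  m <- case_masks(reg_spec(seed = 2, serial_shift_um = c(0, 0),
                           serial_rotation_deg = 0, ck_jitter_um = 0))
  reg <- register_masks(m$fixed, m$moving, m$res)
  expect_equal(reg$status, "success")
  expect_lt(abs(reg$transform$dx_um), 2)
  expect_lt(abs(reg$transform$dy_um), 2)
  expect_lt(abs(reg$transform$theta_deg), 0.1)
  expect_gt(reg$alignment_score, 0.95)
})

test_that("a known rigid transform is recovered within 5 um / 0.5 degrees", {
  m <- case_masks(reg_spec(seed = 4, serial_shift_um = c(120, -80),
                           serial_rotation_deg = 1))
  reg <- register_masks(m$fixed, m$moving, m$res)
  expect_equal(reg$status, "success")
  expect_lt(sqrt((reg$transform$dx_um - 120)^2 + (reg$transform$dy_um + 80)^2), 5)
  expect_lt(abs(reg$transform$theta_deg - 1), 0.5)
})

test_that("image-level serial registration recovers the generator transform", {
  sp <- small_spec(seed = 5, serial_shift_um = c(120, -80),
                   serial_rotation_deg = 1)
  case <- simulate_case(sp)
  reg <- register_serial(case$ck_image, case$ki67_image)
  expect_equal(reg$status, "success")
  expect_lt(sqrt((reg$transform$dx_um - 120)^2 + (reg$transform$dy_um + 80)^2), 5)
  expect_lt(abs(reg$transform$theta_deg - 1), 0.5)
})

test_that("blank foregrounds fail with score zero", {
  blank <- matrix(FALSE, 100, 100)
  reg <- register_masks(blank, blank, 4)
  expect_equal(reg$status, "failed")
  expect_equal(reg$alignment_score, 0)
})

test_that("non-serial sections are flagged as registration failures", {
  for (s in 1:4) {
    m <- case_masks(reg_spec(seed = s, serial_mode = "non_serial"))
    reg <- register_masks(m$fixed, m$moving, m$res)
    expect_equal(reg$status, "failed")
    expect_lt(reg$alignment_score, 0.6)
  }
})

test_that("the VDS mask matches ground-truth epithelium and honours exclusions", {
  sp <- reg_spec(seed = 6, serial_shift_um = c(0, 0), serial_rotation_deg = 0,
                 ck_jitter_um = 0, benign_region_count = 2,
                 insitu_region_count = 1, insitu_positivity = 0.9)
  m <- case_masks(sp)
  cells <- sample_cells(sp, m$regions)
  reg <- register_masks(m$fixed, m$moving, m$res)
  # no exclusions: epithelium recovered
  mask0 <- build_mask_vds(m$moving, reg, res_um = m$res)
  iou <- sum(mask0$mask & m$fixed) / sum(mask0$mask | m$fixed)
  expect_gte(iou, 0.95)
  # with exclusions: no benign or in-situ centroid survives filtering
  excl <- Filter(function(r) r$region_class %in%
                   c("benign_epithelium", "carcinoma_in_situ"), m$regions)
  mask1 <- build_mask_vds(m$moving, reg, exclusion_regions = excl,
                          res_um = m$res)
  kept <- filter_cells_by_mask(cells, mask1)
  expect_false(any(kept$region_class %in%
                   c("benign_epithelium", "carcinoma_in_situ")))
  # invasive cells are essentially all retained
  expect_gt(nrow(kept) / sum(cells$region_class == "invasive_tumour"), 0.95)
})

test_that("a failed registration refuses to build a VDS mask", {
  m <- case_masks(reg_spec(seed = 3, serial_mode = "non_serial"))
  reg <- register_masks(m$fixed, m$moving, m$res)
  expect_error(build_mask_vds(m$moving, reg, res_um = m$res),
               class = "vds_registration_failure")
})

test_that("the rule mask equals rasterised invasive polygons and excludes
           distractors even at high in-situ positivity", {
  sp <- reg_spec(seed = 7, insitu_positivity = 0.95, insitu_region_count = 2)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  mask <- build_mask_rule(regions = rg, res_um = 4,
                          extent_um = c(sp$width_um, sp$height_um))
  truth <- rasterize_regions(rg, dim(mask$mask), 4, classes = "invasive_tumour")
  expect_gte(sum(mask$mask & truth) / sum(mask$mask | truth), 0.99)
  kept <- filter_cells_by_mask(cells, mask)
  expect_false(any(kept$region_class %in%
                   c("benign_epithelium", "carcinoma_in_situ")))
  # the hotspot is never centred in an in-situ region
  hs <- find_hotspot(kept, extent_um = c(sp$width_um, sp$height_um))
  ctr <- hs$origin_um + hs$side_um / 2
  for (rg1 in rg) {
    if (rg1$region_class == "carcinoma_in_situ") {
      expect_false(point_in_polygon(ctr[1], ctr[2], rg1$polygon))
    }
  }
  expect_error(build_mask_rule(), "regions or a detector")
})

test_that("filter_cells_by_mask keeps exactly the cells inside the mask", {
  set.seed(11)
  cells <- random_cells(300, c(400, 400))
  full <- ki67hotspot:::new_tumour_mask(matrix(TRUE, 100, 100), 4, "rule")
  expect_equal(nrow(filter_cells_by_mask(cells, full)), 300)
  none <- ki67hotspot:::new_tumour_mask(matrix(FALSE, 100, 100), 4, "rule")
  expect_equal(nrow(filter_cells_by_mask(cells, none)), 0)
  # half-plane mask: exactly the cells left of the boundary remain
  half <- matrix(FALSE, 100, 100); half[, 1:50] <- TRUE
  hm <- ki67hotspot:::new_tumour_mask(half, 4, "rule")
  kept <- filter_cells_by_mask(cells, hm)
  expect_setequal(kept$id, cells$id[cells$x_um < 200])
})

test_that("rule-arm availability is never below VDS-arm availability", {
  base <- list(width_um = 2000, height_um = 2000, invasive_fraction = 0.55,
               hotspot_center_um = c(1000, 1500))
  cfg <- study_config(n_cases = 6, seed = 5, base_spec = base,
                      nonserial_cases = c(2, 5))
  rep <- run_study(cfg)
  n_rule <- sum(rep$scores$arm == "rule")
  n_vds <- sum(rep$scores$arm == "vds")
  expect_equal(n_rule, 6)
  expect_equal(n_vds, 4)
  expect_setequal(rep$vds_excluded, c("case_002", "case_005"))
  expect_lte(n_vds, n_rule)
})
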