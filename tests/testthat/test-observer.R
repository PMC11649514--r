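# Simulated observers: perceptual hotspot choice, typewriter counting, and
# manual PI scoring.

make_grid_cells <- function(rows, per_row, x0 = 100, y0 = 100, dx = 10,
                            row_h = 20, ratio = 0.4) {
  n <- rows * per_row
  data.frame(id = seq_len(n),
             x_um = x0 + rep(seq_len(per_row) - 1, rows) * dx,
             y_um = y0 + rep(seq_len(rows) - 1, each = per_row) * row_h,
             diameter_um = 8,
             ki67_class = rep(c("positive", "negative"), length.out = n),
             region_class = "invasive_tumour", stringsAsFactors = FALSE)
}

test_that("zero noise picks the dominant bin deterministically", {
  sp <- small_spec(seed = 12)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  prof <- observer_profile(perception_noise_sd = 0)
  r1 <- perceive_hotspot(cells, rg, prof, c(1200, 1200), seed = 1)
  r2 <- perceive_hotspot(cells, rg, prof, c(1200, 1200), seed = 99)
  expect_identical(r1$origin_um, r2$origin_um)
  # the chosen bin centre sits near the planted hotspot
  expect_lt(sqrt(sum((r1$bin_center_um - sp$hotspot_center_um)^2)), 500)
})

test_that("exact perception ties break to the smaller bin y, then x", {
  # two bins with identical ratio and count, zero noise
  mk <- function(cx, cy, id0) {
    data.frame(id = id0 + 1:100,
               x_um = runif(100, cx - 100, cx + 100),
               y_um = runif(100, cy - 100, cy + 100),
               ki67_class = rep(c("positive", "negative"), 50),
               region_class = "invasive_tumour")
  }
  set.seed(13)
  cells <- rbind(mk(1875, 875, 0), mk(875, 1875, 100))
  rg <- list(list(polygon = rbind(c(0, 0), c(2500, 0), c(2500, 2500),
                                  c(0, 2500)),
                  region_class = "invasive_tumour"))
  prof <- observer_profile(perception_noise_sd = 0)
  r <- perceive_hotspot(cells, rg, prof, c(2500, 2500), seed = 1)
  # both bins perceive equal down-weighted ratios; smaller y wins
  expect_equal(r$bin_center_um[2], 875)
})

test_that("a dominant bin wins against noise most of the time", {
  mk <- function(cx, cy, ratio, id0) {
    n <- 200
    data.frame(id = id0 + seq_len(n),
               x_um = runif(n, cx - 120, cx + 120),
               y_um = runif(n, cy - 120, cy + 120),
               ki67_class = c(rep("positive", round(n * ratio)),
                              rep("negative", n - round(n * ratio))),
               region_class = "invasive_tumour")
  }
  set.seed(14)
  cells <- rbind(mk(625, 625, 0.6, 0), mk(1875, 1875, 0.5, 200))
  rg <- list(list(polygon = rbind(c(0, 0), c(2500, 0), c(2500, 2500),
                                  c(0, 2500)),
                  region_class = "invasive_tumour"))
  prof <- observer_profile(perception_noise_sd = 0.05)
  wins <- vapply(1:100, function(s) {
    r <- perceive_hotspot(cells, rg, prof, c(2500, 2500), seed = s)
    r$bin_center_um[1] < 1250
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("typewriter counting stops at the end of the 500th cell's row", {
  set.seed(15)
  # 25 rows of exactly 25 cells: the 500th cell ends row 20 exactly
  cells <- make_grid_cells(rows = 25, per_row = 25)
  prof <- observer_profile(count_row_um = 20, classification_flip_prob = 0)
  roi <- list(origin_um = c(90, 90), side_um = 400)
  cnt <- typewriter_count(cells, roi, prof, extent_um = c(700, 700),
                          seed = 1)
  expect_equal(cnt$n_counted, 500L)
  # 30 cells per row: 500th cell is mid-row, count to the end of that row
  cells2 <- make_grid_cells(rows = 20, per_row = 30)
  cnt2 <- typewriter_count(cells2, roi, prof, extent_um = c(700, 700),
                           seed = 1)
  expect_equal(cnt2$n_counted, 510L)  # ceiling(500/30)*30
})

test_that("an undersized ROI is enlarged until it holds 500 cells", {
  sp <- small_spec(seed = 16)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  prof <- observer_profile()
  tiny <- list(origin_um = c(550, 750), side_um = 100)
  cnt <- typewriter_count(cells, tiny, prof, extent_um = c(1200, 1200),
                          seed = 2)
  expect_gte(cnt$n_counted, 500)
  expect_gt(cnt$roi$side_um, 100)
})

test_that("fewer than 500 invasive cells on the slide is an error", {
  set.seed(17)
  few <- random_cells(120, c(1000, 1000))
  few$region_class <- "invasive_tumour"
  expect_error(typewriter_count(few, list(origin_um = c(0, 0), side_um = 700),
                                observer_profile(), extent_um = c(1000, 1000)),
               "fewer than 500")
})

test_that("noise-free scoring is deterministic and all-negative slides give 0", {
  sp0 <- small_spec(seed = 18, baseline_positivity = 0,
                    hotspot_peak_positivity = 0)
  case0 <- simulate_case(sp0, render = FALSE)
  prof0 <- observer_profile(perception_noise_sd = 0,
                            classification_flip_prob = 0)
  for (s in c(1, 2, 3)) {
    sc <- score_manual(case0, prof0, observer_id = 1, seed = s)
    expect_equal(sc$pi_percent, 0.0)
  }
  sp1 <- small_spec(seed = 18)
  case1 <- simulate_case(sp1, render = FALSE)
  a <- score_manual(case1, prof0, observer_id = 1, seed = 5)
  b <- score_manual(case1, prof0, observer_id = 1, seed = 9)
  expect_equal(a$pi_percent, b$pi_percent)
  expect_equal(a$n_counted, b$n_counted)
})

test_that("a noise-free observer on the automated window scores within
           binomial error of the window PI", {
  sp <- small_spec(seed = 19)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  inv <- cells[cells$region_class == "invasive_tumour", ]
  attr(inv, "extent_um") <- attr(cells, "extent_um")
  hs <- find_hotspot(inv, extent_um = c(1200, 1200))
  prof <- observer_profile(perception_noise_sd = 0,
                           classification_flip_prob = 0)
  roi <- list(origin_um = hs$origin_um, side_um = hs$side_um)
  cnt <- typewriter_count(cells, roi, prof, extent_um = c(1200, 1200),
                          seed = 1)
  obs_pi <- 100 * cnt$n_positive_counted / cnt$n_counted
  p <- hs$pi_percent / 100
  expect_lt(abs(obs_pi - hs$pi_percent),
            3 * 100 * sqrt(p * (1 - p) / cnt$n_counted) + 1)
})
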