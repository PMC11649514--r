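# Heatmap binning, the lattice hotspot search, its brute-force oracle, and
# the minimum-cell-count behaviour.

test_that("compute_pi follows the printed-percentage convention", {
  expect_equal(compute_pi(0, 500), 0.0)
  expect_equal(compute_pi(500, 500), 100.0)
  expect_equal(compute_pi(250, 500), 50.0)
  expect_equal(compute_pi(1, 3), 33.3)
  expect_error(compute_pi(1, 0), ">= 1")
  expect_error(compute_pi(5, 3), "<= n_total")
})

test_that("heatmap bins tally cells exactly and leave empty bins undefined", {
  p <- search_params(heatmap_bin_um = 50)
  one <- data.frame(x_um = 130, y_um = 270, ki67_class = "positive")
  hm <- build_heatmap(one, p, extent_um = c(500, 500))
  hit <- hm[hm$total > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$bin_x, hit$bin_y, hit$total, hit$positive, hit$ratio),
               c(100, 250, 1, 1, 1.0))
  expect_true(all(is.na(hm$ratio[hm$total == 0])))
  # all-positive labels give ratio 1 in every occupied bin
  set.seed(1)
  cells <- random_cells(200, c(500, 500), p_positive = 1)
  hm2 <- build_heatmap(cells, p, extent_um = c(500, 500))
  expect_true(all(hm2$ratio[hm2$total > 0] == 1))
  # per-bin tallies equal a direct per-cell tally
  set.seed(2)
  cells <- random_cells(500, c(500, 500))
  hm3 <- build_heatmap(cells, p, extent_um = c(500, 500))
  for (k in sample(nrow(hm3), 40)) {
    inb <- cells$x_um >= hm3$bin_x[k] & cells$x_um < hm3$bin_x[k] + 50 &
           cells$y_um >= hm3$bin_y[k] & cells$y_um < hm3$bin_y[k] + 50
    expect_equal(hm3$total[k], sum(inb))
    expect_equal(hm3$positive[k], sum(inb & cells$ki67_class == "positive"))
  }
  expect_equal(sum(hm3$total), nrow(cells))
})

test_that("a single eligible window reports its exact counts and PI", {
  # slide barely larger than the window: the lattice holds exactly one
  # candidate, so the counts are the cluster's counts
  set.seed(3)
  cells <- cell_cluster(600, cx = 350, cy = 350, half = 300, ratio = 0.5)
  hs <- find_hotspot(cells, extent_um = c(707.2, 707.2))
  expect_equal(hs$n_cells, 600L)
  expect_equal(hs$n_positive, 300L)
  expect_equal(hs$pi_percent, 50.0)
  expect_equal(hs$origin_um, c(0, 0))
})

test_that("the higher-ratio cluster wins when both are eligible", {
  set.seed(4)
  cells <- rbind(cell_cluster(600, 500, 500, ratio = 0.8),
                 cell_cluster(600, 2500, 2500, ratio = 0.6, id0 = 600))
  hs <- find_hotspot(cells, extent_um = c(3000, 3000))
  expect_lt(hs$origin_um[1], 1000)   # sits on cluster A
  expect_gte(hs$pi_percent, 80)      # at least A's overall ratio
  expect_gte(hs$n_cells, 500L)
})

test_that("a 499-cell cluster at ratio 1 loses to an eligible 600-cell cluster", {
  set.seed(5)
  cells <- rbind(cell_cluster(499, 500, 500, ratio = 1),
                 cell_cluster(600, 2500, 2500, ratio = 0.5, id0 = 499))
  hs <- find_hotspot(cells, extent_um = c(3000, 3000))
  expect_gt(hs$origin_um[1], 1500)   # the 499-cell cluster is ineligible
  expect_gte(hs$n_cells, 500L)
  expect_lt(hs$pi_percent, 60)
})

test_that("the lattice search equals brute-force enumeration exactly", {
  for (s in 1:12) {
    set.seed(s)
    cells <- random_cells(800 + s * 50, c(1000, 1000),
                          p_positive = runif(1, 0.2, 0.8))
    p <- search_params(stride_um = 50, min_cells = 100)
    a <- find_hotspot(cells, p, extent_um = c(1000, 1000))
    b <- brute_force_hotspot(cells, p, extent_um = c(1000, 1000))
    expect_identical(a$origin_um, b$origin_um)
    expect_identical(a$n_cells, b$n_cells)
    expect_identical(a$n_positive, b$n_positive)
    expect_identical(a$pi_percent, b$pi_percent)
  }
})

test_that("no eligible window raises the unscorable-case error in both paths", {
  set.seed(6)
  cells <- random_cells(100, c(1000, 1000))
  expect_error(find_hotspot(cells, extent_um = c(1000, 1000)),
               class = "hotspot_no_window")
  expect_error(brute_force_hotspot(cells, extent_um = c(1000, 1000)),
               class = "hotspot_no_window")
})

test_that("raising the DAB threshold never increases the positive count", {
  case <- small_case_rendered()
  det <- detect_nuclei(case$ki67_image)
  thr <- seq(0.05, 0.6, by = 0.05)
  npos <- vapply(thr, function(t) {
    sum(classify_nuclei(det, detection_params(dab_positive_threshold = t))$
          ki67_class == "positive")
  }, numeric(1))
  expect_true(all(diff(npos) <= 0))
})

test_that("hotspot PI is at least the global PI when all tiles are eligible", {
  sp <- small_spec(seed = 31)
  rg <- generate_regions(sp)
  cells <- sample_cells(sp, rg)
  inv <- cells[cells$region_class == "invasive_tumour", ]
  attr(inv, "extent_um") <- attr(cells, "extent_um")
  hs <- find_hotspot(inv, extent_um = c(1200, 1200))
  expect_gte(hs$pi_percent,
             compute_pi(sum(inv$ki67_class == "positive"), nrow(inv)))
})

test_that("a sparse high-ratio margin yields a hotspot near the minimum count", {
  # interior: dense, low ratio; margin strip: just over the minimum per
  # window at ratio ~0.9 - the search must sit on the margin with barely
  # eligible windows
  set.seed(7)
  p <- search_params()
  side <- p$window_side_um
  dense <- data.frame(x_um = runif(6000, 1200, 3000),
                      y_um = runif(6000, 0, 3000),
                      ki67_class = ifelse(runif(6000) < 0.2,
                                          "positive", "negative"))
  marg_n <- 1030  # ~515 cells per window-sized strip segment
  margin <- data.frame(x_um = runif(marg_n, 0, 2 * side),
                       y_um = runif(marg_n, 3100, 3100 + side),
                       ki67_class = ifelse(runif(marg_n) < 0.9,
                                           "positive", "negative"))
  cells <- rbind(dense, margin)
  hs <- find_hotspot(cells, p, extent_um = c(4000, 4000))
  expect_gte(hs$n_cells, p$min_cells)
  expect_lte(hs$n_cells, 1.1 * p$min_cells)
  expect_gt(hs$pi_percent, 80)
})
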