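# Simulated human observers: visual hotspot selection on a coarse perceptual
# grid with additive noise, ROI annotation, and the standardized 500-cell
# "typewriter" count (raster order, stop at the end of the row in which the
# 500th cell is reached - the mechanism behind observed counts of 500-533).

#' Observer behaviour profile
#'
#' @param perception_bin_um grid at which the observer "sees" the positivity
#'   landscape (a ~250 um mental bin, far coarser than the algorithmic
#'   heatmap).
#' @param perception_noise_sd additive Gaussian noise on perceived bin ratios.
#' @param classification_flip_prob per-cell probability of misreading the
#'   Ki67 class while counting.
#' @param roi_side_um side of the annotated ROI (defaults to the hotspot
#'   window side, 707.107 um).
#' @param count_row_um height of one counting row in the typewriter pattern.
#'   At realistic hotspot densities (~1400 nuclei/mm^2) a 20 um row holds
#'   ~20 cells, reproducing reported total counts in the 500-533 range.
#' @param seed default seed for [score_manual()].
#' @return object of class `observer_profile`.
#' @export
observer_profile <- function(perception_bin_um = 250,
                             perception_noise_sd = 0.05,
                             classification_flip_prob = 0.03,
                             roi_side_um = hotspot_window_side(),
                             count_row_um = 20,
                             seed = NULL) {
  stopifnot(perception_bin_um > 0, perception_noise_sd >= 0,
            classification_flip_prob >= 0, classification_flip_prob <= 1,
            roi_side_um > 0, count_row_um > 0)
  structure(list(perception_bin_um = perception_bin_um,
                 perception_noise_sd = perception_noise_sd,
                 classification_flip_prob = classification_flip_prob,
                 roi_side_um = roi_side_um, count_row_um = count_row_um,
                 seed = seed),
            class = "observer_profile")
}

#' Visual hotspot selection
#'
#' The observer reads the true slide: invasive-tumour cells are tallied on the
#' coarse perception grid, Gaussian noise is added to each non-empty bin's
#' positive ratio, and bins too sparse to support a 500-cell count (fewer than
#' min_cells * bin_area / window_area cells) are down-weighted in proportion
#' to their occupancy - observers judge the "apparent highest proliferation
#' rate" from areas dense enough to read, not from a handful of margin cells.
#' The ROI is centred on the winning bin, clipped to the invasive region's
#' bounding box and the slide. Zero noise with a single dominant bin is
#' deterministic; exact ties break to the smaller bin y, then x.
#'
#' @param truth_cells ground-truth cells ([sample_cells()]).
#' @param regions the case's `region_set` (for the invasive bounding box).
#' @param profile an [observer_profile()].
#' @param extent_um slide extent c(width, height).
#' @param search a [search_params()] (supplies min_cells and window area for
#'   the sparse-bin rule).
#' @param seed optional; NULL uses the current RNG stream.
#' @return list: `origin_um` (x0, y0), `side_um`, `bin_um` centre of the
#'   chosen perception bin.
#' @export
perceive_hotspot <- function(truth_cells, regions, profile = observer_profile(),
                             extent_um = attr(truth_cells, "extent_um"),
                             search = search_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inv <- truth_cells[truth_cells$region_class == "invasive_tumour", ,
                     drop = FALSE]
  if (!nrow(inv)) stop("no invasive cells to perceive")
  b <- profile$perception_bin_um
  nx <- max(1L, ceiling(extent_um[1] / b)); ny <- max(1L, ceiling(extent_um[2] / b))
  ix <- pmin(nx, floor(inv$x_um / b) + 1L)
  iy <- pmin(ny, floor(inv$y_um / b) + 1L)
  key <- (iy - 1L) * nx + ix
  total <- tabulate(key, nbins = nx * ny)
  positive <- tabulate(key[inv$ki67_class == "positive"], nbins = nx * ny)
  nonempty <- which(total > 0)
  ratio <- positive[nonempty] / total[nonempty]
  sparse_thr <- search$min_cells * b^2 / search$window_side_um^2
  weight <- pmin(1, total[nonempty] / sparse_thr)
  perceived <- ratio * weight +
    stats::rnorm(length(nonempty), 0, profile$perception_noise_sd)
  byy <- (nonempty - 1L) %/% nx; bxx <- (nonempty - 1L) %% nx
  pick <- order(-perceived, byy, bxx)[1]
  cx <- (bxx[pick] + 0.5) * b; cy <- (byy[pick] + 0.5) * b
  side <- profile$roi_side_um
  bb <- apply(Filter(function(r) r$region_class == "invasive_tumour",
                     regions)[[1]]$polygon, 2, range)
  clamp <- function(o, lo, hi) min(max(o, lo), hi)
  lo_x <- max(0, bb[1, 1]); hi_x <- min(extent_um[1], bb[2, 1]) - side
  lo_y <- max(0, bb[1, 2]); hi_y <- min(extent_um[2], bb[2, 2]) - side
  if (hi_x < lo_x) { lo_x <- 0; hi_x <- extent_um[1] - side }
  if (hi_y < lo_y) { lo_y <- 0; hi_y <- extent_um[2] - side }
  list(origin_um = c(clamp(cx - side / 2, lo_x, max(lo_x, hi_x)),
                     clamp(cy - side / 2, lo_y, max(lo_y, hi_y))),
       side_um = side, bin_center_um = c(cx, cy))
}

#' Typewriter count of 500 tumour cells in an ROI
#'
#' Invasive cells inside the (half-open) ROI are visited in raster order: rows
#' of height `count_row_um` top to bottom, left to right within a row.
#' Counting stops at the end of the row in which the 500th cell is reached, so
#' the total count lands in [500, 500 + row capacity). Each counted cell's
#' true class is misread with `classification_flip_prob`. An ROI with fewer
#' than 500 invasive cells is enlarged in 10% steps about its centre (clipped
#' to the slide) until it holds 500.
#'
#' @param truth_cells ground-truth cells.
#' @param roi list with `origin_um` and `side_um` (from [perceive_hotspot()]).
#' @param profile an [observer_profile()].
#' @param extent_um slide extent.
#' @param min_count cells to count (500 by the standardized protocol).
#' @param seed optional; NULL uses the current RNG stream.
#' @return list: n_counted, n_positive_counted, roi (possibly enlarged).
#' @export
typewriter_count <- function(truth_cells, roi, profile = observer_profile(),
                             extent_um = attr(truth_cells, "extent_um"),
                             min_count = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inv <- truth_cells[truth_cells$region_class == "invasive_tumour", ,
                     drop = FALSE]
  if (nrow(inv) < min_count) {
    stop("fewer than ", min_count, " invasive cells on the whole slide")
  }
  o <- roi$origin_um; side <- roi$side_um
  centre <- o + side / 2
  repeat {
    sel <- inv$x_um >= o[1] & inv$x_um < o[1] + side &
           inv$y_um >= o[2] & inv$y_um < o[2] + side
    if (sum(sel) >= min_count) break
    side <- side * 1.1
    o <- pmax(c(0, 0), pmin(centre - side / 2, extent_um - side))
    o <- pmax(o, c(0, 0))
    side <- min(side, min(extent_um))
  }
  cc <- inv[sel, , drop = FALSE]
  row <- floor((cc$y_um - o[2]) / profile$count_row_um)
  ord <- order(row, cc$x_um)
  cc <- cc[ord, , drop = FALSE]; row <- row[ord]
  stop_row <- row[min_count]
  n_counted <- max(which(row == stop_row))
  counted <- cc[seq_len(n_counted), , drop = FALSE]
  flip <- stats::runif(n_counted) < profile$classification_flip_prob
  observed_pos <- xor(counted$ki67_class == "positive", flip)
  list(n_counted = n_counted,
       n_positive_counted = as.integer(sum(observed_pos)),
       roi = list(origin_um = o, side_um = side))
}

#' Full manual scoring of one case by one observer
#'
#' Perceive a hotspot, annotate the ROI, count by typewriter pattern, and
#' report PI = 100 * positives / counted. With zero perception noise and zero
#' flip probability the score is deterministic given the case.
#'
#' @param case a `synthetic_case` (or a list with `cells` and `regions`).
#' @param profile an [observer_profile()].
#' @param observer_id label recorded on the score.
#' @param seed integer; defaults to the profile seed, else the case seed
#'   combined with the observer id.
#' @return object of class `observer_score`: roi origin/side, n_counted,
#'   n_positive_counted, pi_percent, observer_id, seed.
#' @export
score_manual <- function(case, profile = observer_profile(), observer_id = 1,
                         seed = NULL) {
  if (is.null(seed)) {
    seed <- if (!is.null(profile$seed)) profile$seed else
      derive_seed(case$spec$seed, paste0("observer", observer_id))
  }
  set.seed(seed)
  extent <- attr(case$cells, "extent_um")
  roi <- perceive_hotspot(case$cells, case$regions, profile, extent)
  cnt <- typewriter_count(case$cells, roi, profile, extent)
  structure(list(roi_origin_um = cnt$roi$origin_um,
                 roi_side_um = cnt$roi$side_um,
                 n_counted = cnt$n_counted,
                 n_positive_counted = cnt$n_positive_counted,
                 pi_percent = compute_pi(cnt$n_positive_counted, cnt$n_counted),
                 observer_id = observer_id, seed = seed),
            class = "observer_score")
}

#' @export
print.observer_score <- function(x, ...) {
  cat(sprintf("observer %s: counted %d (%d Ki67+), PI %.1f%%\n",
              x$observer_id, x$n_counted, x$n_positive_counted, x$pi_percent))
  invisible(x)
}
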