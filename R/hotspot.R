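# Fixed-area square hotspot search under a minimum-cell constraint.
# The hotspot is the axis-aligned 0.5 mm^2 window (side 707.107 um), placed on
# a stride lattice fully inside the slide, holding >= 500 masked tumour cells,
# that maximises the Ki67-positive ratio. The PI is computed over ALL cells in
# the window (observed counts routinely exceed the 500 minimum).

#' Hotspot search parameters
#'
#' @param hotspot_area_mm2 window area; side = sqrt(area) mm.
#' @param min_cells minimum number of (masked) cells a window must contain to
#'   be eligible.
#' @param stride_um candidate-origin lattice pitch.
#' @param heatmap_bin_um bin size of the diagnostic ratio heatmap.
#' @return object of class `search_params` with the derived `window_side_um`.
#' @export
search_params <- function(hotspot_area_mm2 = 0.5, min_cells = 500,
                          stride_um = 25, heatmap_bin_um = 50) {
  stopifnot(hotspot_area_mm2 > 0, min_cells >= 1, stride_um > 0,
            heatmap_bin_um > 0)
  structure(list(hotspot_area_mm2 = hotspot_area_mm2,
                 window_side_um = hotspot_window_side(hotspot_area_mm2),
                 min_cells = as.integer(min_cells),
                 stride_um = stride_um, heatmap_bin_um = heatmap_bin_um),
            class = "search_params")
}

#' Proliferation index in percent
#'
#' 100 * n_positive / n_total, reported to one decimal (the convention of
#' printed Ki67 hotspot PIs).
#'
#' @param n_positive,n_total non-negative counts, n_positive <= n_total,
#'   n_total >= 1.
#' @return percentage rounded to one decimal.
#' @export
compute_pi <- function(n_positive, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(n_positive < 0) || any(n_positive > n_total)) {
    stop("need 0 <= n_positive <= n_total")
  }
  round(100 * n_positive / n_total, 1)
}

#' Ki67-ratio heatmap over masked cells
#'
#' Cells are binned by centroid into half-open square bins; per-bin totals,
#' positive counts and ratios. Empty bins carry an undefined (NA) ratio, never
#' zero, so cell-free area cannot dilute the map.
#'
#' @param cells a cell table (already mask-filtered) with x_um, y_um,
#'   ki67_class.
#' @param params a [search_params()].
#' @param extent_um slide extent c(width, height); defaults to the table's
#'   `extent_um` attribute.
#' @return data.frame of class `heatmap_grid`: bin_x, bin_y (origin um),
#'   total, positive, ratio; attribute `bin_um`.
#' @export
build_heatmap <- function(cells, params = search_params(),
                          extent_um = attr(cells, "extent_um")) {
  b <- params$heatmap_bin_um
  if (b <= 0) stop("bin size must be positive")
  nx <- max(1L, ceiling(extent_um[1] / b))
  ny <- max(1L, ceiling(extent_um[2] / b))
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  total <- positive <- integer(nrow(grid))
  if (nrow(cells)) {
    ix <- pmin(nx, floor(cells$x_um / b) + 1L)
    iy <- pmin(ny, floor(cells$y_um / b) + 1L)
    key <- (iy - 1L) * nx + ix
    tt <- tabulate(key, nbins = nx * ny)
    pp <- tabulate(key[cells$ki67_class == "positive"], nbins = nx * ny)
    kk <- (grid$iy - 1L) * nx + grid$ix
    total <- tt[kk]; positive <- pp[kk]
  }
  out <- data.frame(bin_x = (grid$ix - 1L) * b, bin_y = (grid$iy - 1L) * b,
                    total = total, positive = positive,
                    ratio = ifelse(total > 0, positive / total, NA_real_))
  attr(out, "bin_um") <- b
  attr(out, "extent_um") <- extent_um
  class(out) <- c("heatmap_grid", "data.frame")
  out
}

# index range of lattice origins whose half-open window [o, o + side) contains
# coordinate v; origins are k * stride, k = 0 .. nk - 1. Direct-comparison
# fix-ups make the ranges exactly consistent with `v >= o & v < o + side`.
origin_index_range <- function(v, side, stride, nk) {
  lo <- floor((v - side) / stride) + 1
  lo_ok <- v < (lo - 1) * stride + side
  lo[lo_ok] <- lo[lo_ok] - 1
  bump <- !(v < lo * stride + side)
  lo[bump] <- lo[bump] + 1
  hi <- floor(v / stride)
  hi_ok <- v >= (hi + 1) * stride
  hi[hi_ok] <- hi[hi_ok] + 1
  drop <- v < hi * stride
  hi[drop] <- hi[drop] - 1
  cbind(pmax(lo, 0), pmin(hi, nk - 1))
}

# per-window cell counts on the full candidate lattice via a 2-D difference
# array: each cell adds +1 over a rectangle of origin indices, then two
# cumulative sums produce the counts. Exact integer tallies.
window_counts <- function(x, y, positive, side, stride, nkx, nky) {
  cnt <- function(xs, ys) {
    D <- matrix(0, nky + 1L, nkx + 1L)
    if (length(xs)) {
      rx <- origin_index_range(xs, side, stride, nkx)
      ry <- origin_index_range(ys, side, stride, nky)
      ok <- rx[, 1] <= rx[, 2] & ry[, 1] <= ry[, 2]
      rx <- rx[ok, , drop = FALSE]; ry <- ry[ok, , drop = FALSE]
      if (nrow(rx)) {
        add <- function(i, j, v) {
          m <- cbind(i + 1L, j + 1L)
          u <- rowsum(v, group = (m[, 1] - 1) * (nkx + 1) + m[, 2])
          idx <- as.integer(rownames(u))
          D[cbind((idx - 1) %/% (nkx + 1) + 1, (idx - 1) %% (nkx + 1) + 1)] <<-
            D[cbind((idx - 1) %/% (nkx + 1) + 1, (idx - 1) %% (nkx + 1) + 1)] + u[, 1]
          invisible(NULL)
        }
        add(ry[, 1], rx[, 1], rep(1, nrow(rx)))
        add(ry[, 1], rx[, 2] + 1L, rep(-1, nrow(rx)))
        add(ry[, 2] + 1L, rx[, 1], rep(-1, nrow(rx)))
        add(ry[, 2] + 1L, rx[, 2] + 1L, rep(1, nrow(rx)))
      }
    }
    M <- apply(D, 2, cumsum)
    M <- t(apply(M, 1, cumsum))
    M[seq_len(nky), seq_len(nkx), drop = FALSE]
  }
  list(total = cnt(x, y), positive = cnt(x[positive], y[positive]))
}

# deterministic selection shared by the search and its oracle: maximise the
# positive ratio exactly (integer cross-multiplication), break ties by higher
# n_cells, then smaller y0, then smaller x0
select_best_window <- function(pos, tot, x0, y0) {
  best <- 1L
  for (i in seq_along(pos)[-1]) {
    a <- pos[i] * tot[best] - pos[best] * tot[i]
    pick <- if (a > 0) TRUE else if (a < 0) FALSE else {
      if (tot[i] != tot[best]) tot[i] > tot[best]
      else if (y0[i] != y0[best]) y0[i] < y0[best]
      else x0[i] < x0[best]
    }
    if (pick) best <- i
  }
  best
}

no_window_error <- function() {
  stop(structure(class = c("hotspot_no_window", "error", "condition"),
                 list(message = paste(
                   "no candidate window contains the minimum cell count;",
                   "case is unscorable"), call = NULL)))
}

hotspot_result <- function(x0, y0, side, pos, tot, method) {
  structure(list(origin_um = c(x0, y0), side_um = side,
                 n_cells = as.integer(tot), n_positive = as.integer(pos),
                 pi_percent = compute_pi(pos, tot), method = method),
            class = "hotspot")
}

#' @export
print.hotspot <- function(x, ...) {
  cat(sprintf("hotspot [%s]: origin (%.0f, %.0f) um, side %.1f um, %d cells (%d Ki67+), PI %.1f%%\n",
              x$method, x$origin_um[1], x$origin_um[2], x$side_um,
              x$n_cells, x$n_positive, x$pi_percent))
  invisible(x)
}

#' Find the Ki67 hotspot
#'
#' Candidate windows are axis-aligned squares of side `window_side_um` with
#' origins on the stride lattice, fully inside the slide. Cells are counted by
#' half-open centroid-in-window membership. Among windows holding at least
#' `min_cells` cells, the one with the maximal positive ratio wins; ties break
#' to higher cell count, then smaller y origin, then smaller x origin.
#'
#' @param cells cell table (already mask-filtered if a mask applies); any
#'   data.frame with x_um, y_um, ki67_class.
#' @param params a [search_params()].
#' @param extent_um slide extent c(width, height) in um.
#' @param mask optional `tumour_mask`: if supplied, cells are filtered through
#'   it first (convenience; equivalent to calling [filter_cells_by_mask()]).
#' @param method tag recorded on the result (e.g. "vds", "rule").
#' @return object of class `hotspot`.
#' @export
find_hotspot <- function(cells, params = search_params(),
                         extent_um = attr(cells, "extent_um"),
                         mask = NULL, method = "rule") {
  if (!is.null(mask)) cells <- filter_cells_by_mask(cells, mask)
  side <- params$window_side_um; st <- params$stride_um
  if (side > extent_um[1] || side > extent_um[2]) {
    config_error("hotspot window exceeds the slide extent")
  }
  nkx <- floor((extent_um[1] - side) / st) + 1L
  nky <- floor((extent_um[2] - side) / st) + 1L
  wc <- window_counts(cells$x_um, cells$y_um,
                      cells$ki67_class == "positive", side, st, nkx, nky)
  elig <- which(wc$total >= params$min_cells)
  if (!length(elig)) no_window_error()
  ky <- (elig - 1L) %% nky          # column-major: rows are y-origins
  kx <- (elig - 1L) %/% nky
  x0 <- kx * st; y0 <- ky * st
  i <- select_best_window(wc$positive[elig], wc$total[elig], x0, y0)
  hotspot_result(x0[i], y0[i], side, wc$positive[elig][i], wc$total[elig][i],
                 method)
}

#' Brute-force hotspot search (definitional oracle)
#'
#' Direct O(candidates x cells) enumeration of the same candidate lattice with
#' per-cell comparisons, identical eligibility and tie-break rules. Intended
#' for small instances and as the correctness oracle for [find_hotspot()].
#'
#' @inheritParams find_hotspot
#' @return object of class `hotspot`.
#' @export
brute_force_hotspot <- function(cells, params = search_params(),
                                extent_um = attr(cells, "extent_um"),
                                mask = NULL, method = "rule") {
  if (!is.null(mask)) cells <- filter_cells_by_mask(cells, mask)
  side <- params$window_side_um; st <- params$stride_um
  if (side > extent_um[1] || side > extent_um[2]) {
    config_error("hotspot window exceeds the slide extent")
  }
  nkx <- floor((extent_um[1] - side) / st) + 1L
  nky <- floor((extent_um[2] - side) / st) + 1L
  pos <- cells$ki67_class == "positive"
  out <- list(pos = integer(0), tot = integer(0), x0 = numeric(0),
              y0 = numeric(0))
  for (ky in seq_len(nky) - 1L) {
    yo <- ky * st
    iny <- cells$y_um >= yo & cells$y_um < yo + side
    for (kx in seq_len(nkx) - 1L) {
      xo <- kx * st
      inw <- iny & cells$x_um >= xo & cells$x_um < xo + side
      n <- sum(inw)
      if (n >= params$min_cells) {
        out$pos <- c(out$pos, sum(pos & inw)); out$tot <- c(out$tot, n)
        out$x0 <- c(out$x0, xo); out$y0 <- c(out$y0, yo)
      }
    }
  }
  if (!length(out$tot)) no_window_error()
  i <- select_best_window(out$pos, out$tot, out$x0, out$y0)
  hotspot_result(out$x0[i], out$y0[i], side, out$pos[i], out$tot[i], method)
}
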