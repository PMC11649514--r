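# Plain-matrix polygon utilities used by the generator and the masking layer.
# Coordinates are in micrometres, origin at the top-left pixel corner,
# x rightward, y downward. Pixel (row i, col j) has its centre at
# ((j - 0.5) * res, (i - 0.5) * res).

#' Signed area of a simple polygon (shoelace formula)
#'
#' @param poly two-column matrix of vertices (x, y); the ring may be open or
#'   explicitly closed.
#' @return Positive area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- close_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

close_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (!isTRUE(all.equal(poly[1, ], poly[nrow(poly), ], check.attributes = FALSE))) {
    poly <- rbind(poly, poly[1, ])
  }
  poly
}

#' Vectorised point-in-polygon test
#'
#' Even-odd (ray casting) rule; points exactly on the boundary are not
#' guaranteed either way and callers that need a guarantee use
#' [points_in_polygon_margin()].
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- close_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xin <- (x[j] - x[i]) * (py[crosses] - y[i]) / (y[j] - y[i]) + x[i]
      flip <- px[crosses] < xin
      inside[crosses] <- xor(inside[crosses], flip)
    }
    j <- i
  }
  inside
}

#' Minimum distance from points to a polygon boundary
#'
#' @inheritParams point_in_polygon
#' @return numeric vector of distances (always >= 0, irrespective of side).
#' @export
dist_to_polygon_boundary <- function(px, py, poly) {
  poly <- close_ring(poly)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(poly) - 1L)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[i + 1, 1]; y2 <- poly[i + 1, 2]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dd <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
      dd <- (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Points strictly inside a polygon with a safety margin
#'
#' @inheritParams point_in_polygon
#' @param margin minimum distance to the boundary (same units as coordinates).
#' @return logical vector: inside and at least `margin` from every edge.
#' @export
points_in_polygon_margin <- function(px, py, poly, margin = 0) {
  ok <- point_in_polygon(px, py, poly)
  if (margin > 0 && any(ok)) {
    ok[ok] <- dist_to_polygon_boundary(px[ok], py[ok], poly) >= margin
  }
  ok
}

#' Rasterise a simple polygon onto a pixel grid
#'
#' Scanline even-odd fill; a pixel belongs to the polygon iff its centre does.
#'
#' @param poly two-column vertex matrix in micrometres.
#' @param dims integer c(n_rows, n_cols) of the target raster.
#' @param res resolution in micrometres per pixel.
#' @return logical matrix of dim `dims`.
#' @export
rasterize_polygon <- function(poly, dims, res) {
  poly <- close_ring(poly)
  h <- dims[1]; w <- dims[2]
  out <- matrix(FALSE, h, w)
  ycent <- (seq_len(h) - 0.5) * res
  rows_all <- integer(0); xs_all <- numeric(0)
  for (i in seq_len(nrow(poly) - 1L)) {
    y1 <- poly[i, 2]; y2 <- poly[i + 1, 2]
    if (y1 == y2) next
    x1 <- poly[i, 1]; x2 <- poly[i + 1, 1]
    ylo <- min(y1, y2); yhi <- max(y1, y2)
    # half-open [ylo, yhi): each scanline crossing a shared vertex counted once
    r1 <- max(1L, ceiling(ylo / res + 0.5))
    r2 <- min(h, ceiling(yhi / res + 0.5) - 1L)
    if (r1 > r2) next
    rr <- r1:r2
    xc <- x1 + (ycent[rr] - y1) * (x2 - x1) / (y2 - y1)
    rows_all <- c(rows_all, rr)
    xs_all <- c(xs_all, xc)
  }
  if (!length(rows_all)) return(out)
  ord <- order(rows_all, xs_all)
  rows_all <- rows_all[ord]; xs_all <- xs_all[ord]
  # difference-array fill per row, then cumulative sum across columns
  starts <- xs_all[seq(1, length(xs_all), by = 2)]
  ends <- xs_all[seq(2, length(xs_all), by = 2)]
  rset <- rows_all[seq(1, length(rows_all), by = 2)]
  c1 <- pmax(1L, floor(starts / res + 0.5) + 1L)
  c2 <- pmin(w, ceiling(ends / res + 0.5) - 1L)
  keep <- c1 <= c2
  if (!any(keep)) return(out)
  diffm <- matrix(0L, h, w + 1L)
  idx1 <- cbind(rset[keep], c1[keep])
  idx2 <- cbind(rset[keep], c2[keep] + 1L)
  # aggregate duplicates (a row can be hit by several span pairs)
  for (k in seq_len(nrow(idx1))) {
    diffm[idx1[k, 1], idx1[k, 2]] <- diffm[idx1[k, 1], idx1[k, 2]] + 1L
    diffm[idx2[k, 1], idx2[k, 2]] <- diffm[idx2[k, 1], idx2[k, 2]] - 1L
  }
  filled <- t(apply(diffm, 1, cumsum))[, seq_len(w), drop = FALSE]
  out[] <- filled > 0L
  out
}

#' Rasterise a set of regions, selecting classes
#'
#' @param regions a `region_set` (see [generate_regions()]).
#' @param dims integer c(n_rows, n_cols).
#' @param res micrometres per pixel.
#' @param classes region classes to include.
#' @return logical matrix: union of the rasterised polygons.
#' @export
rasterize_regions <- function(regions, dims, res,
                              classes = c("invasive_tumour", "benign_epithelium",
                                          "carcinoma_in_situ")) {
  out <- matrix(FALSE, dims[1], dims[2])
  for (rg in regions) {
    if (rg$region_class %in% classes) {
      out <- out | rasterize_polygon(rg$polygon, dims, res)
    }
  }
  out
}

# Raster-based intersection area of two polygons (test oracle helper).
#' Approximate intersection area of two polygons by rasterisation
#'
#' @param a,b two-column vertex matrices (micrometres).
#' @param res grid resolution for the check.
#' @return area in square micrometres of the pixelwise intersection.
#' @export
polygon_intersection_area <- function(a, b, res = 2) {
  xr <- range(c(a[, 1], b[, 1])); yr <- range(c(a[, 2], b[, 2]))
  # shift into a common positive frame
  a2 <- cbind(a[, 1] - xr[1], a[, 2] - yr[1])
  b2 <- cbind(b[, 1] - xr[1], b[, 2] - yr[1])
  dims <- c(ceiling(diff(yr) / res) + 1L, ceiling(diff(xr) / res) + 1L)
  ra <- rasterize_polygon(a2, dims, res)
  rb <- rasterize_polygon(b2, dims, res)
  sum(ra & rb) * res^2
}
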