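# Synthetic slide-pair generator. Each case is a Ki67-stained section plus a
# CK8/18-stained serial section related by a small rigid transform, with
# per-nucleus vector ground truth (centroid, size, Ki67 class, region).

derive_seed <- function(seed, key) {
  # deterministic sub-stream seed; stays exact in double arithmetic and < 2^31
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 7 + 1)) %% 65521
  as.integer((as.numeric(seed) %% 20771) * 65537 + h * 31 + 12345) %% 2147483629L
}

config_error <- function(msg) {
  stop(structure(class = c("ki67_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Specification of a synthetic slide case
#'
#' Physical extent, nucleus density, the planted Ki67-positivity field
#' (Gaussian bump on a uniform baseline), distractor-region counts, and the
#' serial-section transform. Defaults are the study conditions: 4 x 4 mm at
#' 1 um/px, 1400 invasive nuclei per mm^2 (a 0.5 mm^2 hotspot window then holds
#' ~700 cells, the scale of published DIA hotspot counts), baseline positivity
#' 0.15 rising to 0.6 at the planted hotspot.
#'
#' @param width_um,height_um slide extent in micrometres; must admit at least
#'   one full hotspot window (side sqrt(0.5) mm = 707.107 um).
#' @param resolution_um_per_px raster resolution.
#' @param tumour_density_per_mm2 expected invasive-tumour nuclei per mm^2.
#' @param baseline_positivity,hotspot_peak_positivity Ki67-positive fractions
#'   away from / at the hotspot centre; baseline <= peak required.
#' @param hotspot_center_um length-2 (x, y) of the planted hotspot centre.
#' @param hotspot_radius_um scale of the Gaussian positivity bump.
#' @param benign_region_count,insitu_region_count distractor region counts.
#' @param insitu_positivity Ki67-positive fraction in carcinoma-in-situ
#'   regions (deliberately high by default, so masking - not luck - must
#'   exclude them).
#' @param benign_positivity low fixed positivity of benign epithelium.
#' @param invasive_fraction approximate fraction of the slide covered by the
#'   invasive region (band under a smooth random curve).
#' @param serial_shift_um,serial_rotation_deg rigid transform of the CK
#'   section relative to the Ki67 section (about the image centre).
#' @param serial_mode `"serial"` or `"non_serial"`; the latter regenerates the
#'   CK layout from a different seed with a markedly smaller invasive
#'   cross-section, so no rigid transform aligns the sections.
#' @param nucleus_diameter_um range of nucleus diameters (uniform).
#' @param ck_jitter_um vertex jitter applied to CK region outlines (boundary
#'   roughness of the serial section).
#' @param seed integer; every stochastic step derives its stream from it.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(width_um = 4000, height_um = 4000,
                       resolution_um_per_px = 1,
                       tumour_density_per_mm2 = 1400,
                       baseline_positivity = 0.15,
                       hotspot_center_um = c(width_um * 0.5, height_um * 0.8),
                       hotspot_peak_positivity = 0.6,
                       hotspot_radius_um = 400,
                       benign_region_count = 2,
                       insitu_region_count = 1,
                       insitu_positivity = 0.6,
                       benign_positivity = 0.05,
                       invasive_fraction = 0.4,
                       serial_shift_um = c(60, -40),
                       serial_rotation_deg = 1,
                       serial_mode = c("serial", "non_serial"),
                       nucleus_diameter_um = c(6, 10),
                       ck_jitter_um = 3,
                       seed = 1L) {
  serial_mode <- match.arg(serial_mode)
  side <- hotspot_window_side()
  if (resolution_um_per_px <= 0) config_error("resolution must be positive")
  if (width_um < side || height_um < side) {
    config_error("slide extent cannot contain one full hotspot window (707.107 um)")
  }
  if (baseline_positivity < 0 || hotspot_peak_positivity > 1 ||
      baseline_positivity > hotspot_peak_positivity) {
    config_error("need 0 <= baseline_positivity <= hotspot_peak_positivity <= 1")
  }
  if (benign_region_count < 0 || insitu_region_count < 0) {
    config_error("region counts must be non-negative")
  }
  structure(list(
    width_um = width_um, height_um = height_um,
    resolution_um_per_px = resolution_um_per_px,
    tumour_density_per_mm2 = tumour_density_per_mm2,
    baseline_positivity = baseline_positivity,
    hotspot_center_um = as.numeric(hotspot_center_um),
    hotspot_peak_positivity = hotspot_peak_positivity,
    hotspot_radius_um = hotspot_radius_um,
    benign_region_count = as.integer(benign_region_count),
    insitu_region_count = as.integer(insitu_region_count),
    insitu_positivity = insitu_positivity,
    benign_positivity = benign_positivity,
    invasive_fraction = invasive_fraction,
    serial_shift_um = as.numeric(serial_shift_um),
    serial_rotation_deg = serial_rotation_deg,
    serial_mode = serial_mode,
    nucleus_diameter_um = as.numeric(nucleus_diameter_um),
    ck_jitter_um = ck_jitter_um,
    seed = as.integer(seed)), class = "slide_spec")
}

#' Side of the hotspot window in micrometres
#' @param area_mm2 window area (default 0.5 mm^2).
#' @return sqrt(area) in micrometres (707.107 for the default).
#' @export
hotspot_window_side <- function(area_mm2 = 0.5) sqrt(area_mm2) * 1000

# smooth random invasive-front curve f(x): depth of the stroma/invasive
# boundary (y downward); integer harmonics keep the mean fraction exact
invasive_front <- function(spec, n = 81) {
  W <- spec$width_um; H <- spec$height_um
  x <- seq(0, W, length.out = n)
  a <- 0.08 * H
  k1 <- sample(1:2, 1); k2 <- sample(3:5, 1)
  ph <- runif(2, 0, 2 * pi)
  f <- H * (1 - spec$invasive_fraction) +
    0.6 * a * sin(2 * pi * k1 * x / W + ph[1]) +
    0.4 * a * sin(2 * pi * k2 * x / W + ph[2])
  f <- pmin(pmax(f, 0.05 * H), 0.95 * H)
  list(x = x, f = f)
}

#' Generate the region layout of a synthetic case
#'
#' One invasive-tumour region (a band under a smooth random front, anchored on
#' the bottom slide edge) that fully contains the hotspot window; the requested
#' numbers of benign-epithelium and carcinoma-in-situ regions as half-ellipse
#' notches on the top edge; and one explicit stroma region (the complement).
#' All regions are simple polygons, pairwise disjoint, union = slide.
#'
#' @param spec a [slide_spec()].
#' @param seed optional integer overriding the spec-derived stream.
#' @param require_hotspot_window check that the window centred at
#'   `hotspot_center_um` fits inside the invasive region (default TRUE).
#' @return object of class `region_set`: list of regions, each
#'   `list(polygon = <n x 2 matrix, um>, region_class = <chr>)`.
#' @export
generate_regions <- function(spec, seed = NULL,
                             require_hotspot_window = TRUE) {
  set.seed(if (is.null(seed)) derive_seed(spec$seed, "regions") else seed)
  W <- spec$width_um; H <- spec$height_um
  side <- hotspot_window_side()
  fr <- invasive_front(spec)
  if (require_hotspot_window) {
    cx <- spec$hotspot_center_um[1]; cy <- spec$hotspot_center_um[2]
    x0 <- cx - side / 2; x1 <- cx + side / 2
    y0 <- cy - side / 2; y1 <- cy + side / 2
    if (x0 < 0 || x1 > W || y0 < 0 || y1 > H) {
      config_error("hotspot window exceeds the slide extent")
    }
    fmax_win <- max(fr$f[fr$x >= x0 - (fr$x[2] - fr$x[1]) &
                         fr$x <= x1 + (fr$x[2] - fr$x[1])])
    if (fmax_win >= y0) {
      config_error("hotspot window is not containable in the invasive region")
    }
  }
  invasive <- rbind(cbind(fr$x, fr$f), c(W, H), c(0, H))
  regions <- list(list(polygon = invasive, region_class = "invasive_tumour"))

  k <- spec$benign_region_count + spec$insitu_region_count
  notches <- list()
  if (k > 0) {
    span0 <- 0.08 * W; span1 <- W - 0.08 * W
    slot <- (span1 - span0) / k
    fmin <- min(fr$f)
    rymax <- min(0.45 * fmin - 20, 240)
    if (rymax < 50 || slot < 260) {
      config_error("slide too small for the requested distractor regions")
    }
    classes <- sample(c(rep("benign_epithelium", spec$benign_region_count),
                        rep("carcinoma_in_situ", spec$insitu_region_count)))
    for (i in seq_len(k)) {
      cx <- span0 + (i - 1) * slot + runif(1, 0.35, 0.65) * slot
      rx <- runif(1, min(110, 0.25 * slot), min(0.3 * slot, 280))
      ry <- runif(1, min(60, rymax * 0.6), rymax)
      t <- seq(pi, 0, length.out = 25)
      arc <- cbind(cx + rx * cos(t), ry * sin(t))
      arc[1, 2] <- 0; arc[nrow(arc), 2] <- 0
      notches[[i]] <- list(polygon = arc, region_class = classes[i])
    }
  }
  regions <- c(regions, notches)

  # stroma: top area minus the notches, traversed along the top edge with a
  # detour around each notch arc
  top_path <- matrix(c(0, 0), ncol = 2)
  if (k > 0) {
    ord <- order(vapply(notches, function(n) n$polygon[1, 1], numeric(1)))
    for (i in ord) top_path <- rbind(top_path, notches[[i]]$polygon)
  }
  top_path <- rbind(top_path, c(W, 0))
  stroma <- rbind(top_path, cbind(rev(fr$x), rev(fr$f)))
  regions <- c(regions, list(list(polygon = stroma, region_class = "stroma")))
  structure(regions, class = "region_set",
            extent_um = c(W, H))
}

#' Sample ground-truth cells into the regions
#'
#' Hard-core placement on a jittered grid: pitch 1/sqrt(density), per-point
#' uniform jitter leaving a minimum centre separation of at least the maximum
#' nucleus diameter (rendered discs never overlap). Each cell's centroid must
#' lie inside its region with a margin of one nucleus radius (the whole
#' nucleus fits inside the region). Invasive cells are Ki67-positive with
#' probability p(x, y) = baseline + (peak - baseline) exp(-d^2 / (2 radius^2)),
#' d = distance to the planted hotspot centre; benign cells at the low fixed
#' benign positivity; in-situ cells at `insitu_positivity`; stroma holds no
#' cells.
#'
#' @param spec a [slide_spec()].
#' @param regions result of [generate_regions()].
#' @param seed optional integer overriding the spec-derived stream.
#' @return data.frame of class `gt_cells` with columns id, x_um, y_um,
#'   diameter_um, ki67_class, region_class; attributes `extent_um` and
#'   `resolution_um_per_px`.
#' @export
sample_cells <- function(spec, regions, seed = NULL) {
  set.seed(if (is.null(seed)) derive_seed(spec$seed, "cells") else seed)
  W <- spec$width_um; H <- spec$height_um
  dmax <- max(spec$nucleus_diameter_um)
  g <- sqrt(1e6 / spec$tumour_density_per_mm2)
  if (g <= dmax * 1.02) {
    stop(structure(class = c("ki67_generation_error", "error", "condition"),
                   list(message = paste0(
                     "requested density (", spec$tumour_density_per_mm2,
                     "/mm^2) is incompatible with the hard-core separation of ",
                     dmax, " um"), call = NULL)))
  }
  jit <- 0.475 * (g - dmax)
  ox <- runif(1, 0, g); oy <- runif(1, 0, g)
  gx <- seq(ox - g, W + g, by = g)
  gy <- seq(oy - g, H + g, by = g)
  pts <- expand.grid(x = gx, y = gy)
  n <- nrow(pts)
  x <- pts$x + runif(n, -jit, jit)
  y <- pts$y + runif(n, -jit, jit)
  diam <- runif(n, spec$nucleus_diameter_um[1], spec$nucleus_diameter_um[2])
  inb <- x > 0 & x < W & y > 0 & y < H
  x <- x[inb]; y <- y[inb]; diam <- diam[inb]

  cls <- rep(NA_character_, length(x))
  for (rg in regions) {
    if (rg$region_class == "stroma") next
    bb <- apply(rg$polygon, 2, range)
    cand <- which(is.na(cls) &
                  x >= bb[1, 1] & x <= bb[2, 1] &
                  y >= bb[1, 2] & y <= bb[2, 2])
    if (!length(cand)) next
    ok <- points_in_polygon_margin(x[cand], y[cand], rg$polygon,
                                   margin = 0)
    cand <- cand[ok]
    if (!length(cand)) next
    deep <- dist_to_polygon_boundary(x[cand], y[cand], rg$polygon) >=
      diam[cand] / 2 + 0.5
    cls[cand[deep]] <- rg$region_class
  }
  keep <- !is.na(cls)
  x <- x[keep]; y <- y[keep]; diam <- diam[keep]; cls <- cls[keep]

  d2 <- (x - spec$hotspot_center_um[1])^2 + (y - spec$hotspot_center_um[2])^2
  p <- spec$baseline_positivity +
    (spec$hotspot_peak_positivity - spec$baseline_positivity) *
    exp(-d2 / (2 * spec$hotspot_radius_um^2))
  p[cls == "benign_epithelium"] <- spec$benign_positivity
  p[cls == "carcinoma_in_situ"] <- spec$insitu_positivity
  pos <- runif(length(x)) < p

  out <- data.frame(id = seq_along(x), x_um = x, y_um = y,
                    diameter_um = diam,
                    ki67_class = ifelse(pos, "positive", "negative"),
                    region_class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "extent_um") <- c(W, H)
  attr(out, "resolution_um_per_px") <- spec$resolution_um_per_px
  class(out) <- c("gt_cells", "data.frame")
  out
}

#' Planted positivity probability at given coordinates
#'
#' The generator's Gaussian-bump field for invasive cells; used by tests and
#' by the planted-hotspot recovery check.
#'
#' @param spec a [slide_spec()].
#' @param x,y coordinates in micrometres.
#' @return numeric vector of Bernoulli probabilities.
#' @export
positivity_field <- function(spec, x, y) {
  d2 <- (x - spec$hotspot_center_um[1])^2 + (y - spec$hotspot_center_um[2])^2
  spec$baseline_positivity +
    (spec$hotspot_peak_positivity - spec$baseline_positivity) *
    exp(-d2 / (2 * spec$hotspot_radius_um^2))
}
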