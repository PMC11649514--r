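# Forward rendering of synthetic sections through the Beer-Lambert model.

#' Construct a slide image container
#' @param raster numeric array (rows, cols, 3), 8-bit intensities 0..255.
#' @param resolution_um_per_px micrometres per pixel.
#' @return object of class `slide_image`.
#' @export
slide_image <- function(raster, resolution_um_per_px) {
  structure(list(raster = raster, resolution_um_per_px = resolution_um_per_px),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("slide_image: %d x %d px at %.3g um/px (%.2f x %.2f mm)\n",
              d[2], d[1], x$resolution_um_per_px,
              d[2] * x$resolution_um_per_px / 1000,
              d[1] * x$resolution_um_per_px / 1000))
  invisible(x)
}

image_dims <- function(spec) {
  c(round(spec$height_um / spec$resolution_um_per_px),
    round(spec$width_um / spec$resolution_um_per_px))
}

# low-frequency background texture, clamped so it never crosses the
# detector's nuclear threshold (amplitude << 0.05 OD)
background_od <- function(dims, mean_od, sd_od, clamp_hi, block = 8L) {
  ch <- ceiling(dims[1] / block); cw <- ceiling(dims[2] / block)
  coarse <- matrix(stats::rnorm(ch * cw), ch, cw)
  up <- kronecker(coarse, matrix(1, block, block))[seq_len(dims[1]),
                                                   seq_len(dims[2]), drop = FALSE]
  up <- EBImage::gblur(up, sigma = block / 2)
  pmin(pmax(mean_od + sd_od * up, 0), clamp_hi)
}

stamp_discs <- function(mat, x, y, r, value, res) {
  h <- nrow(mat); w <- ncol(mat)
  for (i in seq_along(x)) {
    jlo <- max(1L, as.integer(ceiling((x[i] - r[i]) / res + 0.5 - 1e-9)))
    jhi <- min(w, as.integer(floor((x[i] + r[i]) / res + 0.5 + 1e-9)))
    ilo <- max(1L, as.integer(ceiling((y[i] - r[i]) / res + 0.5 - 1e-9)))
    ihi <- min(h, as.integer(floor((y[i] + r[i]) / res + 0.5 + 1e-9)))
    if (jlo > jhi || ilo > ihi) next
    xc <- (jlo:jhi - 0.5) * res - x[i]
    yc <- (ilo:ihi - 0.5) * res - y[i]
    disc <- outer(yc^2, xc^2, "+") <= r[i]^2
    blk <- mat[ilo:ihi, jlo:jhi, drop = FALSE]
    blk[disc] <- pmax(blk[disc], value[i])
    mat[ilo:ihi, jlo:jhi] <- blk
  }
  mat
}

#' Render the Ki67 section
#'
#' Each nucleus is a flat disc of its ground-truth diameter. Negative nuclei
#' carry haematoxylin OD only; positive nuclei carry haematoxylin plus a DAB
#' OD well above the classifier's default positivity threshold ("any intensity
#' of brown nuclear staining" scores positive, so the rendered DAB signal is
#' unambiguous). A low-frequency background texture (amplitude < 0.05 OD)
#' emulates faint counterstain wash without creating spurious blobs at the
#' default detection threshold.
#'
#' @param cells ground-truth cells from [sample_cells()].
#' @param regions region layout (kept for interface symmetry; the Ki67 render
#'   is fully determined by the cells).
#' @param spec the [slide_spec()].
#' @param seed optional integer overriding the spec-derived stream.
#' @param stains the [stain_matrix()] used for Beer-Lambert composition.
#' @return a [slide_image()].
#' @export
render_ki67_image <- function(cells, regions, spec, seed = NULL,
                              stains = stain_matrix()) {
  set.seed(if (is.null(seed)) derive_seed(spec$seed, "render_ki67") else seed)
  dims <- image_dims(spec)
  res <- spec$resolution_um_per_px
  h_od <- background_od(dims, mean_od = 0.02, sd_od = 0.008, clamp_hi = 0.045)
  dab_od <- background_od(dims, mean_od = 0.004, sd_od = 0.002, clamp_hi = 0.02)
  if (nrow(cells) > 0) {
    pos <- cells$ki67_class == "positive"
    n <- nrow(cells)
    h_cell <- ifelse(pos, stats::runif(n, 0.45, 0.65), stats::runif(n, 0.65, 0.90))
    d_cell <- ifelse(pos, stats::runif(n, 0.50, 0.80), 0)
    r <- cells$diameter_um / 2
    h_od <- stamp_discs(h_od, cells$x_um, cells$y_um, r, h_cell, res)
    dab_od <- stamp_discs(dab_od, cells$x_um, cells$y_um, r, d_cell, res)
  }
  slide_image(forward_render(h_od, dab_od, stains), res)
}

#' Render the CK8/18 serial section
#'
#' Epithelial regions (invasive, benign, in-situ) are filled with a DAB-like
#' membrane blush after applying the spec's rigid transform (about the image
#' centre) and a small vertex jitter (serial-section boundary roughness,
#' <= `ck_jitter_um`). In `serial_mode = "non_serial"` the layout is
#' regenerated from a different seed with the invasive cross-section area
#' scaled by U(0.45, 0.60) - a distant tissue level - so no rigid transform
#' within the registration search range aligns the sections (best IoU is
#' bounded above by the area ratio, < 0.6).
#'
#' @inheritParams render_ki67_image
#' @param render build the RGB raster (set FALSE to obtain only the CK-frame
#'   polygons and the true transform, e.g. for mask-level studies).
#' @return list: `image` (a [slide_image()] or NULL), `transform` (the true
#'   [rigid_transform()] taking Ki67-frame coordinates to CK-frame
#'   coordinates), `regions_ck` (epithelial polygons in the CK frame).
#' @export
render_ck_serial <- function(cells, regions, spec, seed = NULL,
                             stains = stain_matrix(), render = TRUE) {
  set.seed(if (is.null(seed)) derive_seed(spec$seed, "render_ck") else seed)
  res <- spec$resolution_um_per_px
  dims <- image_dims(spec)
  centre <- c(spec$width_um / 2, spec$height_um / 2)
  tr <- rigid_transform(spec$serial_shift_um[1], spec$serial_shift_um[2],
                        spec$serial_rotation_deg)
  layout <- regions
  if (spec$serial_mode == "non_serial") {
    spec2 <- spec
    spec2$seed <- derive_seed(spec$seed, "nonserial_layout")
    spec2$invasive_fraction <- spec$invasive_fraction * stats::runif(1, 0.45, 0.60)
    layout <- generate_regions(spec2, require_hotspot_window = FALSE)
  }
  epi <- Filter(function(r) r$region_class != "stroma", layout)
  regions_ck <- lapply(epi, function(rg) {
    p <- apply_rigid(rg$polygon, tr, centre)
    if (spec$ck_jitter_um > 0) {
      jx <- pmin(pmax(stats::rnorm(nrow(p), 0, spec$ck_jitter_um / 2),
                      -spec$ck_jitter_um), spec$ck_jitter_um)
      jy <- pmin(pmax(stats::rnorm(nrow(p), 0, spec$ck_jitter_um / 2),
                      -spec$ck_jitter_um), spec$ck_jitter_um)
      p <- cbind(p[, 1] + jx, p[, 2] + jy)
    }
    list(polygon = p, region_class = rg$region_class)
  })
  img <- NULL
  if (render) {
    epi_mask <- matrix(FALSE, dims[1], dims[2])
    for (rg in regions_ck) {
      epi_mask <- epi_mask | rasterize_polygon(rg$polygon, dims, res)
    }
    h_od <- background_od(dims, mean_od = 0.03, sd_od = 0.008, clamp_hi = 0.06)
    dab_od <- background_od(dims, mean_od = 0.003, sd_od = 0.002, clamp_hi = 0.02)
    blush <- pmin(pmax(0.35 + 0.03 * stats::rnorm(sum(epi_mask)), 0.25), 0.45)
    dab_od[epi_mask] <- blush
    img <- slide_image(forward_render(h_od, dab_od, stains), res)
  }
  list(image = img, transform = tr, regions_ck = regions_ck)
}

#' Generate one full synthetic case
#'
#' Regions, ground-truth cells, the Ki67 render, and the CK serial section
#' (image plus the true rigid transform). Same seed, bit-identical case.
#'
#' @param spec a [slide_spec()].
#' @param render build the RGB rasters (FALSE keeps the case vector-only,
#'   which is what mask-level method-comparison studies use).
#' @return object of class `synthetic_case`: list with spec, regions, cells,
#'   ki67_image, ck_image, ck_regions, true_serial_transform.
#' @export
simulate_case <- function(spec, render = TRUE) {
  regions <- generate_regions(spec)
  cells <- sample_cells(spec, regions)
  ki <- if (render) render_ki67_image(cells, regions, spec) else NULL
  ck <- render_ck_serial(cells, regions, spec, render = render)
  structure(list(spec = spec, regions = regions, cells = cells,
                 ki67_image = ki, ck_image = ck$image,
                 ck_regions = ck$regions_ck,
                 true_serial_transform = ck$transform),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic_case: %.1f x %.1f mm, %d cells (%.1f%% Ki67+), %s mode\n",
              x$spec$width_um / 1000, x$spec$height_um / 1000, nrow(x$cells),
              100 * mean(x$cells$ki67_class == "positive"), x$spec$serial_mode))
  invisible(x)
}
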