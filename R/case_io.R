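# On-disk representation of a synthetic case: TIFF images with resolution
# metadata, a CSV cell table, GeoJSON region polygons (um coordinates), a JSON
# spec + true-transform record, and a checksum manifest.

CELL_CSV_HEADER <- c("id", "x_um", "y_um", "diameter_um", "ki67_class",
                     "region_class")

#' Write a slide image as 8-bit RGB TIFF with resolution metadata
#'
#' The resolution (um per pixel) travels in a JSON sidecar
#' (`<path>.meta.json`): the installed TIFF writer does not expose the
#' ResolutionUnit/XResolution tags, and the sidecar round-trips exactly.
#'
#' @param image a [slide_image()].
#' @param path output file.
#' @export
write_slide_tiff <- function(image, path) {
  tiff::writeTIFF(image$raster / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(
    list(resolution_um_per_px = image$resolution_um_per_px),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RGB TIFF written by [write_slide_tiff()]
#' @param path file path.
#' @param resolution_um_per_px override; by default recovered from the TIFF
#'   resolution tags (when present) or the JSON sidecar.
#' @return a [slide_image()].
#' @export
read_slide_tiff <- function(path, resolution_um_per_px = NULL) {
  r <- tiff::readTIFF(path, info = TRUE)
  if (is.null(resolution_um_per_px)) {
    xres <- attr(r, "x.resolution")
    unit <- attr(r, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0 &&
        (is.null(unit) || identical(unit, "inch"))) {
      resolution_um_per_px <- 25400 / xres
    } else if (file.exists(paste0(path, ".meta.json"))) {
      meta <- jsonlite::read_json(paste0(path, ".meta.json"))
      resolution_um_per_px <- meta$resolution_um_per_px
    } else {
      stop("no resolution metadata found; pass resolution_um_per_px")
    }
  }
  raster <- round(r * 255)
  attributes(raster) <- list(dim = dim(r))
  slide_image(raster, resolution_um_per_px)
}

regions_to_geojson <- function(regions, path) {
  feats <- lapply(regions, function(rg) {
    ring <- close_ring(rg$polygon)
    list(type = "Feature",
         properties = list(region_class = rg$region_class),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region GeoJSON (FeatureCollection with `region_class` property)
#' @param path file path.
#' @param extent_um optional slide extent to attach.
#' @return a `region_set`.
#' @export
read_regions_geojson <- function(path, extent_um = NULL) {
  gj <- jsonlite::read_json(path)
  regions <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    list(polygon = ring, region_class = f$properties$region_class)
  })
  structure(regions, class = "region_set", extent_um = extent_um)
}

#' Write a synthetic case to a directory
#'
#' Emits ki67.tif and ck.tif (8-bit RGB, resolution tags), cells.csv with the
#' fixed header `id,x_um,y_um,diameter_um,ki67_class,region_class`,
#' regions.geojson, case.json (spec plus true serial transform) and
#' manifest.json (MD5 checksums). Rendering is deterministic from the spec, so
#' rewriting the same case reproduces identical checksums.
#'
#' @param case a [simulate_case()] result; if it was generated with
#'   `render = FALSE`, the images are rendered here (deterministically).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a named list of file checksums.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create case directory: ", dir)
  if (is.null(case$ki67_image)) {
    case$ki67_image <- render_ki67_image(case$cells, case$regions, case$spec)
  }
  if (is.null(case$ck_image)) {
    ck <- render_ck_serial(case$cells, case$regions, case$spec)
    case$ck_image <- ck$image
  }
  write_slide_tiff(case$ki67_image, file.path(dir, "ki67.tif"))
  write_slide_tiff(case$ck_image, file.path(dir, "ck.tif"))
  cells <- as.data.frame(case$cells)[, CELL_CSV_HEADER]
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE,
                   quote = FALSE)
  regions_to_geojson(case$regions, file.path(dir, "regions.geojson"))
  tr <- case$true_serial_transform
  meta <- c(unclass(case$spec),
            list(true_transform = list(dx_um = tr$dx_um, dy_um = tr$dy_um,
                                       theta_deg = tr$theta_deg)))
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("ki67.tif", "ki67.tif.meta.json", "ck.tif", "ck.tif.meta.json",
             "cells.csv", "regions.geojson", "case.json")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  jsonlite::write_json(list(files = sums), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(sums)
}

#' Read a synthetic case written by [write_case()]
#' @param dir case directory.
#' @return a `synthetic_case` (ck_regions are not round-tripped; the CK-frame
#'   layout is recoverable from the spec when needed).
#' @export
read_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"))
  tr <- rigid_transform(as.numeric(meta$true_transform$dx_um),
                        as.numeric(meta$true_transform$dy_um),
                        as.numeric(meta$true_transform$theta_deg))
  spec_args <- meta[setdiff(names(meta), "true_transform")]
  spec <- do.call(slide_spec, lapply(spec_args, function(v)
    if (is.list(v)) unlist(v) else v))
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  attr(cells, "extent_um") <- c(spec$width_um, spec$height_um)
  attr(cells, "resolution_um_per_px") <- spec$resolution_um_per_px
  class(cells) <- c("gt_cells", "data.frame")
  regions <- read_regions_geojson(file.path(dir, "regions.geojson"),
                                  extent_um = c(spec$width_um, spec$height_um))
  structure(list(spec = spec, regions = regions, cells = cells,
                 ki67_image = read_slide_tiff(file.path(dir, "ki67.tif")),
                 ck_image = read_slide_tiff(file.path(dir, "ck.tif")),
                 ck_regions = NULL, true_serial_transform = tr),
            class = "synthetic_case")
}
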