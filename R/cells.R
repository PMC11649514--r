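# Nucleus detection and Ki67 classification on the Ki67 section: stain
# deconvolution -> total nuclear OD -> smoothing at nucleus scale -> threshold
# -> distance-transform watershed split -> shape/size filter. Classification
# is a single DAB threshold on the per-nucleus mean, with an inclusive >=
# convention ("any intensity of brown nuclear staining" scores positive).

#' Nucleus detection parameters
#'
#' @param min_diameter_um,max_diameter_um admissible equivalent-diameter range;
#'   converted to an area filter [pi (min/2)^2, pi (max/2)^2].
#' @param nuclear_od_threshold threshold on the smoothed haematoxylin + DAB
#'   concentration separating nuclei from background.
#' @param dab_positive_threshold mean-DAB concentration at or above which a
#'   nucleus is Ki67-positive (low by default: any clear brown signal counts).
#' @param min_circularity minimal 4 pi A / P^2 (permissive, tolerating
#'   watershed fragment shapes).
#' @param smooth_sigma_um Gaussian smoothing scale before thresholding.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(min_diameter_um = 4.5, max_diameter_um = 13,
                             nuclear_od_threshold = 0.3,
                             dab_positive_threshold = 0.15,
                             min_circularity = 0.4,
                             smooth_sigma_um = 1) {
  stopifnot(min_diameter_um < max_diameter_um, nuclear_od_threshold > 0,
            dab_positive_threshold > 0,
            min_circularity > 0, min_circularity <= 1)
  structure(list(min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 nuclear_od_threshold = nuclear_od_threshold,
                 dab_positive_threshold = dab_positive_threshold,
                 min_circularity = min_circularity,
                 smooth_sigma_um = smooth_sigma_um),
            class = "detection_params")
}

#' Detect nuclei in a Ki67 image
#'
#' @param ki67_image a [slide_image()] (resolution metadata required).
#' @param params a [detection_params()].
#' @param stains the [stain_matrix()].
#' @return data.frame of class `cell_table`: id, x_um, y_um, area_um2,
#'   equivalent_diameter_um, mean_dab_od, mean_h_od and an unset ki67_class
#'   (filled by [classify_nuclei()]); attributes `extent_um`,
#'   `resolution_um_per_px`, `detection_params`.
#' @export
detect_nuclei <- function(ki67_image, params = detection_params(),
                          stains = stain_matrix()) {
  if (!inherits(ki67_image, "slide_image") ||
      is.null(ki67_image$resolution_um_per_px)) {
    stop("ki67_image must be a slide_image with resolution metadata")
  }
  res <- ki67_image$resolution_um_per_px
  conc <- deconvolve(rgb_to_od(ki67_image), stains)
  total <- conc$h + conc$dab
  sm <- EBImage::gblur(total, sigma = max(params$smooth_sigma_um / res, 0.3))
  bw <- sm > params$nuclear_od_threshold
  empty <- function() {
    out <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      mean_dab_od = numeric(0), mean_h_od = numeric(0),
                      ki67_class = character(0), stringsAsFactors = FALSE)
    attr(out, "extent_um") <- c(ncol(bw), nrow(bw)) * res
    attr(out, "resolution_um_per_px") <- res
    attr(out, "detection_params") <- params
    class(out) <- c("cell_table", "data.frame")
    out
  }
  if (!any(bw)) return(empty())
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  n <- max(lab)
  if (n == 0) return(empty())
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area_um2 <- shp[, "s.area"] * res^2
  perim <- shp[, "s.perimeter"] * res
  circ <- ifelse(perim > 0, 4 * pi * area_um2 / perim^2, 0)
  amin <- pi * (params$min_diameter_um / 2)^2
  amax <- pi * (params$max_diameter_um / 2)^2
  keep <- which(area_um2 >= amin & area_um2 <= amax &
                circ >= params$min_circularity)
  if (!length(keep)) return(empty())
  labv <- as.integer(lab)
  sums_d <- rowsum(conc$dab[labv > 0], labv[labv > 0])
  sums_h <- rowsum(conc$h[labv > 0], labv[labv > 0])
  npix <- tabulate(labv[labv > 0], nbins = n)
  ids <- as.integer(rownames(sums_d))
  mean_d <- mean_h <- rep(NA_real_, n)
  mean_d[ids] <- sums_d[, 1] / npix[ids]
  mean_h[ids] <- sums_h[, 1] / npix[ids]
  # EBImage centroids: m.cx along dim 1 (our y/rows), m.cy along dim 2 (x);
  # they are 0.5-based pixel centres
  out <- data.frame(id = seq_along(keep),
                    x_um = mom[keep, "m.cy"] * res,
                    y_um = mom[keep, "m.cx"] * res,
                    area_um2 = area_um2[keep],
                    equivalent_diameter_um = 2 * sqrt(area_um2[keep] / pi),
                    mean_dab_od = mean_d[keep],
                    mean_h_od = mean_h[keep],
                    ki67_class = NA_character_,
                    stringsAsFactors = FALSE)
  attr(out, "extent_um") <- c(ncol(bw), nrow(bw)) * res
  attr(out, "resolution_um_per_px") <- res
  attr(out, "detection_params") <- params
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Classify detected nuclei as Ki67-positive or -negative
#'
#' `ki67_class = "positive"` iff `mean_dab_od >= dab_positive_threshold`
#' (inclusive at the boundary).
#'
#' @param cell_table output of [detect_nuclei()].
#' @param params a [detection_params()].
#' @return the table with ki67_class filled in.
#' @export
classify_nuclei <- function(cell_table, params = detection_params()) {
  cell_table$ki67_class <- ifelse(
    cell_table$mean_dab_od >= params$dab_positive_threshold,
    "positive", "negative")
  cell_table
}

#' Detect and classify in one step
#' @inheritParams detect_nuclei
#' @return a classified `cell_table`.
#' @export
analyse_ki67_image <- function(ki67_image, params = detection_params(),
                               stains = stain_matrix()) {
  classify_nuclei(detect_nuclei(ki67_image, params, stains), params)
}

#' Match detected nuclei to ground truth
#'
#' Greedy distance-sorted one-to-one matching within `match_radius_um`;
#' reports precision, recall, F1 and the Ki67 class confusion matrix over
#' matched pairs.
#'
#' @param detected a `cell_table` (classified or not).
#' @param truth_cells ground-truth cells ([sample_cells()]).
#' @param match_radius_um maximal centroid distance for a match.
#' @return list of class `match_report`: n_detected, n_truth, n_matched,
#'   precision, recall, f1, class_accuracy (NA when classes are absent),
#'   confusion (2 x 2 matrix truth x detected), matches (data.frame of index
#'   pairs and distances).
#' @export
match_to_ground_truth <- function(detected, truth_cells, match_radius_um = 5) {
  nd <- nrow(detected); nt <- nrow(truth_cells)
  pairs <- NULL
  if (nd > 0 && nt > 0) {
    # candidate pairs within radius via coarse bucketing
    b <- match_radius_um
    key <- function(x, y) paste(floor(x / b), floor(y / b))
    tk <- split(seq_len(nt), key(truth_cells$x_um, truth_cells$y_um))
    cand_i <- integer(0); cand_j <- integer(0)
    for (i in seq_len(nd)) {
      cx <- floor(detected$x_um[i] / b); cy <- floor(detected$y_um[i] / b)
      for (ox in -1:1) for (oy in -1:1) {
        js <- tk[[paste(cx + ox, cy + oy)]]
        if (!is.null(js)) { cand_i <- c(cand_i, rep(i, length(js)))
                            cand_j <- c(cand_j, js) }
      }
    }
    if (length(cand_i)) {
      d <- sqrt((detected$x_um[cand_i] - truth_cells$x_um[cand_j])^2 +
                (detected$y_um[cand_i] - truth_cells$y_um[cand_j])^2)
      ok <- d <= match_radius_um
      cand_i <- cand_i[ok]; cand_j <- cand_j[ok]; d <- d[ok]
      ord <- order(d)
      used_d <- logical(nd); used_t <- logical(nt)
      sel <- logical(length(ord))
      for (k in ord) {
        if (!used_d[cand_i[k]] && !used_t[cand_j[k]]) {
          used_d[cand_i[k]] <- TRUE; used_t[cand_j[k]] <- TRUE
          sel[k] <- TRUE
        }
      }
      pairs <- data.frame(detected = cand_i[sel], truth = cand_j[sel],
                          dist_um = d[sel])
    }
  }
  nm <- if (is.null(pairs)) 0L else nrow(pairs)
  precision <- if (nd > 0) nm / nd else NA_real_
  recall <- if (nt > 0) nm / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(truth = c("negative", "positive"),
                                      detected = c("negative", "positive")))
  class_accuracy <- NA_real_
  if (nm > 0 && !all(is.na(detected$ki67_class))) {
    tc <- truth_cells$ki67_class[pairs$truth]
    dc <- detected$ki67_class[pairs$detected]
    for (a in c("negative", "positive")) for (b in c("negative", "positive")) {
      confusion[a, b] <- sum(tc == a & dc == b)
    }
    class_accuracy <- mean(tc == dc)
  }
  structure(list(n_detected = nd, n_truth = nt, n_matched = nm,
                 precision = precision, recall = recall, f1 = f1,
                 class_accuracy = class_accuracy, confusion = confusion,
                 matches = pairs),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: %d/%d matched | precision %.3f recall %.3f F1 %.3f | class acc %.3f\n",
              x$n_matched, x$n_truth, x$precision, x$recall, x$f1,
              x$class_accuracy))
  invisible(x)
}
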