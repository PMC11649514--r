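# Invasive-tumour masking in two arms: "vds" (virtual dual staining - the CK
# serial section is rigidly registered onto the Ki67 section and its epithelial
# mask, minus manually supplied exclusion regions, restricts the analysis) and
# "rule" (region-based masking on the Ki67 section itself; the default stand-in
# for a trained tumour detector is the ground-truth region set behind the same
# interface). VDS can fail for misalignment; rule mode never does.

#' Rigid transform (about the image centre)
#' @param dx_um,dy_um translation in micrometres.
#' @param theta_deg rotation in degrees, |theta| <= 180.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx_um = 0, dy_um = 0, theta_deg = 0) {
  stopifnot(is.finite(dx_um), is.finite(dy_um), is.finite(theta_deg),
            abs(theta_deg) <= 180)
  structure(list(dx_um = dx_um, dy_um = dy_um, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param xy n x 2 matrix of (x, y) in micrometres.
#' @param transform a [rigid_transform()].
#' @param center_um rotation centre (x, y).
#' @return transformed n x 2 matrix: R(theta) (p - c) + c + t.
#' @export
apply_rigid <- function(xy, transform, center_um) {
  th <- transform$theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sw <- sweep(as.matrix(xy), 2, center_um)
  out <- sw %*% t(R)
  cbind(out[, 1] + center_um[1] + transform$dx_um,
        out[, 2] + center_um[2] + transform$dy_um)
}

# nearest-neighbour resampling of a logical mask under p -> R(theta)(p-c)+c+t
# (i.e. out(p) = in(T(p)); T maps the output frame into the input frame)
resample_mask <- function(mask, transform, res, center_um = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(center_um)) center_um <- c(w * res / 2, h * res / 2)
  th <- transform$theta_deg * pi / 180
  px <- (seq_len(w) - 0.5) * res - center_um[1]
  py <- (seq_len(h) - 0.5) * res - center_um[2]
  X <- matrix(px, h, w, byrow = TRUE); Y <- matrix(py, h, w)
  qx <- cos(th) * X - sin(th) * Y + center_um[1] + transform$dx_um
  qy <- sin(th) * X + cos(th) * Y + center_um[2] + transform$dy_um
  j <- round(qx / res + 0.5); i <- round(qy / res + 0.5)
  ok <- i >= 1 & i <= h & j >= 1 & j <= w
  out <- matrix(FALSE, h, w)
  out[ok] <- mask[cbind(i[ok], j[ok])]
  out
}

downsample_any <- function(mask, f) {
  if (f <= 1) return(mask)
  hh <- ceiling(nrow(mask) / f); ww <- ceiling(ncol(mask) / f)
  pad <- matrix(FALSE, hh * f, ww * f)
  pad[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  out <- matrix(FALSE, hh, ww)
  for (a in seq_len(f)) for (b in seq_len(f)) {
    out <- out | pad[seq(a, hh * f, by = f), seq(b, ww * f, by = f)]
  }
  out
}

# circular cross-correlation via FFT: C[u] = sum_x A[x] B[x - u]; the best
# shift is searched over dy in cy +/- hw[1], dx in cx +/- hw[2] (pixels), with
# parabolic sub-pixel interpolation (valid because the masks are blurred)
xcorr_best_shift <- function(FB, FA, P, center_px = c(0, 0), hw) {
  C <- Re(stats::fft(FA * Conj(FB), inverse = TRUE)) / length(FA)
  wrap <- function(v, n) ((v %% n) + n) %% n + 1
  dys <- seq(center_px[1] - hw[1], center_px[1] + hw[1])
  dxs <- seq(center_px[2] - hw[2], center_px[2] + hw[2])
  sub <- C[wrap(dys, P[1]), wrap(dxs, P[2]), drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  dy <- dys[k[1]]; dx <- dxs[k[2]]
  para <- function(sm1, s0, sp1) {
    den <- sm1 - 2 * s0 + sp1
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (sm1 - sp1) / den))
  }
  sy <- para(C[wrap(dy - 1, P[1]), wrap(dx, P[2])], sub[k[1], k[2]],
             C[wrap(dy + 1, P[1]), wrap(dx, P[2])])
  sx <- para(C[wrap(dy, P[1]), wrap(dx - 1, P[2])], sub[k[1], k[2]],
             C[wrap(dy, P[1]), wrap(dx + 1, P[2])])
  list(score = sub[k[1], k[2]], dy = dy + sy, dx = dx + sx,
       dy_int = dy, dx_int = dx)
}

# smallest highly composite (2^a 3^b 5^c) size >= n, for fast mixed-radix FFTs
good_fft_size <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

#' Rigid registration of two binary foreground masks
#'
#' Exhaustive translation search (FFT cross-correlation, restricted to
#' +/- `max_shift_um`) over a rotation grid (+/- `rot_range_deg`), followed by
#' a finer rotation pass and parabolic sub-pixel interpolation in both shift
#' and angle. The alignment score is the foreground IoU after applying the
#' estimated transform; registration fails below `fail_threshold` (default
#' 0.6) or on blank input.
#'
#' @param fixed,moving logical matrices (the Ki67-section and CK-section
#'   foregrounds) of equal dimension.
#' @param res_um resolution of the masks in micrometres per pixel.
#' @param max_shift_um,rot_range_deg search ranges.
#' @param fail_threshold IoU below which the result is flagged failed.
#' @return object of class `registration_result`: `transform` (the estimated
#'   [rigid_transform()] taking fixed-frame coordinates to moving-frame
#'   coordinates), `alignment_score` (IoU), `status` ("success"/"failed").
#' @export
register_masks <- function(fixed, moving, res_um, max_shift_um = 500,
                           rot_range_deg = 5, fail_threshold = 0.6,
                           blur_um = 10) {
  fail <- function(score) structure(
    list(transform = rigid_transform(0, 0, 0), alignment_score = score,
         status = "failed", fail_threshold = fail_threshold),
    class = "registration_result")
  if (!sum(fixed) || !sum(moving)) return(fail(0))
  stopifnot(identical(dim(fixed), dim(moving)))
  # boundary map of a mask: 4-neighbour morphological gradient, with the
  # artificial frame-border edges removed (solid tumour regions carry almost
  # no translation signal along their long axis and are clipped at the frame;
  # the boundary curves - invasive front, distractor arcs - are the reliable
  # correspondences), lightly blurred so the correlation peak is smooth and
  # parabolic sub-pixel interpolation is unbiased
  edge_map <- function(m, sig) {
    h <- nrow(m); w <- ncol(m)
    er <- m
    er[2:h, ] <- er[2:h, ] & m[1:(h - 1), ]
    er[1:(h - 1), ] <- er[1:(h - 1), ] & m[2:h, ]
    er[, 2:w] <- er[, 2:w] & m[, 1:(w - 1)]
    er[, 1:(w - 1)] <- er[, 1:(w - 1)] & m[, 2:w]
    e <- m & !er
    e[c(1, 2, h - 1, h), ] <- FALSE
    e[, c(1, 2, w - 1, w)] <- FALSE
    EBImage::gblur(e * 1, sigma = sig)
  }
  run_pass <- function(work_res, thetas, shift_center_um = c(0, 0),
                       shift_halfwidth_um = max_shift_um) {
    f <- max(1L, round(work_res / res_um))
    rw <- res_um * f
    A <- downsample_any(fixed, f); B0 <- downsample_any(moving, f)
    sig <- max(blur_um / rw, 0.8)
    Ab <- edge_map(A, sig)
    # the moving mask is pre-placed at the integer shift estimate, so the
    # canvas only needs to absorb the residual search window
    ctr_px <- round(shift_center_um / rw)   # (dy, dx) order
    hw_px <- rep(ceiling(shift_halfwidth_um / rw), 2)
    P <- c(good_fft_size(nrow(A) + 2 * (hw_px[1] + 4)),
           good_fft_size(ncol(A) + 2 * (hw_px[2] + 4)))
    place <- function(img, off) {
      out <- matrix(0, P[1], P[2])
      ri <- seq_len(nrow(img)); ci <- seq_len(ncol(img))
      rok <- ri + off[1] >= 1 & ri + off[1] <= P[1]
      cok <- ci + off[2] >= 1 & ci + off[2] <= P[2]
      out[ri[rok] + off[1], ci[cok] + off[2]] <- img[ri[rok], ci[cok]]
      out
    }
    FA <- stats::fft(place(Ab, c(0, 0)))
    centre <- c(ncol(A) * rw / 2, nrow(A) * rw / 2)
    best <- NULL
    scores <- numeric(length(thetas))
    for (k in seq_along(thetas)) {
      Br <- resample_mask(B0, rigid_transform(0, 0, thetas[k]), rw, centre)
      Bb <- edge_map(Br, sig)
      r <- xcorr_best_shift(stats::fft(place(Bb, ctr_px)), FA = FA, P = P,
                            center_px = c(0, 0), hw = hw_px)
      r$dy <- r$dy + ctr_px[1]; r$dx <- r$dx + ctr_px[2]
      scores[k] <- r$score
      if (is.null(best) || r$score > best$score) {
        best <- r; best$theta_idx <- k
      }
    }
    list(best = best, scores = scores, thetas = thetas, rw = rw)
  }
  # stage 1: full translation range, 1-degree rotation grid, 8 um
  p1 <- run_pass(8, seq(-rot_range_deg, rot_range_deg, by = 1))
  th0 <- p1$thetas[p1$best$theta_idx]
  u1 <- c(p1$best$dx, p1$best$dy) * p1$rw
  # stage 2: 0.25-degree grid around the stage-1 angle (still 8 um; the
  # continuous polish below supplies the final precision)
  p2 <- run_pass(8, seq(max(-rot_range_deg, th0 - 1.25),
                        min(rot_range_deg, th0 + 1.25), by = 0.25),
                 shift_center_um = rev(u1), shift_halfwidth_um = 80)
  k <- p2$best$theta_idx
  th <- p2$thetas[k]
  if (k > 1 && k < length(p2$thetas)) {
    sm1 <- p2$scores[k - 1]; s0 <- p2$scores[k]; sp1 <- p2$scores[k + 1]
    den <- sm1 - 2 * s0 + sp1
    if (den < 0) th <- th + 0.25 * max(-0.5, min(0.5, 0.5 * (sm1 - sp1) / den))
  }
  u2 <- c(p2$best$dx, p2$best$dy) * p2$rw
  # stage 3: sub-pixel shift at the refined angle
  p3 <- run_pass(max(res_um, 4), th, shift_center_um = rev(u2),
                 shift_halfwidth_um = 40)
  u <- c(p3$best$dx, p3$best$dy) * p3$rw
  # shift u aligns rot(moving, th) onto fixed => t = -R(th) u
  a <- th * pi / 180
  par <- c(-(cos(a) * u[1] - sin(a) * u[2]),
           -(sin(a) * u[1] + cos(a) * u[2]), th)
  # stage 4: continuous Nelder-Mead polish of the blurred-edge overlap,
  # evaluated sparsely on the fixed-edge support with bilinear sampling
  fp <- max(1L, round(max(res_um, 2) / res_um))
  rp <- res_um * fp
  Af <- downsample_any(fixed, fp); Bf <- downsample_any(moving, fp)
  sigp <- max(blur_um / rp, 0.8)
  EA <- edge_map(Af, sigp); EB <- edge_map(Bf, sigp)
  hs <- nrow(EA); ws <- ncol(EA)
  sup <- which(EA > max(EA) * 0.02)
  if (length(sup) > 15000) sup <- sup[seq(1, length(sup), length.out = 15000)]
  if (length(sup) > 10) {
    ctr <- c(ws * rp / 2, hs * rp / 2)
    sx <- ((sup - 1) %/% hs + 0.5) * rp - ctr[1]
    sy <- ((sup - 1) %% hs + 0.5) * rp - ctr[2]
    ea <- EA[sup]
    objective <- function(p) {
      aa <- p[3] * pi / 180
      qx <- (cos(aa) * sx - sin(aa) * sy + ctr[1] + p[1]) / rp + 0.5
      qy <- (sin(aa) * sx + cos(aa) * sy + ctr[2] + p[2]) / rp + 0.5
      j0 <- floor(qx); i0 <- floor(qy); fx <- qx - j0; fy <- qy - i0
      val <- numeric(length(sup))
      for (di in 0:1) for (dj in 0:1) {
        ii <- i0 + di; jj <- j0 + dj
        ok <- ii >= 1 & ii <= hs & jj >= 1 & jj <= ws
        wgt <- (if (di == 1) fy else 1 - fy) * (if (dj == 1) fx else 1 - fx)
        val[ok] <- val[ok] + wgt[ok] * EB[cbind(ii[ok], jj[ok])]
      }
      -sum(ea * val)
    }
    op <- stats::optim(par, objective, method = "Nelder-Mead",
                       control = list(maxit = 100, reltol = 1e-9,
                                      parscale = c(2, 2, 0.05)))
    if (op$value <= objective(par)) par <- op$par
  }
  tr <- rigid_transform(par[1], par[2], par[3])
  aligned <- resample_mask(moving, tr, res_um)
  inter <- sum(fixed & aligned); union <- sum(fixed | aligned)
  iou <- if (union > 0) inter / union else 0
  structure(list(transform = tr,
                 alignment_score = iou,
                 status = if (iou < fail_threshold) "failed" else "success",
                 fail_threshold = fail_threshold),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration: %s (IoU %.3f), dx %.1f um, dy %.1f um, theta %.2f deg\n",
              x$status, x$alignment_score, x$transform$dx_um,
              x$transform$dy_um, x$transform$theta_deg))
  invisible(x)
}

#' Epithelium foreground of a CK8/18 image
#' @param ck_image a [slide_image()].
#' @param dab_threshold DAB concentration (OD) above which a pixel is
#'   CK-positive epithelium.
#' @param stains the [stain_matrix()].
#' @return logical matrix at image resolution.
#' @export
ck_epithelium_mask <- function(ck_image, dab_threshold = 0.15,
                               stains = stain_matrix()) {
  deconvolve(rgb_to_od(ck_image), stains)$dab >= dab_threshold
}

ki67_tissue_mask <- function(ki67_image, od_threshold = 0.2,
                             close_radius_um = 18,
                             stains = stain_matrix()) {
  conc <- deconvolve(rgb_to_od(ki67_image), stains)
  fg <- (conc$h + conc$dab) >= od_threshold
  # fill inter-nucleus gaps so the dotted nuclear pattern approximates the
  # epithelial region it samples; work at 4 um to keep the brush small
  f <- max(1L, round(4 / ki67_image$resolution_um_per_px))
  fg4 <- downsample_any(fg, f)
  r <- max(1L, round(close_radius_um / (ki67_image$resolution_um_per_px * f)))
  k <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  fg4 <- EBImage::closing(EBImage::dilate(fg4 * 1, k), k) > 0.5
  list(mask = fg4, res = ki67_image$resolution_um_per_px * f)
}

#' Register the CK serial section onto the Ki67 section
#'
#' Foregrounds: the CK epithelial mask (DAB threshold) and the Ki67 tissue
#' approximation (nuclear OD threshold, morphologically closed at nucleus
#' spacing scale). Both are registered with [register_masks()].
#'
#' @param ck_image,ki67_image [slide_image()]s at equal resolution.
#' @param max_shift_um,rot_range_deg,fail_threshold see [register_masks()].
#' @param stains the [stain_matrix()].
#' @return a `registration_result`.
#' @export
register_serial <- function(ck_image, ki67_image, max_shift_um = 500,
                            rot_range_deg = 5, fail_threshold = 0.6,
                            stains = stain_matrix()) {
  if (abs(ck_image$resolution_um_per_px - ki67_image$resolution_um_per_px) >
      1e-9) stop("images must share resolution")
  ki <- ki67_tissue_mask(ki67_image, stains = stains)
  f <- round(ki$res / ki67_image$resolution_um_per_px)
  ck <- downsample_any(ck_epithelium_mask(ck_image, stains = stains), f)
  dd <- pmin(dim(ki$mask), dim(ck))
  register_masks(ki$mask[seq_len(dd[1]), seq_len(dd[2])],
                 ck[seq_len(dd[1]), seq_len(dd[2])],
                 res_um = ki$res, max_shift_um = max_shift_um,
                 rot_range_deg = rot_range_deg,
                 fail_threshold = fail_threshold)
}

new_tumour_mask <- function(mask, res, mode, excluded = character(0)) {
  structure(list(mask = mask, resolution_um_per_px = res, mode = mode,
                 excluded_classes = excluded), class = "tumour_mask")
}

#' @export
print.tumour_mask <- function(x, ...) {
  cat(sprintf("tumour_mask [%s]: %d x %d px at %.3g um/px, %.1f%% foreground\n",
              x$mode, ncol(x$mask), nrow(x$mask), x$resolution_um_per_px,
              100 * mean(x$mask)))
  invisible(x)
}

#' Build the VDS-arm tumour mask
#'
#' The CK epithelial mask is brought into the Ki67 frame with the estimated
#' registration transform, exclusion polygons (the manual discard of benign
#' and in-situ areas, supplied in Ki67-frame coordinates) are removed, and the
#' result is morphologically closed at nucleus scale. Refuses with a
#' `vds_registration_failure` error when registration failed - the case is
#' excluded from the VDS arm.
#'
#' @param ck_epithelium either a CK [slide_image()] (thresholded internally)
#'   or a logical epithelium matrix.
#' @param registration a `registration_result` from [register_serial()] /
#'   [register_masks()].
#' @param exclusion_regions region list (polygons in um, Ki67 frame) to
#'   discard; typically the benign + in-situ ground-truth polygons.
#' @param res_um resolution of `ck_epithelium` when given as a matrix.
#' @param close_radius_um radius of the final morphological closing.
#' @param stains the [stain_matrix()] (image input only).
#' @return a `tumour_mask` with mode "vds".
#' @export
build_mask_vds <- function(ck_epithelium, registration,
                           exclusion_regions = list(), res_um = NULL,
                           close_radius_um = 10, stains = stain_matrix()) {
  if (registration$status != "success") {
    stop(structure(class = c("vds_registration_failure", "error", "condition"),
                   list(message = paste(
                     "serial-section registration failed (IoU",
                     sprintf("%.3f", registration$alignment_score),
                     "< threshold); case excluded from the VDS arm"),
                     call = NULL)))
  }
  if (inherits(ck_epithelium, "slide_image")) {
    res_um <- ck_epithelium$resolution_um_per_px
    epi <- ck_epithelium_mask(ck_epithelium, stains = stains)
  } else {
    if (is.null(res_um)) stop("res_um required for a matrix input")
    epi <- ck_epithelium
  }
  mask <- resample_mask(epi, registration$transform, res_um)
  r <- max(1L, round(close_radius_um / res_um))
  k <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  mask <- EBImage::closing(mask * 1, k) > 0.5
  excluded <- character(0)
  for (rg in exclusion_regions) {
    mask <- mask & !rasterize_polygon(rg$polygon, dim(mask), res_um)
    excluded <- union(excluded, rg$region_class)
  }
  new_tumour_mask(mask, res_um, "vds", excluded)
}

#' Build the rule-arm tumour mask
#'
#' Region-based masking on the Ki67 section alone: by default the
#' invasive-tumour ground-truth polygons are rasterised (the stand-in for a
#' trained tumour detector, behind the same interface); benign and in-situ
#' epithelium are always excluded. A pluggable `detector` function
#' (ki67_image -> logical matrix) may replace the polygons. Never needs the CK
#' image, so this arm is available for every case.
#'
#' @param ki67_image the Ki67 [slide_image()] (required for `detector` mode;
#'   otherwise only used for dimensions when given).
#' @param regions a `region_set` with the invasive polygons.
#' @param detector optional function of the image returning a logical mask.
#' @param res_um output mask resolution (defaults to the image resolution or
#'   4 um in region mode).
#' @param extent_um slide extent, required in region mode without an image.
#' @return a `tumour_mask` with mode "rule" (or "ground_truth" when built
#'   directly from ground-truth polygons).
#' @export
build_mask_rule <- function(ki67_image = NULL, regions = NULL, detector = NULL,
                            res_um = NULL,
                            extent_um = attr(regions, "extent_um")) {
  if (!is.null(detector)) {
    if (is.null(ki67_image)) stop("detector mode needs the Ki67 image")
    m <- detector(ki67_image)
    return(new_tumour_mask(m, ki67_image$resolution_um_per_px, "rule",
                           c("benign_epithelium", "carcinoma_in_situ")))
  }
  if (is.null(regions)) {
    stop("either ground-truth regions or a detector must be supplied")
  }
  if (is.null(res_um)) {
    res_um <- if (!is.null(ki67_image)) ki67_image$resolution_um_per_px else 4
  }
  dims <- c(ceiling(extent_um[2] / res_um), ceiling(extent_um[1] / res_um))
  m <- rasterize_regions(regions, dims, res_um, classes = "invasive_tumour")
  new_tumour_mask(m, res_um, "rule",
                  c("benign_epithelium", "carcinoma_in_situ"))
}

#' Keep the cells whose centroid lies inside a tumour mask
#'
#' Membership is centroid-in-mask (the pixel containing the centroid), the
#' simplest reproducible rule. All columns are preserved.
#'
#' @param cells data.frame with x_um, y_um.
#' @param mask a `tumour_mask` covering the same slide extent.
#' @return the filtered cell table (attributes preserved).
#' @export
filter_cells_by_mask <- function(cells, mask) {
  res <- mask$resolution_um_per_px
  ext <- attr(cells, "extent_um")
  if (!is.null(ext)) {
    cover <- c(ncol(mask$mask), nrow(mask$mask)) * res
    if (any(cover < ext - res)) {
      stop("mask does not cover the cell table's slide extent (resolution mismatch?)")
    }
  }
  j <- floor(cells$x_um / res) + 1L
  i <- floor(cells$y_um / res) + 1L
  ok <- i >= 1 & i <= nrow(mask$mask) & j >= 1 & j <= ncol(mask$mask)
  ok[ok] <- mask$mask[cbind(i[ok], j[ok])]
  out <- cells[ok, , drop = FALSE]
  for (a in c("extent_um", "resolution_um_per_px")) {
    attr(out, a) <- attr(cells, a)
  }
  out
}
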