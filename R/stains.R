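# Beer-Lambert two-stain optical model (haematoxylin + DAB). The same model is
# used forwards by the slide generator and backwards by the nucleus detector,
# so generator and detector share one colour convention.

#' Construct a two-stain (haematoxylin, DAB) matrix
#'
#' Columns are optical-density direction vectors for the blue nuclear
#' counterstain (haematoxylin) and the brown chromogen (DAB). Defaults are the
#' Ruifrok-Johnston calibration. The residual direction (normalised cross
#' product) completes the basis; the two-stain least-squares projection is
#' invariant to any pixel component along it.
#'
#' @param haematoxylin,dab length-3 numeric OD vectors.
#' @param normalize scale each column to unit norm (default TRUE).
#' @return object of class `stain_matrix`: list with `S` (3 x 2 matrix),
#'   `residual` (length-3 unit vector), `pinv` (2 x 3 least-squares inverse).
#' @export
stain_matrix <- function(haematoxylin = c(0.65, 0.70, 0.29),
                         dab = c(0.27, 0.57, 0.78),
                         normalize = TRUE) {
  h <- as.numeric(haematoxylin); d <- as.numeric(dab)
  stopifnot(length(h) == 3, length(d) == 3, all(is.finite(c(h, d))))
  if (normalize) {
    h <- h / sqrt(sum(h^2)); d <- d / sqrt(sum(d^2))
  }
  cosang <- sum(h * d) / sqrt(sum(h^2) * sum(d^2))
  if (abs(cosang) > cos(10 * pi / 180)) {
    stop("stain vectors are closer than 10 degrees; matrix is ill-conditioned")
  }
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- r / sqrt(sum(r^2))
  S <- cbind(haematoxylin = h, dab = d)
  structure(list(S = S, residual = r, pinv = solve(crossprod(S), t(S))),
            class = "stain_matrix")
}

#' Convert an 8-bit RGB raster to optical density
#'
#' OD_c = -log10((I_c + eps) / 255) with eps = 1 guarding saturated zeros, and
#' an upper clamp at 3.0 OD.
#'
#' @param rgb numeric array (rows, cols, 3) of 8-bit intensities in 0..255, or
#'   a `slide_image`.
#' @return array of the same shape with per-channel optical densities.
#' @export
rgb_to_od <- function(rgb) {
  if (inherits(rgb, "slide_image")) rgb <- rgb$raster
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("expected an RGB raster with three channels")
  }
  od <- -log10((rgb + 1) / 255)
  pmin(od, 3.0)
}

#' Render haematoxylin / DAB optical-density maps to 8-bit RGB
#'
#' I_c = round(255 * 10^-(H * S_Hc + DAB * S_Dc)).
#'
#' @param h_od,dab_od non-negative numeric matrices of equal dimension.
#' @param stains a [stain_matrix()].
#' @return numeric array (rows, cols, 3) of integers in 0..255.
#' @export
forward_render <- function(h_od, dab_od, stains = stain_matrix()) {
  stopifnot(identical(dim(h_od), dim(dab_od)))
  if (min(h_od) < 0 || min(dab_od) < 0) stop("optical densities must be non-negative")
  S <- stains$S
  out <- array(0, dim = c(dim(h_od), 3L))
  for (ch in 1:3) {
    out[, , ch] <- round(255 * 10^(-(h_od * S[ch, 1] + dab_od * S[ch, 2])))
  }
  out
}

#' Least-squares stain deconvolution
#'
#' Projects each pixel's OD vector onto the two-stain basis (ordinary least
#' squares); the component along the residual direction is discarded. Small
#' negative concentrations from noise are clamped at -0.05.
#'
#' @param od 3-channel OD array from [rgb_to_od()], or an RGB `slide_image`
#'   (converted first).
#' @param stains a [stain_matrix()].
#' @return list of class `od_image`: matrices `h` and `dab` of per-pixel stain
#'   concentrations (OD units).
#' @export
deconvolve <- function(od, stains = stain_matrix()) {
  if (inherits(od, "slide_image")) od <- rgb_to_od(od)
  d <- dim(od)
  stopifnot(length(d) == 3, d[3] == 3)
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% t(stains$pinv)
  conc <- pmax(conc, -0.05)
  structure(list(h = matrix(conc[, 1], d[1], d[2]),
                 dab = matrix(conc[, 2], d[1], d[2])),
            class = "od_image")
}
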