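# CIE 1976 L*a*b* <-> sRGB (IEC 61966-2-1), D65 reference white, 2 deg observer.
# The conversion is written out in full because the contrast statistic is
# defined directly on these coordinates; grDevices::convertColor serves as an
# independent oracle in the test-suite only.

# sRGB (linear) -> XYZ, D65
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.srgb_linearize <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

.srgb_delinearize <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

# Accepts an H x W x 3 array or an n x 3 matrix; returns a list with the
# normalized [0,1] matrix (n x 3) and the original dimensions (or NULL).
.as_rgb01 <- function(image) {
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] < 3L) {
      ce_stop("format_error", "image must have 3 colour channels, got %d", dim(image)[3])
    }
    if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE] # drop alpha
    dims <- dim(image)[1:2]
    m <- matrix(image, ncol = 3L)
  } else if (is.matrix(image) && ncol(image) == 3L) {
    dims <- NULL
    m <- image
  } else if (is.numeric(image) && length(image) == 3L) {
    dims <- NULL
    m <- matrix(image, ncol = 3L)
  } else {
    ce_stop("format_error", "image must be an HxWx3 array or an n x 3 matrix")
  }
  if (anyNA(m)) ce_stop("format_error", "image contains missing values")
  mx <- max(m)
  mn <- min(m)
  if (mn < 0) ce_stop("format_error", "negative colour values are not valid sRGB")
  if (mx > 1) {
    if (mx > 255) ce_stop("format_error", "colour values exceed the 0-255 range")
    m <- m / 255
  }
  list(m = m, dims = dims)
}

.reshape_like <- function(m, dims, names3) {
  colnames(m) <- names3
  if (is.null(dims)) return(m)
  array(m, dim = c(dims, 3L), dimnames = list(NULL, NULL, names3))
}

#' Convert an 8-bit sRGB raster to CIE LAB
#'
#' Standard sRGB linearization, the D65 RGB-to-XYZ matrix and the CIE 1976
#' L*a*b* transform. Pure greys map to a = b = 0; white maps to L = 100.
#'
#' @param image An H x W x 3 array (values in \code{[0,1]} as read by
#'   [png::readPNG()], or 8-bit integers 0-255) or an n x 3 matrix of sRGB
#'   triples.
#' @return An object of the same shape with channels L (0-100), a, b.
#' @examples
#' srgb_to_lab(c(255, 255, 255)) # L = 100, a = 0, b = 0
#' @export
srgb_to_lab <- function(image) {
  x <- .as_rgb01(image)
  lin <- .srgb_linearize(x$m)
  xyz <- lin %*% t(.M_RGB2XYZ)
  fx <- .lab_f(xyz[, 1] / .WHITE_D65[["X"]])
  fy <- .lab_f(xyz[, 2] / .WHITE_D65[["Y"]])
  fz <- .lab_f(xyz[, 3] / .WHITE_D65[["Z"]])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  .reshape_like(lab, x$dims, c("L", "a", "b"))
}

#' Convert CIE LAB to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colours are reported via the
#' `clip` argument: with `clip = TRUE` (default) channels are clamped to
#' \code{[0,1]}; with `clip = FALSE` an error names the offending channel.
#'
#' @param lab H x W x 3 array or n x 3 matrix of L, a, b values.
#' @param clip clamp out-of-gamut channels instead of erroring.
#' @return sRGB values in \code{[0,1]}, same shape as the input.
#' @export
lab_to_srgb <- function(lab, clip = TRUE) {
  if (is.array(lab) && length(dim(lab)) == 3L) {
    dims <- dim(lab)[1:2]
    m <- matrix(lab, ncol = 3L)
  } else if (is.matrix(lab) && ncol(lab) == 3L) {
    dims <- NULL
    m <- lab
  } else if (is.numeric(lab) && length(lab) == 3L) {
    dims <- NULL
    m <- matrix(lab, ncol = 3L)
  } else {
    ce_stop("format_error", "lab must be an HxWx3 array or an n x 3 matrix")
  }
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(
    .lab_f_inv(fx) * .WHITE_D65[["X"]],
    .lab_f_inv(fy) * .WHITE_D65[["Y"]],
    .lab_f_inv(fz) * .WHITE_D65[["Z"]]
  )
  lin <- xyz %*% t(.M_XYZ2RGB)
  if (!clip && (min(lin) < -1e-9 || max(lin) > 1 + 1e-9)) {
    bad <- which(lin < -1e-9 | lin > 1 + 1e-9, arr.ind = TRUE)
    ce_stop(
      "gamut_error", "LAB colour outside the sRGB gamut (channel %s)",
      paste(unique(c("R", "G", "B")[bad[, 2]]), collapse = ", ")
    )
  }
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  .reshape_like(.srgb_delinearize(lin), dims, c("R", "G", "B"))
}

#' Test whether a LAB colour lies inside the sRGB gamut
#'
#' @param lab length-3 vector or n x 3 matrix of L, a, b values.
#' @return Logical vector.
#' @export
lab_in_gamut <- function(lab) {
  m <- if (is.matrix(lab)) lab else matrix(lab, ncol = 3L, byrow = is.null(dim(lab)) && length(lab) > 3L)
  if (length(lab) == 3L && !is.matrix(lab)) m <- matrix(lab, ncol = 3L)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(
    .lab_f_inv(fx) * .WHITE_D65[["X"]],
    .lab_f_inv(fy) * .WHITE_D65[["Y"]],
    .lab_f_inv(fz) * .WHITE_D65[["Z"]]
  )
  lin <- xyz %*% t(.M_XYZ2RGB)
  apply(lin, 1L, function(r) all(r >= -1e-9 & r <= 1 + 1e-9))
}
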