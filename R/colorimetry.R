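# The measurement at the centre of the package: mean CIE LAB colour over the
# iris and pupil regions of one eye, with specular highlights excluded, and
# the per-channel Michelson-type contrast
#   (pupil mean - iris mean) / (pupil mean + iris mean).
# Sign convention: pupil minus iris, so a dark pupil against a lighter iris
# gives a negative L contrast. L contrast is bounded in [-1, 1]; the signed
# a/b channels are not, and a near-zero denominator is flagged as undefined
# rather than propagated as +/-Inf.

#' Remove specular highlights from an annotation
#'
#' Pixels inside the explicit highlight mask (if present) and pixels whose
#' lightness exceeds `threshold` are removed from both region masks — the
#' mechanical analogue of excluding light-source reflections by hand when
#' tracing regions.
#'
#' @param lab LAB raster (H x W x 3) from [srgb_to_lab()].
#' @param annotation an [eye_annotation()].
#' @param threshold L-value above which a pixel counts as a highlight
#'   (default 95).
#' @return The annotation with reduced masks; attribute `removed` holds the
#'   per-region removal counts.
#' @export
exclude_highlights <- function(lab, annotation, threshold = 95) {
  stopifnot(inherits(annotation, "eye_annotation"))
  L <- if (length(dim(lab)) == 3L) lab[, , 1] else ce_stop("format_error", "lab raster must be HxWx3")
  if (!identical(dim(L), dim(annotation$iris_mask))) {
    ce_stop("format_error", "LAB raster and masks differ in dimensions")
  }
  bright <- L > threshold
  if (!is.null(annotation$highlight_mask)) bright <- bright | annotation$highlight_mask
  new_iris <- annotation$iris_mask & !bright
  new_pupil <- annotation$pupil_mask & !bright
  removed <- c(
    iris = sum(annotation$iris_mask) - sum(new_iris),
    pupil = sum(annotation$pupil_mask) - sum(new_pupil)
  )
  if (!any(new_iris)) {
    ce_stop("degenerate_region_error", "highlight exclusion emptied the iris mask")
  }
  if (!any(new_pupil)) {
    ce_stop("degenerate_region_error", "highlight exclusion emptied the pupil mask")
  }
  out <- annotation
  out$iris_mask <- new_iris
  out$pupil_mask <- new_pupil
  attr(out, "removed") <- removed
  out
}

#' Mean LAB colour over the iris and pupil regions
#'
#' @inheritParams exclude_highlights
#' @return A data frame with one row per region: `image_id`, `region`,
#'   `L`, `a`, `b` (region means) and `pixel_count`.
#' @export
region_mean <- function(lab, annotation) {
  stopifnot(inherits(annotation, "eye_annotation"))
  if (length(dim(lab)) != 3L || !identical(dim(lab)[1:2], dim(annotation$iris_mask))) {
    ce_stop("format_error", "LAB raster and masks differ in dimensions")
  }
  one <- function(mask, region) {
    n <- sum(mask)
    if (n == 0L) ce_stop("degenerate_region_error", "empty %s mask", region)
    data.frame(
      image_id = annotation$image_id, region = region,
      L = mean(lab[, , 1][mask]),
      a = mean(lab[, , 2][mask]),
      b = mean(lab[, , 3][mask]),
      pixel_count = n,
      stringsAsFactors = FALSE
    )
  }
  rbind(one(annotation$iris_mask, "iris"), one(annotation$pupil_mask, "pupil"))
}

#' Iris-pupil contrast from region means
#'
#' Per channel: `(pupil - iris) / (pupil + iris)`. A channel whose
#' denominator magnitude falls below `denom_floor` is returned as `NA` with
#' its name recorded in the `undefined` field, never as Inf/NaN.
#'
#' @param pupil,iris length-3 LAB vectors (or single rows of
#'   [region_mean()] output).
#' @param denom_floor smallest admissible |pupil + iris| per channel.
#' @return A list with `c_L`, `c_A`, `c_B` and `undefined` (character vector
#'   of flagged channels).
#' @examples
#' iris_pupil_contrast(c(10, 0, 0), c(50, 0, 0))$c_L # -0.6667
#' @export
iris_pupil_contrast <- function(pupil, iris, denom_floor = 1e-6) {
  as3 <- function(x) {
    if (is.data.frame(x)) x <- unlist(x[1, c("L", "a", "b")])
    stopifnot(length(x) == 3L, all(is.finite(x)))
    as.numeric(x)
  }
  p <- as3(pupil)
  i <- as3(iris)
  den <- p + i
  num <- p - i
  ok <- abs(den) >= denom_floor
  v <- ifelse(ok, num / den, NA_real_)
  list(
    c_L = v[1], c_A = v[2], c_B = v[3],
    undefined = c("L", "A", "B")[!ok]
  )
}

#' Per-image contrast table
#'
#' Runs highlight exclusion, region means and the contrast statistic over a
#' set of images, producing the tidy per-image table consumed by
#' [compare_species()].
#'
#' @param images list of sRGB rasters (H x W x 3).
#' @param annotations list of [eye_annotation()] objects, parallel to
#'   `images`.
#' @param highlight_threshold L-threshold for [exclude_highlights()].
#' @param denom_floor passed to [iris_pupil_contrast()].
#' @return Data frame with columns `image_id`, `species`, `n_iris_px`,
#'   `n_pupil_px`, `iris_L/a/b`, `pupil_L/a/b`, `c_L`, `c_A`, `c_B`,
#'   `undefined_channels` (comma-separated flags, empty if none).
#' @export
contrast_table <- function(images, annotations, highlight_threshold = 95,
                           denom_floor = 1e-6) {
  stopifnot(length(images) == length(annotations))
  rows <- lapply(seq_along(images), function(k) {
    lab <- srgb_to_lab(images[[k]])
    ann <- exclude_highlights(lab, annotations[[k]], threshold = highlight_threshold)
    rm <- region_mean(lab, ann)
    iris <- rm[rm$region == "iris", ]
    pupil <- rm[rm$region == "pupil", ]
    ct <- iris_pupil_contrast(pupil, iris, denom_floor = denom_floor)
    data.frame(
      image_id = ann$image_id, species = ann$species,
      n_iris_px = iris$pixel_count, n_pupil_px = pupil$pixel_count,
      iris_L = iris$L, iris_a = iris$a, iris_b = iris$b,
      pupil_L = pupil$L, pupil_a = pupil$a, pupil_b = pupil$b,
      c_L = ct$c_L, c_A = ct$c_A, c_B = ct$c_B,
      undefined_channels = paste(ct$undefined, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
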