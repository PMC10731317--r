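# Region annotations: which pixels belong to the iris, the pupil, and (if
# known) the specular highlight. Two on-disk dialects are supported and must
# agree: a label-image PNG (0 = background, 1 = iris, 2 = pupil, 3 =
# highlight) and a polygon JSON file with closed rings in 0-based
# pixel-centre (x, y) image coordinates.

LABEL_BACKGROUND <- 0L
LABEL_IRIS <- 1L
LABEL_PUPIL <- 2L
LABEL_HIGHLIGHT <- 3L

#' Construct an eye annotation
#'
#' @param image_id identifier of the photograph.
#' @param species `"wolf"` or `"dog"`.
#' @param iris_mask,pupil_mask logical matrices congruent with the image;
#'   must be disjoint and non-empty.
#' @param highlight_mask optional logical matrix marking specular reflections
#'   of the light source; pixels under it are excluded from both regions.
#' @return An object of class `eye_annotation`.
#' @export
eye_annotation <- function(image_id, species, iris_mask, pupil_mask,
                           highlight_mask = NULL) {
  species <- match.arg(species, c("wolf", "dog"))
  stopifnot(is.matrix(iris_mask), is.matrix(pupil_mask))
  iris_mask <- iris_mask > 0
  pupil_mask <- pupil_mask > 0
  if (!identical(dim(iris_mask), dim(pupil_mask))) {
    ce_stop("format_error", "iris and pupil masks differ in dimensions")
  }
  if (!is.null(highlight_mask)) {
    highlight_mask <- highlight_mask > 0
    if (!identical(dim(highlight_mask), dim(iris_mask))) {
      ce_stop("format_error", "highlight mask dimensions differ from the region masks")
    }
  }
  if (any(iris_mask & pupil_mask)) {
    ce_stop("format_error", "iris and pupil masks overlap (%d pixels)",
            sum(iris_mask & pupil_mask))
  }
  if (!any(iris_mask)) ce_stop("degenerate_region_error", "iris mask is empty")
  if (!any(pupil_mask)) ce_stop("degenerate_region_error", "pupil mask is empty")
  structure(
    list(
      image_id = as.character(image_id), species = species,
      iris_mask = iris_mask, pupil_mask = pupil_mask,
      highlight_mask = highlight_mask
    ),
    class = "eye_annotation"
  )
}

#' @method print eye_annotation
#' @export
print.eye_annotation <- function(x, ...) {
  cat(sprintf(
    "<eye_annotation> %s (%s): %d iris px, %d pupil px, %s highlight px, %dx%d\n",
    x$image_id, x$species, sum(x$iris_mask), sum(x$pupil_mask),
    if (is.null(x$highlight_mask)) "no" else sum(x$highlight_mask),
    nrow(x$iris_mask), ncol(x$iris_mask)
  ))
  invisible(x)
}

#' Convert a label matrix to an annotation
#'
#' @param labels integer matrix with values 0 (background), 1 (iris),
#'   2 (pupil), 3 (highlight).
#' @inheritParams eye_annotation
#' @return An `eye_annotation`.
#' @export
annotation_from_labels <- function(labels, image_id, species) {
  labels <- round(labels)
  if (any(!labels %in% 0:3)) {
    ce_stop("format_error", "label image contains values outside 0..3")
  }
  hl <- labels == LABEL_HIGHLIGHT
  eye_annotation(
    image_id, species,
    iris_mask = labels == LABEL_IRIS,
    pupil_mask = labels == LABEL_PUPIL,
    highlight_mask = if (any(hl)) hl else NULL
  )
}

#' Read a label-image PNG mask
#'
#' The label PNG stores labels 0..3 in an 8-bit grey channel (value = label,
#' i.e. intensity label/255).
#'
#' @param path PNG file path.
#' @inheritParams eye_annotation
#' @return An `eye_annotation`.
#' @export
read_label_mask <- function(path, image_id, species) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  annotation_from_labels(round(g * 255), image_id, species)
}

#' Write a label-image PNG mask
#'
#' @param annotation an `eye_annotation`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(annotation, path) {
  stopifnot(inherits(annotation, "eye_annotation"))
  lab <- matrix(LABEL_BACKGROUND, nrow(annotation$iris_mask), ncol(annotation$iris_mask))
  lab[annotation$iris_mask] <- LABEL_IRIS
  lab[annotation$pupil_mask] <- LABEL_PUPIL
  if (!is.null(annotation$highlight_mask)) lab[annotation$highlight_mask] <- LABEL_HIGHLIGHT
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Rasterize a closed polygon ring to a pixel mask
#'
#' Pixel-centre convention: pixel (row r, column c) of the mask, 1-based,
#' has centre (x, y) = (c - 1, r - 1) in 0-based image coordinates.
#'
#' @param ring m x 2 matrix of (x, y) vertices; closed automatically.
#' @param width,height mask dimensions in pixels.
#' @return Logical `height` x `width` matrix.
#' @export
rasterize_polygon <- function(ring, width, height) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || nrow(ring) < 3L) {
    ce_stop("format_error", "polygon ring must be an m x 2 matrix with m >= 3")
  }
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
    ring <- rbind(ring, ring[1, ])
  }
  centres <- cbind(
    x = rep(seq_len(width) - 1, each = height),
    y = rep(seq_len(height) - 1, times = width)
  )
  inside <- mgcv::in.out(ring, centres)
  matrix(inside, nrow = height, ncol = width)
}

#' Read a polygon-JSON annotation
#'
#' Schema: `{"image_id": ..., "species": ..., "width": w, "height": h,
#' "regions": {"iris": [[x,y],...], "pupil": [...], "highlight": [...]}}`
#' with closed rings in 0-based pixel-centre image coordinates (the
#' `highlight` region is optional).
#'
#' @param path JSON file path.
#' @return An `eye_annotation` identical (on the rasterized test polygons)
#'   to the label-PNG reader's output.
#' @export
read_polygon_mask <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("image_id", "species", "width", "height", "regions")
  if (!all(need %in% names(j))) {
    ce_stop("format_error", "polygon file missing fields: %s",
            paste(setdiff(need, names(j)), collapse = ", "))
  }
  ras <- function(region) {
    if (is.null(j$regions[[region]])) return(NULL)
    rasterize_polygon(j$regions[[region]], j$width, j$height)
  }
  iris <- ras("iris")
  pupil <- ras("pupil")
  if (is.null(iris) || is.null(pupil)) {
    ce_stop("format_error", "polygon file must define both iris and pupil rings")
  }
  hl <- ras("highlight")
  # a highlight ring may legitimately sit inside a region ring
  iris <- iris & !pupil
  eye_annotation(j$image_id, j$species, iris, pupil, highlight_mask = hl)
}

#' Write a polygon-JSON annotation
#'
#' @param image_id,species metadata fields.
#' @param rings named list of m x 2 rings (`iris`, `pupil`, optionally
#'   `highlight`) in 0-based (x, y) coordinates.
#' @param width,height image dimensions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygon_mask <- function(image_id, species, rings, width, height, path) {
  jsonlite::write_json(
    list(
      image_id = image_id, species = species,
      width = width, height = height,
      regions = lapply(rings, function(r) unname(as.matrix(r)))
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
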