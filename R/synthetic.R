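# Synthetic world. Two generators:
#  (a) parametric eye images: anti-aliased concentric ellipses (iris, pupil)
#      with known CIE LAB colours, an optional specular disc at L ~ 100, and
#      Gaussian sRGB noise, emitted together with the exact label mask and
#      the analytic contrast implied by the specified colours;
#  (b) questionnaire data: a two-factor latent model (friendliness,
#      maturity) with an eye-colour shift, stimulus- and participant-level
#      random effects, discretization to the 0-5 item scale, and acceptance
#      responses from a linear model on the rater's own scale scores,
#      discretized to 0-3, under the counterbalanced 4-version design.
# Every generator takes an explicit seed; nothing touches global RNG state.

#' Specification of a synthetic eye image
#'
#' @param width,height image size in pixels.
#' @param centre iris/pupil common centre (x, y), 0-based pixel-centre
#'   coordinates.
#' @param iris_axes,pupil_axes ellipse semi-axes (pixels); the pupil must be
#'   strictly inside the iris (concentric, both axes smaller).
#' @param rotation ellipse rotation in radians.
#' @param iris_lab,pupil_lab length-3 CIE LAB colours; must lie inside the
#'   sRGB gamut.
#' @param highlight optional list(`centre` = c(x, y), `radius`) specular
#'   disc rendered at L = 100 (white).
#' @param noise_sd per-channel Gaussian sRGB noise standard deviation on the
#'   [0,1] scale.
#' @param background_lab LAB colour outside the iris.
#' @param image_id,species metadata attached to the emitted annotation.
#' @return Object of class `synthetic_eye_spec`.
#' @export
synthetic_eye_spec <- function(width = 64, height = 64,
                               centre = c((width - 1) / 2, (height - 1) / 2),
                               iris_axes = c(0.40 * width, 0.34 * height),
                               pupil_axes = 0.35 * iris_axes,
                               rotation = 0,
                               iris_lab = c(40, 15, 30),
                               pupil_lab = c(12, 4, 8),
                               highlight = NULL,
                               noise_sd = 0,
                               background_lab = c(75, 0, 0),
                               image_id = "synthetic", species = "dog") {
  stopifnot(width >= 8, height >= 8, all(iris_axes > 0), all(pupil_axes > 0))
  if (any(pupil_axes >= iris_axes)) {
    ce_stop("format_error", "pupil ellipse must be strictly inside the iris ellipse")
  }
  for (nm in c("iris_lab", "pupil_lab", "background_lab")) {
    lab <- get(nm)
    if (!lab_in_gamut(lab)) ce_stop("gamut_error", "%s is outside the sRGB gamut", nm)
  }
  if (!is.null(highlight)) {
    stopifnot(is.list(highlight), length(highlight$centre) == 2L, highlight$radius > 0)
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height), centre = centre,
      iris_axes = iris_axes, pupil_axes = pupil_axes, rotation = rotation,
      iris_lab = iris_lab, pupil_lab = pupil_lab, highlight = highlight,
      noise_sd = noise_sd, background_lab = background_lab,
      image_id = as.character(image_id), species = species
    ),
    class = "synthetic_eye_spec"
  )
}

# squared normalized ellipse radius of points (x, y)
.ellipse_q <- function(x, y, centre, axes, rotation) {
  dx <- x - centre[1]
  dy <- y - centre[2]
  u <- dx * cos(rotation) + dy * sin(rotation)
  v <- -dx * sin(rotation) + dy * cos(rotation)
  (u / axes[1])^2 + (v / axes[2])^2
}

#' Render a synthetic eye
#'
#' Anti-aliasing by 3 x 3 subpixel sampling; the label mask takes each
#' pixel's majority label (precedence highlight > pupil > iris on ties), so
#' masks are pixel-identical across runs for a fixed spec. Gaussian sRGB
#' noise (if any) is added after compositing, then the image is clipped to
#' [0,1] and quantized to 8 bits.
#'
#' @param spec a [synthetic_eye_spec()].
#' @param seed RNG seed for the noise.
#' @return List: `image` (H x W x 3 sRGB in [0,1], 8-bit quantized),
#'   `labels` (integer matrix, 0 bg / 1 iris / 2 pupil / 3 highlight),
#'   `annotation` ([eye_annotation()]), `analytic` (contrast implied by the
#'   spec colours, via [iris_pupil_contrast()]), `spec`.
#' @export
render_eye <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  h <- spec$height
  w <- spec$width
  # subpixel offsets, pixel centres at 0-based integer coordinates
  off <- c(-1 / 3, 0, 1 / 3)
  px <- rep(seq_len(w) - 1, each = h)
  py <- rep(seq_len(h) - 1, times = w)
  counts <- matrix(0L, h * w, 4L) # columns: bg, iris, pupil, highlight
  for (ox in off) {
    for (oy in off) {
      x <- px + ox
      y <- py + oy
      lab <- integer(h * w) # 0 = background
      lab[.ellipse_q(x, y, spec$centre, spec$iris_axes, spec$rotation) <= 1] <- 1L
      lab[.ellipse_q(x, y, spec$centre, spec$pupil_axes, spec$rotation) <= 1] <- 2L
      if (!is.null(spec$highlight)) {
        r2 <- (x - spec$highlight$centre[1])^2 + (y - spec$highlight$centre[2])^2
        lab[r2 <= spec$highlight$radius^2] <- 3L
      }
      for (k in 0:3) counts[, k + 1L] <- counts[, k + 1L] + (lab == k)
    }
  }
  # composite colour = coverage-weighted mean of the class colours (in sRGB)
  cols <- rbind(
    lab_to_srgb(spec$background_lab),
    lab_to_srgb(spec$iris_lab),
    lab_to_srgb(spec$pupil_lab),
    c(1, 1, 1)
  )
  rgb <- (counts %*% cols) / 9
  if (spec$noise_sd > 0) {
    rgb <- rgb + with_seed(seed, matrix(stats::rnorm(length(rgb), 0, spec$noise_sd),
                                        nrow(rgb), ncol(rgb)))
  }
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  rgb <- round(rgb * 255) / 255
  image <- array(rgb, dim = c(h, w, 3L))
  # majority label; max.col with ties.method "last" gives the precedence
  # highlight > pupil > iris > background on exact ties
  labels <- matrix(max.col(counts, ties.method = "last") - 1L, h, w)
  # ground-truth annotation is conservative: a pixel belongs to a region
  # only when fully covered by it, so edge pixels blended by anti-aliasing
  # never contaminate region means; any highlight coverage excludes a pixel
  annotation <- eye_annotation(
    spec$image_id, spec$species,
    iris_mask = matrix(counts[, 2] == 9L, h, w),
    pupil_mask = matrix(counts[, 3] == 9L, h, w),
    highlight_mask = if (any(counts[, 4] > 0L)) matrix(counts[, 4] > 0L, h, w) else NULL
  )
  list(
    image = image, labels = labels, annotation = annotation,
    analytic = iris_pupil_contrast(spec$pupil_lab, spec$iris_lab),
    spec = spec
  )
}

.trunc_norm1 <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Sample eye-image specifications for a two-species cohort
#'
#' Draws per-image iris and pupil LAB colours and geometry from
#' species-level distributions: wolf-like irises are light and yellowish,
#' dog-like irises darker and more reddish, pupils dark in both; the
#' blue-yellow channel is drawn from the same distribution in both species
#' (a true null). Colours are kept inside the sRGB gamut by truncation.
#' Under the defaults the species gap in L-channel contrast is about one
#' pooled SD at n = 22 vs 81.
#'
#' @param n_wolf,n_dog group sizes (defaults: the 22 + 81 of the reference
#'   design).
#' @param seed RNG seed.
#' @param size image side in pixels.
#' @param noise_sd sRGB noise for the renders.
#' @param highlight_prob probability an image carries a specular disc.
#' @return List of [synthetic_eye_spec()] objects with image_ids
#'   `wolf_01..` / `dog_01..`.
#' @export
sample_eye_specs <- function(n_wolf = 22, n_dog = 81, seed = 1, size = 64,
                             noise_sd = 0.01, highlight_prob = 0.8) {
  with_seed(seed, {
    specs <- list()
    species <- c(rep("wolf", n_wolf), rep("dog", n_dog))
    idx <- c(seq_len(n_wolf), seq_len(n_dog))
    for (k in seq_along(species)) {
      sp <- species[k]
      iris_lab <- c(
        if (sp == "wolf") .trunc_norm1(1, 60, 10, 35, 80) else .trunc_norm1(1, 38, 10, 15, 65),
        if (sp == "wolf") .trunc_norm1(1, 6, 4, -5, 20) else .trunc_norm1(1, 16, 5, 2, 30),
        .trunc_norm1(1, 30, 8, 8, 50)
      )
      pupil_lab <- c(
        .trunc_norm1(1, 12, 6, 4, 30),
        .trunc_norm1(1, 4, 3, -4, 14),
        .trunc_norm1(1, 8, 4, 0, 20)
      )
      # truncation keeps colours realistic; pull chroma in if still out of gamut
      for (try in 1:20) {
        ok_i <- lab_in_gamut(iris_lab)
        ok_p <- lab_in_gamut(pupil_lab)
        if (ok_i && ok_p) break
        if (!ok_i) iris_lab[2:3] <- iris_lab[2:3] * 0.85
        if (!ok_p) pupil_lab[2:3] <- pupil_lab[2:3] * 0.85
      }
      iris_ax <- c(stats::runif(1, 0.34, 0.42) * size, stats::runif(1, 0.28, 0.36) * size)
      pupil_ax <- stats::runif(1, 0.28, 0.42) * iris_ax
      centre <- c((size - 1) / 2, (size - 1) / 2)
      highlight <- if (stats::runif(1) < highlight_prob) {
        r <- stats::runif(1, 0.15, 0.3) * min(pupil_ax)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.5) * min(pupil_ax)
        list(centre = centre + rad * c(cos(ang), sin(ang)), radius = r)
      } else {
        NULL
      }
      specs[[k]] <- synthetic_eye_spec(
        width = size, height = size, centre = centre,
        iris_axes = iris_ax, pupil_axes = pupil_ax,
        rotation = stats::runif(1, 0, pi),
        iris_lab = iris_lab, pupil_lab = pupil_lab,
        highlight = highlight, noise_sd = noise_sd,
        image_id = sprintf("%s_%02d", sp, idx[k]), species = sp
      )
    }
    specs
  })
}

#' Counterbalanced four-version questionnaire design
#'
#' Twelve dog images, each appearing as a dark-eyed and a light-eyed
#' stimulus (24 stimuli). Each version carries 6 stimuli of 6 distinct
#' images, 3 dark and 3 light; across versions A-D each stimulus appears
#' exactly once. Participants are allocated to versions as evenly as the
#' total allows.
#'
#' @param n_participants number of raters (>= 4).
#' @param seed RNG seed.
#' @param n_images number of dog images (must be divisible by 4 x groups;
#'   default 12).
#' @return Object of class `study_design`: `versions` (data frame `version`,
#'   `image_id`, `eye_colour`) and `participants` (data frame
#'   `participant_id`, `version`).
#' @export
generate_design <- function(n_participants, seed = 1, n_images = 12) {
  if (n_participants < 4L) ce_stop("sample_size_error", "need at least 4 participants")
  if (n_images %% 4L != 0L) ce_stop("format_error", "n_images must be divisible by 4")
  with_seed(seed, {
    perm <- sample(n_images)
    g <- split(perm, rep(1:4, each = n_images / 4))
    block <- function(version, dark_ids, light_ids) {
      data.frame(
        version = version,
        image_id = c(dark_ids, light_ids),
        eye_colour = rep(c("dark", "light"), each = length(dark_ids)),
        stringsAsFactors = FALSE
      )
    }
    versions <- rbind(
      block("A", g[[1]], g[[2]]), block("B", g[[2]], g[[1]]),
      block("C", g[[3]], g[[4]]), block("D", g[[4]], g[[3]])
    )
    assignment <- sample(rep_len(c("A", "B", "C", "D"), n_participants))
    structure(
      list(
        versions = versions,
        participants = data.frame(
          participant_id = seq_len(n_participants),
          version = assignment, stringsAsFactors = FALSE
        ),
        n_images = n_images
      ),
      class = "study_design"
    )
  })
}

.default_pattern_loadings <- function() {
  ref <- reference_loadings(2)
  L <- matrix(0, nrow(ref), 2, dimnames = list(ref$item, c("friendliness", "maturity")))
  for (i in seq_len(nrow(ref))) {
    j <- which.max(abs(c(ref$factor1[i], ref$factor2[i])))
    L[i, j] <- c(ref$factor1[i], ref$factor2[i])[j]
  }
  L
}

#' Latent rating-model specification
#'
#' The defaults are the package's stated world: the published two-factor
#' salient-loading pattern (cross-loadings zeroed), uniquenesses 1 - lambda^2,
#' latent dark-minus-light shifts calibrated to the published mean scale
#' differences (about +0.87 friendliness and -0.62 maturity on the 0-5
#' scale), stimulus- and participant-level random-effect SDs chosen so each
#' latent factor has unit variance, and acceptance coefficients following
#' the published model (friendliness drives acceptance; eye colour and
#' maturity do not).
#'
#' @param loadings 10 x 2 matrix (items x friendliness/maturity), one
#'   salient loading per item.
#' @param uniqueness per-item unique variances (default `1 - rowSums(loadings^2)`).
#' @param delta_f,delta_m latent dark-minus-light shift on each factor.
#' @param image_sd,participant_sd random-effect SDs per factor (length 2:
#'   friendliness, maturity). The image effect is drawn per *stimulus*
#'   (image x eye colour): recolouring yields a distinct stimulus, and a
#'   draw shared between the two colours of an image would cancel exactly in
#'   the paired contrast. `NULL` = calibrate so each factor has variance 1.
#' @param accept_coefs list with elements `interact` and `keep`, each
#'   `c(intercept, eye, friendliness, maturity)` on the 0-3 response scale
#'   per unit 0-5 scale score.
#' @param accept_image_sd SD of the per-image (12 levels) random intercept
#'   of the acceptance model.
#' @param accept_resid_sd residual SD of the acceptance model.
#' @param anchor half-range of the latent-to-item map: a latent item value
#'   of +/- `anchor` (latent SD) maps to the ends of the 0-5 scale.
#' @param seed RNG seed used by [generate_ratings()].
#' @return Object of class `rating_model_spec`.
#' @export
rating_model_spec <- function(loadings = .default_pattern_loadings(),
                              uniqueness = NULL,
                              delta_f = 1.15, delta_m = -0.95,
                              image_sd = NULL, participant_sd = NULL,
                              accept_coefs = list(
                                interact = c(intercept = 0.85, eye = 0.034,
                                             friendliness = 0.304, maturity = -0.062),
                                keep = c(intercept = 0.50, eye = 0.098,
                                         friendliness = 0.340, maturity = 0.034)
                              ),
                              accept_image_sd = 0.2,
                              accept_resid_sd = 0.6,
                              anchor = 2.5,
                              seed = 1) {
  stopifnot(is.matrix(loadings), ncol(loadings) == 2L)
  if (is.null(uniqueness)) uniqueness <- pmax(1 - rowSums(loadings^2), 0)
  if (any(uniqueness < 0)) ce_stop("format_error", "uniqueness must be non-negative")
  calib <- function(delta) sqrt(max(1 - delta^2 / 4, 0.02) / 2)
  if (is.null(image_sd)) image_sd <- c(calib(delta_f), calib(delta_m))
  if (is.null(participant_sd)) participant_sd <- c(calib(delta_f), calib(delta_m))
  structure(
    list(
      loadings = loadings, uniqueness = uniqueness,
      delta_f = delta_f, delta_m = delta_m,
      image_sd = rep_len(image_sd, 2L), participant_sd = rep_len(participant_sd, 2L),
      accept_coefs = accept_coefs,
      accept_image_sd = accept_image_sd, accept_resid_sd = accept_resid_sd,
      anchor = anchor, seed = seed
    ),
    class = "rating_model_spec"
  )
}

#' Generate questionnaire ratings
#'
#' For each participant x stimulus row: latent factor value = eye-colour
#' shift (+delta/2 dark, -delta/2 light) + stimulus effect + participant
#' effect; item response = loading x latent + uniqueness noise, mapped
#' linearly to 0-5 (anchored at +/- `anchor` latent SD) and rounded/clipped.
#' Acceptance responses come from the linear model on the rater's own
#' observed scale scores plus a per-image random intercept and residual
#' noise, rounded/clipped to 0-3. Deterministic given `model$seed`.
#'
#' @param design a [generate_design()] object.
#' @param model a [rating_model_spec()].
#' @param study cohort label (2 or 3) recorded in the output.
#' @return Data frame, one row per participant x stimulus: `participant_id`,
#'   `study`, `version`, `image_id`, `eye_colour`, the ten item columns,
#'   `interact`, `keep`.
#' @export
generate_ratings <- function(design, model, study = 2) {
  stopifnot(inherits(design, "study_design"), inherits(model, "rating_model_spec"))
  with_seed(model$seed, {
    vs <- design$versions
    parts <- design$participants
    rows <- merge(parts, vs, by = "version")
    rows <- rows[order(rows$participant_id, rows$image_id, rows$eye_colour), ]
    n <- nrow(rows)
    n_part <- nrow(parts)
    stim_key <- paste(vs$image_id, vs$eye_colour)
    stim_of <- match(paste(rows$image_id, rows$eye_colour), stim_key)
    deltas <- c(model$delta_f, model$delta_m)
    dark <- as.numeric(rows$eye_colour == "dark")
    f <- sapply(1:2, function(k) {
      stim_eff <- stats::rnorm(length(stim_key), 0, model$image_sd[k])
      part_eff <- stats::rnorm(n_part, 0, model$participant_sd[k])
      deltas[k] * (dark - 0.5) + stim_eff[stim_of] + part_eff[rows$participant_id]
    })
    items <- rownames(model$loadings)
    half <- 5 / 2
    for (j in seq_along(items)) {
      lam <- model$loadings[j, ]
      x <- f %*% lam + stats::rnorm(n, 0, sqrt(model$uniqueness[j]))
      score <- round(x / model$anchor * half + half)
      rows[[items[j]]] <- pmin(pmax(as.integer(score), 0L), 5L)
    }
    for (j in seq_along(items)) {
      sat <- mean(rows[[items[j]]] %in% c(0L, 5L))
      if (sat > 0.2) {
        warning(sprintf("calibration: item '%s' saturates at a boundary in %.0f%% of responses",
                        items[j], 100 * sat))
      }
    }
    # observed scale scores (aggressive is the one negatively keyed item)
    neg <- items[model$loadings[, 1] < 0 | model$loadings[, 2] < 0]
    vals <- as.matrix(rows[, items])
    vals[, neg] <- 5 - vals[, neg]
    on_f <- items[model$loadings[, 1] != 0]
    on_m <- items[model$loadings[, 2] != 0]
    F_obs <- rowMeans(vals[, on_f, drop = FALSE])
    M_obs <- rowMeans(vals[, on_m, drop = FALSE])
    for (resp in c("interact", "keep")) {
      bc <- model$accept_coefs[[resp]]
      img_re <- stats::rnorm(design$n_images, 0, model$accept_image_sd)
      y <- bc[1] + bc[2] * dark + bc[3] * F_obs + bc[4] * M_obs +
        img_re[rows$image_id] + stats::rnorm(n, 0, model$accept_resid_sd)
      rows[[resp]] <- pmin(pmax(as.integer(round(y)), 0L), 3L)
      sat <- mean(rows[[resp]] %in% c(0L, 3L))
      if (sat > 0.2) {
        warning(sprintf("calibration: response '%s' saturates at a boundary in %.0f%% of responses",
                        resp, 100 * sat))
      }
    }
    out <- data.frame(
      participant_id = rows$participant_id, study = study,
      version = rows$version, image_id = rows$image_id,
      eye_colour = rows$eye_colour,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, rows[, c(items, "interact", "keep")])
    rownames(out) <- NULL
    out
  })
}
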