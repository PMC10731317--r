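# Shared fixture builders. Everything is generated in code; no binary data.

# uniform-colour image with simple rectangular region masks
uniform_eye_fixture <- function(h = 20, w = 20, colour = c(0.5, 0.4, 0.3),
                                species = "dog", image_id = "fix") {
  img <- array(rep(colour, each = h * w), dim = c(h, w, 3))
  iris <- matrix(FALSE, h, w)
  iris[3:8, 3:18] <- TRUE
  pupil <- matrix(FALSE, h, w)
  pupil[12:17, 3:18] <- TRUE
  list(
    image = img,
    annotation = eye_annotation(image_id, species, iris, pupil)
  )
}

# default salient-pattern mapping, bypassing factor analysis
pattern_mapping <- function() {
  sol <- as_factor_solution(reference_loadings(2))
  suppressMessages(assign_items(sol))
}

# small rating table with perfectly known scores: every rater gives
# `dark_vals` / `light_vals` (named by item) to every stimulus
constant_ratings <- function(dark_vals, light_vals, n_raters = 4, n_images = 12) {
  items <- names(dark_vals)
  grid <- expand.grid(
    participant_id = seq_len(n_raters),
    image_id = seq_len(n_images),
    eye_colour = c("dark", "light"),
    stringsAsFactors = FALSE
  )
  vals <- t(vapply(grid$eye_colour,
                   function(ec) if (ec == "dark") dark_vals else light_vals,
                   numeric(length(items))))
  colnames(vals) <- items
  cbind(grid, as.data.frame(vals))
}

# items drawn from a known 2-factor model without the design machinery:
# returns the item matrix only (continuous latent, discretized like the
# generator), for factor-analysis unit tests
quick_factor_data <- function(n, loadings, seed) {
  with_seed <- canideye:::with_seed
  with_seed(seed, {
    f <- matrix(stats::rnorm(n * 2), n, 2)
    uniq <- pmax(1 - rowSums(loadings^2), 0.05)
    x <- f %*% t(loadings) +
      matrix(stats::rnorm(n * nrow(loadings)), n) %*% diag(sqrt(uniq))
    colnames(x) <- rownames(loadings)
    x
  })
}

pattern_loadings_matrix <- function() {
  ref <- reference_loadings(2)
  L <- matrix(0, nrow(ref), 2, dimnames = list(ref$item, NULL))
  for (i in seq_len(nrow(ref))) {
    j <- which.max(abs(c(ref$factor1[i], ref$factor2[i])))
    L[i, j] <- c(ref$factor1[i], ref$factor2[i])[j]
  }
  L
}
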