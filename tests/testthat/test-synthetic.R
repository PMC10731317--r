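# eye renderer, counterbalanced design, latent rating generator

test_that("render_eye is deterministic and self-consistent without noise", {
  spec <- synthetic_eye_spec(
    width = 64, height = 64, iris_lab = c(55, 8, 35), pupil_lab = c(14, 4, 8),
    noise_sd = 0
  )
  r1 <- render_eye(spec, seed = 5)
  r2 <- render_eye(spec, seed = 5)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$image, r2$image)

  lab <- srgb_to_lab(r1$image)
  rm <- region_mean(lab, r1$annotation)
  expect_equal(unlist(rm[rm$region == "iris", c("L", "a", "b")]),
               c(55, 8, 35), tolerance = 1, ignore_attr = TRUE)
  expect_equal(unlist(rm[rm$region == "pupil", c("L", "a", "b")]),
               c(14, 4, 8), tolerance = 1, ignore_attr = TRUE)
})

test_that("render_eye noise is seed-deterministic and masks never change", {
  spec <- synthetic_eye_spec(noise_sd = 0.02)
  a <- render_eye(spec, seed = 1)
  b <- render_eye(spec, seed = 1)
  c <- render_eye(spec, seed = 2)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c$image))
  expect_identical(a$labels, c$labels)
})

test_that("the specular disc covers ~ pi r^2 pixels and is excludable", {
  r <- 4.5
  spec <- synthetic_eye_spec(
    width = 64, height = 64,
    highlight = list(centre = c(31.5, 31.5), radius = r), noise_sd = 0
  )
  out <- render_eye(spec, seed = 1)
  area <- sum(out$labels == 3L)
  expect_lt(abs(area - pi * r^2), 0.15 * pi * r^2 + 2)
  # exclusion via the emitted highlight mask removes exactly those pixels
  lab <- srgb_to_lab(out$image)
  before <- sum(out$annotation$pupil_mask)
  ann <- exclude_highlights(lab, out$annotation, threshold = 101)
  expect_equal(before, sum(ann$pupil_mask)) # highlight already separated in labels
  # and the L-threshold path removes the white disc when it is unlabelled
  ann2 <- eye_annotation(spec$image_id, "dog",
                         out$annotation$iris_mask,
                         out$annotation$pupil_mask | (out$labels == 3L))
  ann2x <- exclude_highlights(lab, ann2, threshold = 95)
  expect_lt(abs(sum(ann2$pupil_mask) - sum(ann2x$pupil_mask) - area), area * 0.3 + 3)
})

test_that("gamut violations and invalid geometry are rejected", {
  expect_error(synthetic_eye_spec(iris_lab = c(50, 120, 0)), class = "gamut_error")
  expect_error(synthetic_eye_spec(pupil_axes = c(30, 30), iris_axes = c(20, 20)),
               class = "format_error")
})

test_that("wolf-like eyes have stronger L contrast than dog-like eyes", {
  wolf <- synthetic_eye_spec(iris_lab = c(62, 5, 35), pupil_lab = c(12, 4, 8),
                             species = "wolf")
  dog <- synthetic_eye_spec(iris_lab = c(35, 15, 22), pupil_lab = c(12, 4, 8),
                            species = "dog")
  expect_gt(abs(render_eye(wolf)$analytic$c_L), abs(render_eye(dog)$analytic$c_L))
})

test_that("sampled cohorts are reproducible and respect the group sizes", {
  s1 <- sample_eye_specs(n_wolf = 5, n_dog = 7, seed = 9, size = 40)
  s2 <- sample_eye_specs(n_wolf = 5, n_dog = 7, seed = 9, size = 40)
  expect_equal(s1, s2)
  expect_equal(sum(vapply(s1, `[[`, "", "species") == "wolf"), 5)
  expect_true(all(vapply(s1, function(s) lab_in_gamut(s$iris_lab), logical(1))))
})

test_that("generated designs satisfy the counterbalancing invariants", {
  for (seed in 1:20) {
    d <- generate_design(n_participants = 4 + seed, seed = seed)
    v <- d$versions
    expect_equal(nrow(v), 24)
    # each stimulus exactly once across the four versions
    expect_false(any(duplicated(v[, c("image_id", "eye_colour")])))
    for (ver in c("A", "B", "C", "D")) {
      sub <- v[v$version == ver, ]
      expect_equal(nrow(sub), 6)
      expect_equal(sum(sub$eye_colour == "dark"), 3)
      expect_equal(sum(sub$eye_colour == "light"), 3)
      expect_false(any(duplicated(sub$image_id))) # never the same dog twice
    }
  }
  d4 <- generate_design(4, seed = 1)
  expect_equal(sort(table(d4$participants$version)), sort(c(A = 1, B = 1, C = 1, D = 1)),
               ignore_attr = TRUE)
  expect_error(generate_design(3), class = "sample_size_error")
})

test_that("the reference cohort size yields 456 rating rows", {
  design <- generate_design(76, seed = 2)
  ratings <- generate_ratings(design, rating_model_spec(seed = 3))
  expect_equal(nrow(ratings), 456)
  expect_true(all(ratings$interact %in% 0:3))
  expect_true(all(ratings$keep %in% 0:3))
  items <- reference_loadings(2)$item
  expect_true(all(as.matrix(ratings[, items]) %in% 0:5))
})

test_that("a fully degenerate model gives identical responses per stimulus", {
  design <- generate_design(8, seed = 4)
  model <- rating_model_spec(
    delta_f = 0, delta_m = 0, image_sd = c(0, 0), participant_sd = c(0, 0),
    uniqueness = rep(0, 10), accept_image_sd = 0, accept_resid_sd = 0, seed = 5
  )
  ratings <- generate_ratings(design, model)
  items <- reference_loadings(2)$item
  per_stim <- split(ratings[, c(items, "interact", "keep")],
                    paste(ratings$image_id, ratings$eye_colour))
  for (chunk in per_stim) {
    expect_true(all(vapply(chunk, function(col) length(unique(col)) == 1L, logical(1))))
  }
})

test_that("marginal item SDs stay in [0.5, 1.5] under the default calibration", {
  design <- generate_design(76, seed = 6)
  ratings <- generate_ratings(design, rating_model_spec(seed = 7))
  items <- reference_loadings(2)$item
  sds <- vapply(ratings[, items], sd, numeric(1))
  expect_true(all(sds > 0.5 & sds < 1.5))
})

test_that("the dark-light score gap tracks the discretization-mapped shift", {
  # mapped shift = mean |salient loading| x delta_f on the 0-5 scale
  model <- rating_model_spec(seed = 1)
  lam_f <- mean(abs(model$loadings[model$loadings[, 1] != 0, 1]))
  target <- lam_f * model$delta_f
  gaps <- vapply(1:5, function(s) {
    design <- generate_design(76, seed = 70 + s)
    ratings <- generate_ratings(design, rating_model_spec(seed = 80 + s))
    sc <- suppressMessages(scale_scores(ratings, pattern_mapping()))
    mean(sc$friendliness[sc$eye_colour == "dark"]) -
      mean(sc$friendliness[sc$eye_colour == "light"])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - target), 0.15)
})

test_that("paired tests recover the generating direction", {
  hits <- vapply(1:10, function(s) {
    design <- generate_design(76, seed = 300 + s)
    ratings <- generate_ratings(design, rating_model_spec(seed = 400 + s))
    sc <- suppressMessages(scale_scores(ratings, pattern_mapping()))
    pf <- paired_eye_colour_test(sc, "friendliness")
    pm <- paired_eye_colour_test(sc, "maturity")
    (pf$t > 0 && pf$p < 0.05) && (pm$t < 0)
  }, logical(1))
  expect_gte(sum(hits), 10 * 0.95 - 0.5) # >= 10/10 at these frozen seeds
})

test_that("acceptance generator: friendliness drives the LMM, eye colour does not", {
  model <- rating_model_spec(
    accept_coefs = list(
      interact = c(intercept = 0.85, eye = 0, friendliness = 0.3, maturity = 0),
      keep = c(intercept = 0.5, eye = 0, friendliness = 0.3, maturity = 0)
    ),
    seed = 11
  )
  ok <- vapply(1:10, function(s) {
    design <- generate_design(76, seed = 500 + s)
    m <- model
    m$seed <- 600 + s
    ratings <- generate_ratings(design, m)
    fit <- suppressMessages(fit_acceptance_lmm(ratings, "interact", pattern_mapping()))
    fr <- fit[fit$term == "friendliness", ]
    eye <- fit[fit$term == "eye colour", ]
    (fr$ci_lo <= 0.3 && 0.3 <= fr$ci_hi) && eye$p > 0.05
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("end-to-end: rendered cohorts detect the species L difference", {
  hits <- vapply(1:10, function(s) {
    specs <- sample_eye_specs(n_wolf = 22, n_dog = 81, seed = 900 + s, size = 56)
    renders <- lapply(seq_along(specs), function(k) render_eye(specs[[k]], seed = s * 1000 + k))
    ct <- contrast_table(lapply(renders, `[[`, "image"),
                         lapply(renders, `[[`, "annotation"))
    res <- compare_species(ct)
    res$p[res$channel == "L"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})
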