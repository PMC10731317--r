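# paired eye-colour tests, MANOVA, acceptance LMM

make_scale_table <- function(dark, light, scale = "friendliness") {
  n <- length(dark)
  out <- data.frame(
    image_id = rep(seq_len(n), 2),
    eye_colour = rep(c("dark", "light"), each = n),
    friendliness = NA_real_, maturity = NA_real_,
    n_raters = 5
  )
  out[[scale]] <- c(dark, light)
  out
}

test_that("paired test matches the hand-derived closed form", {
  # diffs (1,1,2): mean 4/3, sd sqrt(1/3), t = 4 on 2 df
  pt <- paired_eye_colour_test(make_scale_table(c(3, 4, 6), c(2, 3, 4)))
  expect_equal(pt$t, 4, tolerance = 1e-12)
  expect_equal(pt$df, 2L)
  expect_equal(pt$d, (4 / 3) / sqrt(1 / 3), tolerance = 1e-12)

  # dark identical to light for every image: t = 0, p = 1
  null <- paired_eye_colour_test(make_scale_table(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)
})

test_that("paired test equals a one-sample t on the differences (oracle)", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(3:15, 1)
    dark <- rnorm(n, 3, 1)
    light <- dark - rnorm(n, 0.5, 0.7)
    pt <- paired_eye_colour_test(make_scale_table(dark, light))
    o <- t.test(dark - light)
    expect_equal(pt$t, unname(o$statistic), tolerance = 1e-10)
    expect_equal(pt$p, o$p.value, tolerance = 1e-10)
    expect_equal(pt$ci, as.numeric(o$conf.int), tolerance = 1e-10)
  }
})

test_that("the full 12-image design gives df = 11 and errors are raised", {
  set.seed(3)
  tbl <- make_scale_table(rnorm(12, 3), rnorm(12, 2.5))
  expect_equal(paired_eye_colour_test(tbl)$df, 11L)
  expect_error(paired_eye_colour_test(tbl[-1, ]), class = "pairing_error")
  expect_error(paired_eye_colour_test(tbl[-1, ]), "1")
  const <- make_scale_table(c(3, 3, 3), c(2, 2, 2))
  expect_error(paired_eye_colour_test(const), class = "degenerate_data_error")
})

test_that("item_manova: exact null when groups are duplicated", {
  items <- reference_loadings(2)$item
  vals <- stats::setNames(sample(0:5, 10, replace = TRUE), items)
  ratings <- constant_ratings(vals, vals, n_raters = 3)
  # identical group means: zero between-group SSP, with within-group spread
  set.seed(8)
  jitter_rows <- matrix(sample(c(-1, 0, 1), nrow(ratings) * 10, TRUE),
                        nrow(ratings))
  half <- nrow(ratings) / 2
  jitter_rows[(half + 1):nrow(ratings), ] <- jitter_rows[1:half, ]
  ratings[, items] <- pmin(pmax(as.matrix(ratings[, items]) + jitter_rows, 0), 5)
  res <- item_manova(ratings)
  expect_lt(res$pillai, 1e-10)
  expect_gt(res$p, 0.999)
})

test_that("item_manova flags a single shifted item at n = 456", {
  design <- generate_design(76, seed = 41)
  model <- rating_model_spec(delta_f = 0, delta_m = 0, seed = 42)
  ratings <- generate_ratings(design, model)
  shift <- 2 * sd(ratings$kind)
  ratings$kind <- pmin(ratings$kind + round(shift) * (ratings$eye_colour == "dark"), 5)
  res <- item_manova(ratings)
  uni <- res$univariate
  expect_lt(uni$p[uni$item == "kind"], 1e-3)
  expect_equal(uni$direction[uni$item == "kind"], "dark > light")
  expect_gt(min(uni$p[uni$item != "kind"]), 0.001)
  expect_true(res$pillai >= 0 && res$pillai <= 1)
})

test_that("one response variable reduces the MANOVA to the univariate ANOVA", {
  design <- generate_design(16, seed = 43)
  ratings <- generate_ratings(design, rating_model_spec(seed = 44))
  res <- item_manova(ratings, items = "friendly")
  a <- stats::anova(stats::lm(friendly ~ factor(eye_colour, c("light", "dark")),
                              data = ratings))
  expect_equal(res$approx_f, a[["F value"]][1], tolerance = 1e-8)
  expect_equal(res$p, a[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("LMM with boundary random variance reduces to least squares", {
  # zero true image variance; pick a seed where REML lands on the boundary
  design <- generate_design(40, seed = 51)
  model <- rating_model_spec(accept_image_sd = 0, seed = 151)
  ratings <- generate_ratings(design, model)
  map <- pattern_mapping()
  fit <- suppressMessages(fit_acceptance_lmm(ratings, "interact", map))
  expect_true(isTRUE(attr(fit, "singular"))) # frozen seed lands on the boundary
  r <- suppressMessages(rater_scale_scores(ratings, map))
  ols <- stats::lm(interact ~ factor(eye_colour, c("light", "dark")) +
                     friendliness + maturity, data = r)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("doubling the response doubles beta and leaves Wald chi-square fixed", {
  design <- generate_design(24, seed = 53)
  ratings <- generate_ratings(design, rating_model_spec(seed = 54))
  map <- pattern_mapping()
  f1 <- suppressMessages(fit_acceptance_lmm(ratings, "interact", map))
  ratings$interact <- 2 * ratings$interact
  f2 <- suppressMessages(fit_acceptance_lmm(ratings, "interact", map))
  expect_equal(f2$beta, 2 * f1$beta, tolerance = 1e-6)
  expect_equal(f2$wald_chi2, f1$wald_chi2, tolerance = 1e-6)
})

test_that("Type III equals Type I on a balanced orthogonal design", {
  # covariate values repeated identically in the two eye groups, so the eye
  # contrast is orthogonal to both covariates; no image structure in y, so
  # the REML random-intercept variance sits at the boundary and the fit is
  # ordinary least squares. Then the marginal (Type III) Wald chi-square
  # equals the sequential (Type I) F with eye entered first.
  design <- generate_design(24, seed = 2)
  rows <- merge(design$participants, design$versions, by = "version")
  rows <- rows[order(rows$eye_colour, rows$participant_id, rows$image_id), ]
  n <- nrow(rows)
  per_group <- n / 2
  fvals <- seq(1, 4, length.out = per_group)
  mvals <- rev(fvals)
  f_cov <- rep(fvals, 2) # identical in both groups -> orthogonal to eye
  m_cov <- rep(mvals, 2)
  items <- reference_loadings(2)$item
  ratings <- data.frame(
    participant_id = rows$participant_id, image_id = rows$image_id,
    eye_colour = rows$eye_colour
  )
  for (it in c("sociable", "kind", "friendly", "easygoing")) ratings[[it]] <- f_cov
  ratings$aggressive <- 5 - f_cov # reversed back to f_cov when scoring
  for (it in c("trustworthy", "confident", "independent", "intelligent", "mature")) {
    ratings[[it]] <- m_cov
  }
  y <- canideye:::with_seed(1002,
    1 + 0.4 * (ratings$eye_colour == "dark") + 0.3 * f_cov + rnorm(n, 0, 0.5))
  ratings$interact <- y
  map <- pattern_mapping()
  fit <- suppressMessages(fit_acceptance_lmm(ratings, "interact", map))
  expect_true(isTRUE(attr(fit, "singular"))) # frozen seed lands on the boundary
  ols <- stats::lm(y ~ factor(rows$eye_colour, c("light", "dark")) + f_cov + m_cov)
  seq_f <- stats::anova(ols)[["F value"]][1] # Type I, eye first
  expect_equal(fit$wald_chi2[fit$term == "eye colour"], seq_f, tolerance = 1e-6)
})

test_that("optional LR tests accompany the Wald tests", {
  design <- generate_design(24, seed = 57)
  ratings <- generate_ratings(design, rating_model_spec(seed = 58))
  map <- pattern_mapping()
  fit <- suppressMessages(fit_acceptance_lmm(ratings, "keep", map, lrt = TRUE))
  expect_true(all(c("lrt_chi2", "lrt_p") %in% names(fit)))
  got <- fit[fit$term == "friendliness", ]
  expect_gt(got$lrt_chi2, 0)
  # Wald and LR agree on the strongly identified friendliness term
  expect_lt(abs(got$lrt_chi2 - got$wald_chi2) / got$wald_chi2, 0.5)
  expect_error(fit_acceptance_lmm(ratings, "nope", map), "arg")
})

test_that("stimulus-level covariates are available and logged", {
  design <- generate_design(24, seed = 59)
  ratings <- generate_ratings(design, rating_model_spec(seed = 60))
  map <- pattern_mapping()
  f_r <- suppressMessages(fit_acceptance_lmm(ratings, "interact", map, covariate_level = "rater"))
  f_s <- suppressMessages(fit_acceptance_lmm(ratings, "interact", map, covariate_level = "stimulus"))
  expect_equal(attr(f_s, "covariate_level"), "stimulus")
  expect_false(isTRUE(all.equal(f_r$beta[3], f_s$beta[3])))
})
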