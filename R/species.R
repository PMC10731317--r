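# Study-1 statistics: Welch two-sample comparison of contrast values between
# wolves and dogs, with a standardized effect size. The closed forms are
# written out (Welch-Satterthwaite df, pooled-SD Cohen's d); stats::t.test is
# used as an independent oracle in the tests only.

#' Welch's two-sample t-test
#'
#' @param group_a,group_b numeric vectors (>= 2 finite values each; NAs are
#'   dropped). The difference is `mean(group_a) - mean(group_b)`.
#' @param conf confidence level for the mean-difference CI.
#' @return An object of class `welch_result`: `t`, `df`
#'   (Welch-Satterthwaite, real-valued), `p` (two-sided), `ci`,
#'   `mean_diff`, `n`.
#' @export
welch_t <- function(group_a, group_b, conf = 0.95) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    ce_stop("sample_size_error", "each group needs at least 2 finite values")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    ce_stop("degenerate_data_error", "zero variance in both groups")
  }
  na <- length(a)
  nb <- length(b)
  sa2 <- va / na
  sb2 <- vb / nb
  se <- sqrt(sa2 + sb2)
  df <- (sa2 + sb2)^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
  diff <- mean(a) - mean(b)
  t <- diff / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  q <- stats::qt(1 - (1 - conf) / 2, df)
  structure(
    list(
      t = t, df = df, p = p,
      ci = c(diff - q * se, diff + q * se),
      mean_diff = diff, n = c(na, nb), conf = conf
    ),
    class = "welch_result"
  )
}

#' @method print welch_result
#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf(
    "Welch t = %.3f, d.f. = %.3f, p = %.4g, %g%%CI [%.3f, %.3f] (n = %d, %d)\n",
    x$t, x$df, x$p, 100 * x$conf, x$ci[1], x$ci[2], x$n[1], x$n[2]
  ))
  invisible(x)
}

#' Cohen's d with confidence interval
#'
#' Pooled-SD standardized mean difference `mean(a) - mean(b)` divided by the
#' pooled standard deviation. The CI uses the large-sample standard error
#' `sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2-2)))` with either a t quantile on
#' `n1+n2-2` df (default; reproduces the symmetric CIs conventionally
#' reported with this design) or a normal quantile.
#'
#' @inheritParams welch_t
#' @param ci_method `"t"` or `"normal"` quantile for the CI.
#' @return List with `d`, `ci`, `se`, `n`.
#' @export
cohens_d <- function(group_a, group_b, conf = 0.95, ci_method = c("t", "normal")) {
  ci_method <- match.arg(ci_method)
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    ce_stop("sample_size_error", "each group needs at least 2 finite values")
  }
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) ce_stop("degenerate_data_error", "pooled standard deviation is zero")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
  q <- switch(ci_method,
    t = stats::qt(1 - (1 - conf) / 2, na + nb - 2),
    normal = stats::qnorm(1 - (1 - conf) / 2)
  )
  list(d = d, ci = c(d - q * se, d + q * se), se = se, n = c(na, nb))
}

#' Species comparison of iris-pupil contrast
#'
#' Welch's t-test and Cohen's d per colour channel (L, A, B), dogs minus
#' wolves, with no multiplicity adjustment. Rows whose channel was flagged
#' undefined are dropped listwise per channel with a logged count.
#'
#' @param contrasts data frame from [contrast_table()] (needs `species`,
#'   `c_L`, `c_A`, `c_B`).
#' @param conf confidence level.
#' @param ci_method passed to [cohens_d()].
#' @return Data frame with one row per channel: sample sizes, dropped
#'   counts, group means, Welch `t`/`df`/`p`, mean-difference CI, `d` and
#'   its CI, and the direction of the dog-wolf difference.
#' @export
compare_species <- function(contrasts, conf = 0.95, ci_method = "t") {
  if (!all(c("wolf", "dog") %in% contrasts$species)) {
    ce_stop("grouping_error", "both species must be present, got: %s",
            paste(unique(contrasts$species), collapse = ", "))
  }
  rows <- lapply(c(c_L = "L", c_A = "A", c_B = "B"), function(ch) ch)
  out <- lapply(names(rows), function(col) {
    x <- contrasts[[col]]
    dog <- x[contrasts$species == "dog"]
    wolf <- x[contrasts$species == "wolf"]
    dropped <- sum(!is.finite(dog)) + sum(!is.finite(wolf))
    if (dropped > 0) {
      message(sprintf("channel %s: dropped %d undefined value(s)", rows[[col]], dropped))
    }
    wt <- welch_t(dog[is.finite(dog)], wolf[is.finite(wolf)], conf = conf)
    ds <- cohens_d(dog[is.finite(dog)], wolf[is.finite(wolf)], conf = conf,
                   ci_method = ci_method)
    data.frame(
      channel = rows[[col]],
      n_dog = wt$n[1], n_wolf = wt$n[2], n_dropped = dropped,
      mean_dog = mean(dog, na.rm = TRUE), mean_wolf = mean(wolf, na.rm = TRUE),
      t = wt$t, df = wt$df, p = wt$p,
      ci_lo = wt$ci[1], ci_hi = wt$ci[2],
      d = ds$d, d_lo = ds$ci[1], d_hi = ds$ci[2],
      direction = if (wt$mean_diff > 0) "dog > wolf" else "dog < wolf",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
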