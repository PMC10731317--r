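# Eye-colour effects on the personality scales and the acceptance-attitude
# mixed models. The paired t closed form is authored; the MANOVA uses
# stats::manova (Pillai's trace) and the LMM uses lme4 with REML, with
# Type III Wald chi-square tests per fixed term (each term here has 1 df, so
# the Type III Wald chi-square is (beta/se)^2 adjusted for all other terms).

#' Paired eye-colour test on a scale score
#'
#' Paired t-test of dark vs light stimulus means of the same dog images.
#' The difference is dark minus light; paired Cohen's d is
#' `mean(diff)/sd(diff)` with a CI from
#' `se = sqrt(1/n + d^2 / (2 (n - 1)))` and a t quantile on n-1 df.
#'
#' @param scale_table output of [scale_scores()].
#' @param scale `"friendliness"` or `"maturity"`.
#' @param conf confidence level.
#' @return Object of class `paired_test`: `t`, `df` (pairs - 1), `p`, `ci`
#'   of the mean paired difference, `d`, `d_ci`, `mean_diff`, `n_pairs`.
#' @export
paired_eye_colour_test <- function(scale_table, scale = c("friendliness", "maturity"),
                                   conf = 0.95) {
  scale <- match.arg(scale)
  dark <- scale_table[scale_table$eye_colour == "dark", c("image_id", scale)]
  light <- scale_table[scale_table$eye_colour == "light", c("image_id", scale)]
  ids <- union(dark$image_id, light$image_id)
  incomplete <- ids[!(ids %in% dark$image_id & ids %in% light$image_id)]
  if (length(incomplete)) {
    ce_stop("pairing_error", "image(s) missing one eye colour: %s",
            paste(incomplete, collapse = ", "))
  }
  m <- merge(dark, light, by = "image_id", suffixes = c("_dark", "_light"))
  diffs <- m[[paste0(scale, "_dark")]] - m[[paste0(scale, "_light")]]
  n <- length(diffs)
  if (n < 2L) ce_stop("sample_size_error", "need at least 2 complete pairs")
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    if (all(diffs == 0)) {
      # dark identical to light everywhere: a true null, not an error
      return(structure(
        list(scale = scale, t = 0, df = n - 1L, p = 1, ci = c(0, 0),
             d = 0, d_ci = c(0, 0), mean_diff = 0, n_pairs = n, conf = conf),
        class = "paired_test"
      ))
    }
    ce_stop("degenerate_data_error", "zero variance of paired differences")
  }
  mdiff <- mean(diffs)
  se <- sdd / sqrt(n)
  t <- mdiff / se
  df <- n - 1L
  q <- stats::qt(1 - (1 - conf) / 2, df)
  d <- mdiff / sdd
  d_se <- sqrt(1 / n + d^2 / (2 * (n - 1)))
  structure(
    list(
      scale = scale, t = t, df = df,
      p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
      ci = c(mdiff - q * se, mdiff + q * se),
      d = d, d_ci = c(d - q * d_se, d + q * d_se),
      mean_diff = mdiff, n_pairs = n, conf = conf
    ),
    class = "paired_test"
  )
}

#' @method print paired_test
#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t (%s, dark - light): t = %.3f, d.f. = %d, p = %.4g, %g%%CI [%.3f, %.3f], d = %.3f\n",
    x$scale, x$t, x$df, x$p, 100 * x$conf, x$ci[1], x$ci[2], x$d
  ))
  invisible(x)
}

#' MANOVA of the personality items on eye colour
#'
#' One-way MANOVA (Pillai's trace) of the item responses on eye colour,
#' with unadjusted univariate follow-up F tests per item.
#'
#' @param ratings rating table with `eye_colour` and the item columns.
#' @param items item column names (default the ten personality items).
#' @return List: `pillai`, `approx_f`, `df` (numerator, denominator), `p`,
#'   and `univariate` (data frame item, F, p, direction of the dark - light
#'   mean difference).
#' @export
item_manova <- function(ratings, items = PERSONALITY_ITEMS) {
  if (!all(c("dark", "light") %in% ratings$eye_colour)) {
    ce_stop("grouping_error", "both eye-colour groups must be present")
  }
  if (nrow(ratings) < length(items) + 2L) {
    ce_stop("sample_size_error", "need at least items + 2 rows")
  }
  Y <- .item_matrix(ratings, items)
  g <- factor(ratings$eye_colour, levels = c("light", "dark"))
  if (length(items) == 1L) {
    # single response: Pillai = SSB/(SSB+SSW) and the approx F is the ANOVA F
    a <- stats::anova(stats::lm(Y[, 1] ~ g))
    uni_tab <- data.frame(
      item = items, F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
      mean_dark = mean(Y[g == "dark", 1]), mean_light = mean(Y[g == "light", 1]),
      stringsAsFactors = FALSE
    )
    uni_tab$direction <- ifelse(uni_tab$mean_dark > uni_tab$mean_light,
                                "dark > light", "dark < light")
    return(list(
      pillai = a[["Sum Sq"]][1] / sum(a[["Sum Sq"]]),
      approx_f = a[["F value"]][1],
      df = c(num = a$Df[1], den = a$Df[2]),
      p = a[["Pr(>F)"]][1],
      univariate = uni_tab
    ))
  }
  fit <- tryCatch(
    stats::manova(Y ~ g),
    error = function(e) ce_stop("rank_error", "singular within-group covariance; consider removing an item (%s)", conditionMessage(e))
  )
  s <- summary(fit, test = "Pillai")$stats
  uni <- summary.aov(fit)
  uni_tab <- do.call(rbind, lapply(seq_along(items), function(j) {
    a <- uni[[j]]
    data.frame(
      item = items[j],
      F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
      mean_dark = mean(Y[g == "dark", j]),
      mean_light = mean(Y[g == "light", j]),
      stringsAsFactors = FALSE
    )
  }))
  uni_tab$direction <- ifelse(uni_tab$mean_dark > uni_tab$mean_light,
                              "dark > light", "dark < light")
  list(
    pillai = s["g", "Pillai"],
    approx_f = s["g", "approx F"],
    df = c(num = s["g", "num Df"], den = s["g", "den Df"]),
    p = s["g", "Pr(>F)"],
    univariate = uni_tab
  )
}

#' Acceptance-attitude linear mixed model
#'
#' Gaussian LMM of an acceptance rating (0-3) on eye colour and the
#' friendliness/maturity scale scores, with a random intercept per dog
#' image, fitted by REML. Covariates are each rater's own scale scores for
#' that stimulus by default (`covariate_level = "rater"`), or the
#' stimulus-level mean scores (`"stimulus"`). Each fixed term gets a
#' Type III Wald chi-square on 1 df and a Wald 95% CI; an optional
#' likelihood-ratio test per term is available for comparison.
#'
#' @param ratings rating table (one row per participant x stimulus) with
#'   the response column, `eye_colour`, `image_id` and the item columns.
#' @param response `"interact"` or `"keep"`.
#' @param mapping item-to-scale mapping from [assign_items()].
#' @param covariate_level `"rater"` or `"stimulus"`.
#' @param conf confidence level for the Wald CIs.
#' @param lrt also compute a likelihood-ratio test per term (ML refits).
#' @return Data frame of class `lmm_terms`: one row per fixed term with
#'   `beta`, `ci_lo`, `ci_hi`, `wald_chi2`, `df`, `p` (and `lrt_chi2`,
#'   `lrt_p` when requested). Attributes: `singular` flag, `ranef_sd`,
#'   `resid_sd`, `covariate_level`.
#' @export
fit_acceptance_lmm <- function(ratings, response = c("interact", "keep"),
                               mapping, covariate_level = c("rater", "stimulus"),
                               conf = 0.95, lrt = FALSE) {
  response <- match.arg(response)
  covariate_level <- match.arg(covariate_level)
  if (!response %in% names(ratings)) {
    ce_stop("format_error", "response column '%s' not found", response)
  }
  r <- suppressMessages(rater_scale_scores(ratings, mapping))
  if (covariate_level == "stimulus") {
    st <- scale_scores(ratings, mapping, n_images = NULL)
    r$friendliness <- st$friendliness[match(paste(r$image_id, r$eye_colour),
                                            paste(st$image_id, st$eye_colour))]
    r$maturity <- st$maturity[match(paste(r$image_id, r$eye_colour),
                                    paste(st$image_id, st$eye_colour))]
  }
  dat <- data.frame(
    y = r[[response]],
    eye_colour = factor(r$eye_colour, levels = c("light", "dark")),
    friendliness = r$friendliness,
    maturity = r$maturity,
    image_id = factor(r$image_id)
  )
  fit <- lme4::lmer(y ~ eye_colour + friendliness + maturity + (1 | image_id),
                    data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  if (singular) {
    message("random-intercept variance estimated at the boundary (0); fixed effects equal ordinary least squares")
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  wald <- (beta / se)^2
  q <- stats::qnorm(1 - (1 - conf) / 2)
  terms <- c("(Intercept)", "eye_colourdark", "friendliness", "maturity")
  labels <- c("(intercept)", "eye colour", "friendliness", "maturity")
  out <- data.frame(
    term = labels,
    beta = beta[terms], ci_lo = beta[terms] - q * se[terms],
    ci_hi = beta[terms] + q * se[terms],
    wald_chi2 = wald[terms], df = 1L,
    p = stats::pchisq(wald[terms], df = 1L, lower.tail = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (lrt) {
    full_ml <- stats::update(fit, REML = FALSE)
    drops <- list(
      "eye colour" = . ~ . - eye_colour,
      "friendliness" = . ~ . - friendliness,
      "maturity" = . ~ . - maturity
    )
    out$lrt_chi2 <- NA_real_
    out$lrt_p <- NA_real_
    for (nm in names(drops)) {
      red <- stats::update(full_ml, drops[[nm]])
      an <- stats::anova(red, full_ml)
      out$lrt_chi2[out$term == nm] <- an$Chisq[2]
      out$lrt_p[out$term == nm] <- an[["Pr(>Chisq)"]][2]
    }
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(out, "singular") <- singular
  attr(out, "ranef_sd") <- vc$sdcor[vc$grp == "image_id"]
  attr(out, "resid_sd") <- vc$sdcor[vc$grp == "Residual"]
  attr(out, "covariate_level") <- covariate_level
  attr(out, "response") <- response
  class(out) <- c("lmm_terms", "data.frame")
  out
}
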