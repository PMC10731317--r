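# Factor structure of the ten personality items and scale construction.
# Extraction is maximum-likelihood (stats::factanal) with varimax rotation
# and Kaiser normalization; factor retention is Horn's parallel analysis,
# authored here (observed correlation eigenvalues against eigenvalues of
# i.i.d. normal data of identical shape).

PERSONALITY_ITEMS <- c(
  "aggressive", "easygoing", "friendly", "kind", "sociable",
  "confident", "independent", "intelligent", "mature", "trustworthy"
)

FRIENDLINESS_MARKERS <- c("sociable", "kind", "friendly")

#' Published two-factor reference loading pattern
#'
#' The package's canonical ten-item two-factor structure (friendliness /
#' maturity), used as the default generator pattern and as a fixture for the
#' variance-explained identity.
#'
#' @param study 2 (printed questionnaire cohort) or 3 (online replication).
#' @return Data frame: `item`, `factor1`, `factor2`, `h2`.
#' @export
reference_loadings <- function(study = 2) {
  stopifnot(study %in% c(2, 3))
  path <- system.file("extdata", "reference_loadings.csv", package = "canideye",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x <- x[x$study == study, c("item", "factor1", "factor2", "h2")]
  rownames(x) <- NULL
  x
}

.item_matrix <- function(x, items = PERSONALITY_ITEMS) {
  if (is.data.frame(x)) {
    missing <- setdiff(items, names(x))
    if (length(missing)) {
      ce_stop("format_error", "missing item columns: %s", paste(missing, collapse = ", "))
    }
    x <- as.matrix(x[, items])
  }
  storage.mode(x) <- "double"
  x
}

#' Horn's parallel analysis
#'
#' Compares eigenvalues of the observed item correlation matrix with the
#' criterion (mean or a quantile) of eigenvalues from `n_random` i.i.d.
#' standard-normal data sets of identical shape. The retained count is the
#' number of leading positions at which the observed eigenvalue exceeds the
#' criterion (stopping at the first failure).
#'
#' @param x numeric matrix or data frame of item responses (rows =
#'   observations).
#' @param n_random number of random comparison data sets.
#' @param quantile `NULL` for the classic mean criterion, or a probability
#'   (e.g. 0.95) for a percentile criterion.
#' @param seed RNG seed (the result is deterministic given the seed).
#' @return List: `n_factors`, `observed` eigenvalues, `criterion`
#'   eigenvalues.
#' @export
parallel_analysis <- function(x, n_random = 100, quantile = NULL, seed = 1) {
  m <- .item_matrix(x, items = if (is.data.frame(x)) intersect(PERSONALITY_ITEMS, names(x)) else NULL)
  if (is.data.frame(x)) m <- .item_matrix(x) # enforce canonical item order
  p <- ncol(m)
  n <- nrow(m)
  if (p < 3L) ce_stop("format_error", "need at least 3 items")
  if (n < 3L * p) ce_stop("sample_size_error", "need at least 3x as many rows as items")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    ce_stop("degenerate_item_error", "constant item column(s): %s",
            paste(colnames(m)[sds == 0], collapse = ", "))
  }
  obs <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  rand <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
            symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  crit <- if (is.null(quantile)) {
    rowMeans(rand)
  } else {
    apply(rand, 1L, stats::quantile, probs = quantile)
  }
  keep <- obs > crit
  n_factors <- if (keep[1]) which.min(c(keep, FALSE)) - 1L else 0L
  list(n_factors = n_factors, observed = obs, criterion = crit)
}

#' Maximum-likelihood factor analysis with varimax rotation
#'
#' ML extraction with orthogonal varimax rotation (Kaiser-normalized).
#' Factors are ordered by descending sum of squared loadings and each
#' factor's sign is fixed so its largest-magnitude loading is positive.
#'
#' @inheritParams parallel_analysis
#' @param n_factors number of factors to extract.
#' @return Object of class `factor_solution`: `loadings` (items x factors),
#'   `communalities` (h2, row sums of squared loadings), `ss_loadings`,
#'   `variance_explained` (total ss / number of items), `n_factors`,
#'   `heywood` flag.
#' @export
ml_factor_analysis <- function(x, n_factors) {
  m <- if (is.data.frame(x)) .item_matrix(x) else .item_matrix(x, items = NULL)
  R <- stats::cor(m)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    ce_stop("degenerate_data_error", "item correlation matrix is not positive definite")
  }
  fit <- stats::factanal(covmat = R, factors = n_factors, n.obs = nrow(m),
                         rotation = "varimax")
  L <- matrix(fit$loadings, nrow = ncol(m), ncol = n_factors,
              dimnames = list(colnames(m), NULL))
  heywood <- any(fit$uniquenesses <= 0.005 + 1e-12)
  if (heywood) warning("Heywood case: communality at/above 1 for at least one item")
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  colnames(L) <- paste0("factor", seq_len(ncol(L)))
  ss <- colSums(L^2)
  structure(
    list(
      n_factors = n_factors,
      loadings = L,
      communalities = rowSums(L^2),
      ss_loadings = ss,
      variance_explained = sum(ss) / ncol(m),
      heywood = heywood
    ),
    class = "factor_solution"
  )
}

#' @method print factor_solution
#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat(sprintf("<factor_solution> %d factors, variance explained %.3f\n",
              x$n_factors, x$variance_explained))
  print(round(cbind(x$loadings, h2 = x$communalities), digits))
  cat("sum of squared loadings:", paste(round(x$ss_loadings, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Build a factor_solution from a printed loadings table
#'
#' Used to feed fixture loadings (e.g. [reference_loadings()]) into
#' [assign_items()] and the variance-explained identity.
#'
#' @param loadings data frame with `item`, `factor1`, `factor2` columns.
#' @return A `factor_solution`.
#' @export
as_factor_solution <- function(loadings) {
  L <- as.matrix(loadings[, c("factor1", "factor2")])
  rownames(L) <- loadings$item
  ss <- colSums(L^2)
  structure(
    list(
      n_factors = ncol(L), loadings = L,
      communalities = rowSums(L^2), ss_loadings = ss,
      variance_explained = sum(ss) / nrow(L), heywood = FALSE
    ),
    class = "factor_solution"
  )
}

#' Assign items to scales by salient loadings
#'
#' Each item is mapped to the factor on which its absolute loading reaches
#' `threshold`; the keying direction is the sign of that loading. The factor
#' capturing the sociable/kind/friendly block is labelled `friendliness`,
#' the other `maturity`. Items salient on neither factor are dropped with a
#' warning; an error is raised only when no item is salient, and an item
#' salient on both factors is a cross-loading error.
#'
#' @param solution a two-factor `factor_solution`.
#' @param threshold salient-loading cutoff (default 0.4).
#' @return Data frame `item`, `scale`, `keying` (+1/-1).
#' @export
assign_items <- function(solution, threshold = 0.4) {
  stopifnot(inherits(solution, "factor_solution"))
  if (solution$n_factors != 2L) {
    ce_stop("format_error", "item assignment requires a two-factor solution")
  }
  L <- solution$loadings
  salient <- abs(L) >= threshold
  cross <- rowSums(salient) > 1L
  if (any(cross)) {
    ce_stop("cross_loading_error", "item(s) load on both factors: %s",
            paste(rownames(L)[cross], collapse = ", "))
  }
  none <- rowSums(salient) == 0L
  if (all(none)) ce_stop("empty_mapping_error", "no item reaches the loading threshold")
  if (any(none)) {
    warning(sprintf("dropping item(s) salient on neither factor: %s",
                    paste(rownames(L)[none], collapse = ", ")))
    L <- L[!none, , drop = FALSE]
    salient <- salient[!none, , drop = FALSE]
  }
  factor_of <- apply(salient, 1L, which)
  marker_factor <- unique(factor_of[intersect(FRIENDLINESS_MARKERS, rownames(L))])
  if (length(marker_factor) != 1L) {
    ce_stop("cross_loading_error", "friendliness marker items split across factors")
  }
  labels <- if (marker_factor == 1L) c("friendliness", "maturity") else c("maturity", "friendliness")
  data.frame(
    item = rownames(L),
    scale = labels[factor_of],
    keying = ifelse(L[cbind(seq_len(nrow(L)), factor_of)] >= 0, 1L, -1L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-rater scale scores
#'
#' Negatively keyed items are reversed (x -> max_score - x) before
#' averaging; this is the reading of "averaging" items that load negatively
#' and is logged once per call.
#'
#' @param ratings rating table with one row per participant x stimulus and
#'   the ten item columns.
#' @param mapping item-to-scale mapping from [assign_items()].
#' @param max_score top of the item scale (default 5).
#' @return `ratings` with `friendliness` and `maturity` columns appended.
#' @export
rater_scale_scores <- function(ratings, mapping, max_score = 5) {
  missing <- setdiff(mapping$item, names(ratings))
  if (length(missing)) {
    ce_stop("format_error", "rating table lacks item column(s): %s",
            paste(missing, collapse = ", "))
  }
  rev_items <- mapping$item[mapping$keying < 0]
  if (length(rev_items)) {
    message(sprintf("reverse-keying item(s) before averaging: %s",
                    paste(rev_items, collapse = ", ")))
  }
  vals <- as.matrix(ratings[, mapping$item])
  vals[, rev_items] <- max_score - vals[, rev_items]
  for (sc in unique(mapping$scale)) {
    ratings[[sc]] <- rowMeans(vals[, mapping$item[mapping$scale == sc], drop = FALSE])
  }
  ratings
}

#' Per-stimulus mean scale scores
#'
#' Averages each rater's friendliness and maturity scores over raters for
#' each of the 24 (image, eye colour) stimuli.
#'
#' @inheritParams rater_scale_scores
#' @param n_images expected number of distinct images in the full design
#'   (default 12); a stimulus of the full 24-cell design with zero raters
#'   raises a coverage error. Pass `NULL` to skip the check.
#' @return Data frame `image_id`, `eye_colour`, `friendliness`, `maturity`,
#'   `n_raters`.
#' @export
scale_scores <- function(ratings, mapping, max_score = 5, n_images = 12) {
  r <- rater_scale_scores(ratings, mapping, max_score = max_score)
  agg <- stats::aggregate(
    r[, c("friendliness", "maturity")],
    by = list(image_id = r$image_id, eye_colour = r$eye_colour),
    FUN = mean
  )
  n <- stats::aggregate(list(n_raters = rep(1L, nrow(r))),
                        by = list(image_id = r$image_id, eye_colour = r$eye_colour),
                        FUN = sum)
  out <- merge(agg, n, by = c("image_id", "eye_colour"))
  if (!is.null(n_images)) {
    full <- expand.grid(image_id = seq_len(n_images),
                        eye_colour = c("dark", "light"),
                        stringsAsFactors = FALSE)
    missing <- !paste(full$image_id, full$eye_colour) %in%
      paste(out$image_id, out$eye_colour)
    if (any(missing)) {
      ce_stop("coverage_error", "stimulus with zero raters: %s",
              paste(paste0(full$image_id[missing], "/", full$eye_colour[missing]),
                    collapse = ", "))
    }
  }
  out <- out[order(out$image_id, out$eye_colour), , drop = FALSE]
  rownames(out) <- NULL
  out
}
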