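#' Cohen's kappa with squared weights
#'
#' Chance-corrected agreement between two raters on an ordinal score scale,
#' penalizing disagreements by the squared category distance:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `w_ij = (i - j)^2`, `O` the
#' observed category-pair proportions and `E` the chance-expected
#' proportions (products of the marginals). Suitable for LCOD totals
#' (0--40) or per-slice counts (0--10).
#'
#' @param x,y Integer-valued ratings of equal length (one element per item).
#' @param categories The full ordered score range; defaults to the span of
#'   the observed values. Categories absent from the data still shape the
#'   weights through their positions.
#' @return Weighted kappa in `[-1, 1]`.
#' @examples
#' weighted_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1))  # chance level: 0
#' @export
weighted_kappa <- function(x, y, categories = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2L,
            !anyNA(x), !anyNA(y))
  if (is.null(categories)) categories <- seq(min(x, y), max(x, y))
  if (!all(c(x, y) %in% categories)) {
    stop("ratings outside the declared categories", call. = FALSE)
  }
  k <- length(categories)
  fx <- factor(x, levels = categories)
  fy <- factor(y, levels = categories)
  O <- table(fx, fy) / length(x)
  E <- outer(rowSums(O), colSums(O))
  w <- outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2)
  denom <- sum(w * E)
  if (denom == 0) {
    warning("both raters constant and equal; kappa defined as 1",
            call. = FALSE)
    return(1)
  }
  1 - sum(w * O) / denom
}

#' Krippendorff's alpha (interval metric)
#'
#' Agreement across two or more raters with missing entries allowed,
#' computed from the coincidence matrix: `alpha = 1 - D_o / D_e` where
#' `D_o` averages the squared difference over all pairs of values within
#' items and `D_e` over all pairs across the pooled values. The interval
#' (squared-difference) metric parallels the squared weighting of
#' [weighted_kappa()].
#'
#' @param scores Numeric items x raters matrix (or data frame); `NA` marks
#'   a missing rating.
#' @return Alpha in `[-1, 1]` (values slightly below -1 are possible for
#'   tiny pathological tables).
#' @export
krippendorff_alpha <- function(scores) {
  m <- as.matrix(scores)
  stopifnot(is.numeric(m), nrow(m) >= 2L, ncol(m) >= 2L)
  # pairable values: items with at least two ratings
  n_item <- rowSums(!is.na(m))
  use <- n_item >= 2L
  if (sum(n_item[use]) < 2L) {
    stop("fewer than two pairable values", call. = FALSE)
  }
  num <- 0
  for (i in which(use)) {
    v <- m[i, !is.na(m[i, ])]
    mu <- length(v)
    dif <- outer(v, v, "-")^2
    num <- num + sum(dif) / (mu - 1)
  }
  pooled <- unlist(lapply(which(use), function(i) m[i, !is.na(m[i, ])]))
  n_tot <- length(pooled)
  D_o <- num / n_tot
  D_e <- sum(outer(pooled, pooled, "-")^2) / (n_tot * (n_tot - 1))
  if (D_e == 0) {
    warning("no expected disagreement; alpha defined as 1", call. = FALSE)
    return(1)
  }
  1 - D_o / D_e
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Overall agreement among k raters scoring n items, from the one-way
#' ANOVA decomposition across items:
#' `ICC(1) = (MSB - MSW) / (MSB + (k - 1) * MSW)`. The 95% confidence
#' interval follows from the F-distribution bounds on `MSB / MSW`.
#'
#' @param scores Complete numeric items x raters matrix.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A tibble with one row: `icc`, `conf_low`, `conf_high`,
#'   `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
icc_oneway <- function(scores, conf_level = 0.95) {
  m <- as.matrix(scores)
  stopifnot(is.numeric(m), !anyNA(m), nrow(m) >= 2L, ncol(m) >= 2L)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  item_means <- rowMeans(m)
  ssb <- k * sum((item_means - grand)^2)
  ssw <- sum((m - item_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw == 0) {
    warning("zero within-item variance; ICC is 1 with a degenerate interval",
            call. = FALSE)
    return(tibble::tibble(icc = 1, conf_low = 1, conf_high = 1,
                          f_statistic = Inf, df1 = n - 1, df2 = n * (k - 1),
                          p_value = 0))
  }
  f_obs <- msb / msw
  df1 <- n - 1; df2 <- n * (k - 1)
  alpha <- 1 - conf_level
  f_low <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
  f_high <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
  tibble::tibble(
    icc = (msb - msw) / (msb + (k - 1) * msw),
    conf_low = (f_low - 1) / (f_low + k - 1),
    conf_high = (f_high - 1) / (f_high + k - 1),
    f_statistic = f_obs,
    df1 = df1, df2 = df2,
    p_value = stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  )
}

#' Bland-Altman agreement summary
#'
#' Differences `d = x - y` between two sets of scores: the mean difference
#' (bias), its unbiased standard deviation, and the limits of agreement
#' `mean(d) +/- 1.96 * sd(d)`. Plot with [autoplot.bland_altman()].
#'
#' @param x,y Paired scores of equal length (>= 2).
#' @return A `bland_altman` object (also a tibble row): `mean_diff`,
#'   `sd_diff`, `lower_limit`, `upper_limit`, with the per-item `means` and
#'   `differences` attached as attributes for plotting.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !anyNA(x), !anyNA(y))
  d <- x - y
  s <- stats::sd(d)
  out <- tibble::tibble(
    mean_diff = mean(d),
    sd_diff = s,
    lower_limit = mean(d) - 1.96 * s,
    upper_limit = mean(d) + 1.96 * s
  )
  attr(out, "means") <- (x + y) / 2
  attr(out, "differences") <- d
  class(out) <- c("bland_altman", class(out))
  out
}
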