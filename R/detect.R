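#' Detection configuration for LCOD scoring
#'
#' Holds every tunable of the statistical detection stage. The family-wise
#' level `alpha_total` (default 0.05) is Bonferroni-divided across the four
#' LCOD slices, giving the per-slice level 0.0125 at which the
#' Benjamini-Hochberg step-up is applied to the 30 hole p-values of each
#' slice. The angle search scans `+/- angle_search_deg` around each spoke's
#' nominal angle in `angle_step_deg` increments, and profiles may be
#' jittered by up to `max_jitter_samples` integer samples to absorb residual
#' geometric error.
#'
#' @param alpha_total Family-wise significance level across the LCOD slices.
#' @param n_lcod_slices Number of LCOD slices the level is divided over.
#' @param angle_search_deg Half-range of the angular search (degrees).
#' @param angle_step_deg Angular search step (degrees).
#' @param max_jitter_samples Maximum profile shift in samples.
#' @param n_profile_samples Profile grid length (default 90, ~0.5 mm).
#' @param sidedness `"two-sided"` (default: a hole passes when its intensity
#'   differs from background in either direction) or `"one-sided"` (requires
#'   the configured polarity).
#' @param polarity Expected sign of the hole contrast under
#'   `sidedness = "one-sided"`: `1` for hyperintense holes, `-1` for
#'   hypointense.
#' @param scoring_mode `"all-passing"` (default): a slice's count is the
#'   number of passing spokes. `"acr-consecutive"`: count from spoke 1 up to
#'   the first failing spoke, as in manual ACR reading.
#' @return An object of class `detection_config`; `per_slice_alpha` is
#'   derived as `alpha_total / n_lcod_slices`.
#' @examples
#' detection_config()$per_slice_alpha  # 0.0125
#' @export
detection_config <- function(alpha_total = 0.05,
                             n_lcod_slices = 4L,
                             angle_search_deg = 8.0,
                             angle_step_deg = 0.5,
                             max_jitter_samples = 5L,
                             n_profile_samples = 90L,
                             sidedness = c("two-sided", "one-sided"),
                             polarity = 1,
                             scoring_mode = c("all-passing", "acr-consecutive")) {
  sidedness <- match.arg(sidedness)
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(
    alpha_total > 0, alpha_total < 1, n_lcod_slices >= 1L,
    angle_search_deg >= 0, angle_step_deg > 0,
    max_jitter_samples >= 0L, n_profile_samples >= 30L,
    polarity %in% c(-1, 1)
  )
  structure(
    list(
      alpha_total = alpha_total,
      n_lcod_slices = as.integer(n_lcod_slices),
      per_slice_alpha = alpha_total / n_lcod_slices,
      angle_search_deg = angle_search_deg,
      angle_step_deg = angle_step_deg,
      max_jitter_samples = as.integer(max_jitter_samples),
      n_profile_samples = as.integer(n_profile_samples),
      poly_order = 2L,
      sidedness = sidedness,
      polarity = polarity,
      scoring_mode = scoring_mode
    ),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(
    "<detection_config> per-slice alpha %.4g (= %.2g / %d), angle +/-%g deg @ %g, jitter +/-%d, %s, %s\n",
    x$per_slice_alpha, x$alpha_total, x$n_lcod_slices, x$angle_search_deg,
    x$angle_step_deg, x$max_jitter_samples, x$sidedness, x$scoring_mode))
  invisible(x)
}

# Least-squares machinery shared by fit_spoke_glm and the candidate search.
# X is the n x 6 design [hole indicators | nuisance]; Y may hold several
# profiles as columns. Returns per-column hole betas, t, p, rss.
glm_fit_columns <- function(X, Y, sidedness = "two-sided", polarity = 1) {
  n <- nrow(X)
  k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) stop("rank-deficient template design", call. = FALSE)
  B <- qr.coef(qrX, Y)
  fitted <- X %*% B
  res <- Y - fitted
  rss <- colSums(res^2)
  dof <- n - k
  R <- qr.R(qrX)
  xtxi <- chol2inv(R)
  piv <- qrX$pivot
  d <- numeric(k)
  d[piv] <- diag(xtxi)
  sigma2 <- rss / dof
  hole_idx <- 1:3
  betas <- B[hole_idx, , drop = FALSE]
  se <- sqrt(outer(d[hole_idx], sigma2))
  t_stat <- betas / se
  p <- if (sidedness == "two-sided") {
    2 * stats::pt(-abs(t_stat), dof)
  } else {
    stats::pt(-polarity * t_stat, dof, lower.tail = TRUE)
  }
  # zero-residual limit: p -> 0 where the effect is exactly recovered,
  # p -> 1 where it is exactly zero
  exact <- rss < 1e-24
  if (any(exact)) {
    nonzero <- abs(betas[, exact, drop = FALSE]) > 1e-12
    t_stat[, exact] <- ifelse(nonzero,
                              sign(betas[, exact, drop = FALSE]) * Inf, 0)
    p[, exact] <- ifelse(nonzero, 0, 1)
  }
  list(betas = betas, nuisance_betas = B[4:k, , drop = FALSE],
       t = t_stat, p = p, rss = rss, dof = dof)
}

# selection statistic: the binding (worst) hole governs the conjunction rule
selection_stat <- function(t_col, sidedness, polarity) {
  if (sidedness == "two-sided") min(abs(t_col)) else min(polarity * t_col)
}

#' Fit the per-spoke GLM of a profile on its template
#'
#' Ordinary least squares of the 90-sample radial profile on the spoke's
#' design: three binary hole indicators plus constant/linear/quadratic
#' nuisance columns. Each hole's effect is tested with
#' `t = beta / SE(beta)` on `n - 6` degrees of freedom (two-sided by
#' default). A zero-residual fit is treated as the limit of vanishing noise:
#' `p = 0` when the hole beta is nonzero, `p = 1` when it is zero.
#'
#' @param profile A [resample_profile()] result.
#' @param template A [build_spoke_template()] result on the same grid.
#' @param sidedness,polarity See [detection_config()].
#' @return A `spoke_glm`: `betas`, `nuisance_betas`, `t_stats`, `p_values`
#'   (each per hole), `dof`, `rss`, plus `angle_deg` and `jitter_samples`
#'   provenance.
#' @export
fit_spoke_glm <- function(profile, template,
                          sidedness = "two-sided", polarity = 1) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(template, "spoke_template"))
  if (profile$n_samples != template$n_samples) {
    stop("profile and template grids differ (", profile$n_samples, " vs ",
         template$n_samples, " samples)", call. = FALSE)
  }
  X <- template_design(template)
  fit <- glm_fit_columns(X, cbind(profile$samples), sidedness, polarity)
  new_spoke_glm(fit, 1L, angle_deg = profile$angle_deg, jitter_samples = 0L)
}

new_spoke_glm <- function(fit, col, angle_deg, jitter_samples) {
  structure(
    list(
      betas = fit$betas[, col],
      nuisance_betas = fit$nuisance_betas[, col],
      t_stats = fit$t[, col],
      p_values = fit$p[, col],
      dof = fit$dof,
      rss = fit$rss[col],
      angle_deg = angle_deg,
      jitter_samples = as.integer(jitter_samples)
    ),
    class = "spoke_glm"
  )
}

#' @export
print.spoke_glm <- function(x, ...) {
  cat(sprintf(
    "<spoke_glm> angle %.1f deg, jitter %+d; t = %s; p = %s (dof %d)\n",
    x$angle_deg, x$jitter_samples,
    paste(sprintf("%.2f", x$t_stats), collapse = ", "),
    paste(sprintf("%.3g", x$p_values), collapse = ", "), x$dof))
  invisible(x)
}

#' Evaluate one spoke with angular and jitter search
#'
#' Scans every candidate angle in `+/- angle_search_deg` around the spoke's
#' nominal angle (compensating phantom rotation) and every integer profile
#' jitter in `+/- max_jitter_samples` (compensating distortion and COG
#' error). Each candidate profile is refit against the spoke template; the
#' candidate maximizing the minimum per-hole detection statistic is kept —
#' the pass rule is a conjunction of the three holes, so the weakest hole
#' governs. Ties keep the earliest candidate (smallest angle, then smallest
#' jitter), making the search deterministic.
#'
#' @param slice A normalized [phantom_slice()].
#' @param mask The slice's [segment_inner_disk()] result.
#' @param spec A [spoke_spec()].
#' @param layout A [phantom_layout()].
#' @param config A [detection_config()].
#' @return The winning candidate's `spoke_glm` (with its `angle_deg` and
#'   `jitter_samples`).
#' @export
evaluate_spoke <- function(slice, mask, spec, layout = phantom_layout(),
                           config = detection_config()) {
  stopifnot(inherits(spec, "spoke_spec"), inherits(config, "detection_config"))
  angles <- if (config$angle_search_deg > 0) {
    seq(spec$nominal_angle_deg - config$angle_search_deg,
        spec$nominal_angle_deg + config$angle_search_deg,
        by = config$angle_step_deg)
  } else {
    spec$nominal_angle_deg
  }
  jitters <- (-config$max_jitter_samples):config$max_jitter_samples
  best <- NULL
  best_stat <- -Inf
  last_err <- NULL
  raws <- cast_rays(slice, mask, angles)
  for (i in seq_along(angles)) {
    ang <- angles[i]
    raw <- raws[[i]]
    if (inherits(raw, "error")) {
      last_err <- raw
      next
    }
    prof <- resample_profile(raw, config$n_profile_samples)
    template <- build_spoke_template(spec, prof$physical_length_mm,
                                     config$n_profile_samples)
    X <- template_design(template)
    Y <- vapply(jitters, function(s) shift_replicate(prof$samples, s),
                numeric(prof$n_samples))
    fit <- glm_fit_columns(X, Y, config$sidedness, config$polarity)
    stats_j <- vapply(seq_along(jitters),
                      function(j) selection_stat(fit$t[, j], config$sidedness,
                                                 config$polarity),
                      numeric(1))
    j_best <- which.max(stats_j)
    if (stats_j[j_best] > best_stat) {
      best_stat <- stats_j[j_best]
      best <- new_spoke_glm(fit, j_best, angle_deg = ang,
                            jitter_samples = jitters[j_best])
    }
  }
  if (is.null(best)) {
    stop("all candidate rays failed for spoke ", spec$spoke_index, ": ",
         conditionMessage(last_err), call. = FALSE)
  }
  best
}

#' Benjamini-Hochberg step-up rejections
#'
#' Step-up false-discovery-rate control: sort the m p-values ascending, find
#' the largest k with `p_(k) <= k * q / m`, and reject the k smallest
#' hypotheses (all values tied at the boundary are rejected). Implemented
#' through [stats::p.adjust()], whose BH adjustment is exactly equivalent to
#' the step-up rule.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return Logical rejection flags aligned with `p_values`.
#' @examples
#' benjamini_hochberg(c(0.001, 0.008, 0.039, 0.041), 0.05)
#' @export
benjamini_hochberg <- function(p_values, q) {
  if (length(p_values) == 0L) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  stats::p.adjust(p_values, method = "BH") <= q
}
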