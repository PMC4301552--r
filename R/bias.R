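#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Standardizes each study effect against the inverse-variance fixed-effect
#' pooled value, `t_i = (theta_i - theta_F) / sqrt(v_i - 1/sum(w))`, then
#' tests for Kendall rank correlation between the standardized effects and
#' their variances. The Kendall score S (concordant minus discordant pairs)
#' is converted to a continuity-corrected normal deviate
#' `z = (|S| - 1) / sqrt(k (k-1) (2k+5) / 18)` (z = 0 when the corrected
#' score crosses zero, giving p = 1) and a two-sided p-value. `tau` uses
#' tau-b tie handling; the variance term uses the untied formula (ties in
#' continuous variances are rare). Correlation between small-study status
#' (large variance) and effect size suggests selective publication.
#'
#' @param effects per-study effects from [estimate_effects()], one contrast
#'   model; at least 2 studies (3 or more for reasonable power, flagged via
#'   `low_power`).
#' @return A `snpmeta_begg`: list with `kendall_score`, `tau`, `z_statistic`,
#'   `p_value`, `k`, `degenerate` (all variances tied; tau reported as 0 with
#'   p = 1) and `low_power`.
#' @export
#' @examples
#' eff <- estimate_effects(apply_continuity(
#'   collapse_counts(crp_studies("rs2808630"), "recessive")))
#' begg_test(eff)
begg_test <- function(effects) {
  effects <- check_effects(effects)
  k <- nrow(effects)
  if (k < 2L) {
    stop("the rank-correlation test needs at least two studies",
         call. = FALSE)
  }
  low_power <- k < 3L
  if (low_power) {
    warning("only ", k, " studies: the rank-correlation test has very low power",
            call. = FALSE)
  }
  w <- 1 / effects$variance
  theta_f <- sum(w * effects$log_or) / sum(w)
  t_std <- (effects$log_or - theta_f) /
    sqrt(effects$variance - 1 / sum(w))

  v <- effects$variance
  degenerate <- length(unique(v)) == 1L
  pairs <- utils::combn(k, 2L)
  dt <- t_std[pairs[1L, ]] - t_std[pairs[2L, ]]
  dv <- v[pairs[1L, ]] - v[pairs[2L, ]]
  score <- sum(sign(dt * dv))

  tie_term <- function(x) {
    n_tied <- table(x)
    sum(n_tied * (n_tied - 1) / 2)
  }
  n0 <- k * (k - 1) / 2
  denom <- sqrt((n0 - tie_term(t_std)) * (n0 - tie_term(v)))
  tau <- if (degenerate || denom == 0) 0 else score / denom

  var_s <- k * (k - 1) * (2 * k + 5) / 18
  z <- if (abs(score) <= 1 || degenerate) 0 else
    sign(score) * (abs(score) - 1) / sqrt(var_s)
  p <- if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  if (degenerate) {
    warning("all study variances are identical; rank test is degenerate",
            call. = FALSE)
  }
  structure(
    list(kendall_score = score, tau = tau, z_statistic = z, p_value = p,
         k = k, degenerate = degenerate, low_power = low_power),
    class = "snpmeta_begg"
  )
}

#' @export
print.snpmeta_begg <- function(x, ...) {
  cat(sprintf(
    "Begg-Mazumdar test: score = %d, tau = %.3f, z = %.3f, p = %.3f (k = %d)\n",
    x$kendall_score, x$tau, x$z_statistic, x$p_value, x$k))
  if (x$degenerate) cat("(degenerate: all variances tied)\n")
  invisible(x)
}

#' Funnel-plot data
#'
#' Returns one point per study (log odds ratio against its standard error,
#' conventionally plotted with the standard-error axis inverted) plus the
#' pooled centre line and pseudo-confidence limits
#' `centre +/- z * se` evaluated over a standard-error grid from 0 to just
#' beyond the largest study standard error. Symmetry of the points about the
#' centre is the visual signature of absence of publication bias.
#'
#' @param effects per-study effects from [estimate_effects()].
#' @param pooled a `snpmeta_pooled` giving the centre, typically the
#'   fixed-effect pool of the same effects.
#' @param grid_n number of grid points for the limit curves.
#' @return List with `points` (data frame `study_id`, `log_or`, `se`),
#'   `center` (pooled log odds ratio), `level`, and `limits` (data frame
#'   `se`, `lower`, `upper`).
#' @export
funnel_data <- function(effects, pooled, grid_n = 50L) {
  effects <- check_effects(effects)
  stopifnot(inherits(pooled, "snpmeta_pooled"))
  se <- sqrt(effects$variance)
  z <- stats::qnorm(1 - (1 - pooled$level) / 2)
  grid <- seq(0, max(se) * 1.1, length.out = grid_n)
  list(
    points = data.frame(study_id = effects$study_id,
                        log_or = effects$log_or, se = se,
                        stringsAsFactors = FALSE),
    center = pooled$log_or,
    level = pooled$level,
    limits = data.frame(se = grid,
                        lower = pooled$log_or - z * grid,
                        upper = pooled$log_or + z * grid)
  )
}
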