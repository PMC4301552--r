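check_effects <- function(effects) {
  stopifnot(is.data.frame(effects))
  need <- c("study_id", "model", "log_or", "variance")
  missing <- setdiff(need, names(effects))
  if (length(missing)) {
    stop("effects table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(effects) == 0L) {
    stop("at least one study effect is required", call. = FALSE)
  }
  if (length(unique(effects$model)) != 1L) {
    stop("all effects must share one contrast model; got: ",
         paste(unique(effects$model), collapse = ", "), call. = FALSE)
  }
  if (any(effects$variance <= 0)) {
    stop("all effect variances must be positive", call. = FALSE)
  }
  effects
}

#' Cochran's Q heterogeneity statistics
#'
#' Q is the inverse-variance weighted sum of squared deviations of the study
#' log odds ratios from the fixed-effect pooled value; under homogeneity it
#' is approximately chi-square with k - 1 degrees of freedom, giving the
#' heterogeneity p-value `p_h` (undefined for a single study). `tau_squared`
#' is the DerSimonian-Laird moment estimate
#' `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` and `i_squared` is
#' `max(0, (Q - df)/Q)`, the fraction of total variability attributable to
#' between-study variance.
#'
#' @param effects per-study effects from [estimate_effects()].
#' @param pooled_log_or centre for Q; defaults to the inverse-variance
#'   fixed-effect pooled log odds ratio (the standard construction, also used
#'   when the random-effects model is ultimately reported).
#' @return List of class `snpmeta_heterogeneity` with elements `q_statistic`,
#'   `df`, `p_h`, `i_squared`, `tau_squared`, `k`.
#' @export
heterogeneity <- function(effects, pooled_log_or = NULL) {
  effects <- check_effects(effects)
  w <- 1 / effects$variance
  if (is.null(pooled_log_or)) {
    pooled_log_or <- sum(w * effects$log_or) / sum(w)
  }
  k <- nrow(effects)
  q <- sum(w * (effects$log_or - pooled_log_or)^2)
  df <- k - 1L
  p_h <- if (df > 0L) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  tau2 <- if (df > 0L) {
    max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  } else 0
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  structure(
    list(q_statistic = q, df = df, p_h = p_h, i_squared = i2,
         tau_squared = tau2, k = k),
    class = "snpmeta_heterogeneity"
  )
}

new_pooled <- function(model, method, effects, log_or, se, level, weights,
                       het) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(
      model = model,
      method = method,
      k = nrow(effects),
      study_ids = effects$study_id,
      log_or = log_or,
      se = se,
      or = exp(log_or),
      ci_low = exp(log_or - z * se),
      ci_high = exp(log_or + z * se),
      level = level,
      weights = stats::setNames(weights, effects$study_id),
      heterogeneity = het
    ),
    class = "snpmeta_pooled"
  )
}

#' Fixed-effect (inverse-variance) pooled odds ratio
#'
#' Weights each study by the reciprocal of its Woolf variance:
#' pooled log OR = sum(w * theta) / sum(w), standard error 1/sqrt(sum(w)).
#' Cochran's Q heterogeneity statistics (computed against this pooled value)
#' are attached.
#'
#' @param effects per-study effects from [estimate_effects()], all under one
#'   contrast model.
#' @param level two-sided confidence level, default 0.95.
#' @return A `snpmeta_pooled` object: pooled odds ratio, CI, per-study
#'   weights, heterogeneity statistics, `method = "fixed_iv"`.
#' @export
#' @examples
#' eff <- estimate_effects(apply_continuity(
#'   collapse_counts(crp_studies("rs2808630"), "recessive")))
#' pool_fixed(eff)
pool_fixed <- function(effects, level = 0.95) {
  effects <- check_effects(effects)
  w <- 1 / effects$variance
  log_or <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- heterogeneity(effects, log_or)
  new_pooled(effects$model[1], "fixed_iv", effects, log_or, se, level, w, het)
}

#' Random-effects (DerSimonian-Laird) pooled odds ratio
#'
#' Adds the moment-estimated between-study variance tau^2 to each study's
#' variance before inverse-variance weighting: w* = 1/(v + tau^2). When
#' tau^2 = 0 the result coincides with [pool_fixed()] in every field except
#' the method label.
#'
#' @inheritParams pool_fixed
#' @return A `snpmeta_pooled` object with `method = "random_dl"`.
#' @export
pool_random <- function(effects, level = 0.95) {
  effects <- check_effects(effects)
  het <- heterogeneity(effects)
  w <- 1 / (effects$variance + het$tau_squared)
  log_or <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_pooled(effects$model[1], "random_dl", effects, log_or, se, level, w, het)
}

#' Mantel-Haenszel pooled odds ratio
#'
#' Pools the fourfold tables directly:
#' `exp(log(sum(a*d/N) / sum(b*c/N)))`, with the Robins-Breslow-Greenland
#' variance for the log pooled odds ratio. By default the Haldane-Anscombe
#' 0.5 correction is applied to zero-cell tables before summation
#' (`correct = TRUE`, the convention of common meta-analysis software);
#' `correct = FALSE` uses the raw counts, for which the Mantel-Haenszel point
#' estimate is defined even with zero cells. Heterogeneity statistics are the
#' standard inverse-variance construction on the (corrected) tables.
#'
#' @param tables fourfold-table data frame from [collapse_counts()]
#'   (uncorrected; correction is handled here).
#' @param level two-sided confidence level, default 0.95.
#' @param correct apply the 0.5 correction to zero-cell tables first.
#' @param increment correction increment when `correct = TRUE`.
#' @return A `snpmeta_pooled` object with `method = "fixed_mh"`.
#' @export
pool_mh <- function(tables, level = 0.95, correct = TRUE, increment = 0.5) {
  stopifnot(is.data.frame(tables),
            all(c("a", "b", "c", "d") %in% names(tables)))
  if (nrow(tables) == 0L) {
    stop("at least one table is required", call. = FALSE)
  }
  corrected <- apply_continuity(tables, increment)
  use <- if (correct) corrected else tables
  a <- use$a; b <- use$b; cc <- use$c; d <- use$d
  n <- a + b + cc + d
  r <- a * d / n
  s <- b * cc / n
  if (sum(r) <= 0 || sum(s) <= 0) {
    stop("degenerate data: a Mantel-Haenszel cross-product sum is zero",
         call. = FALSE)
  }
  log_or <- log(sum(r) / sum(s))
  p <- (a + d) / n
  q <- (b + cc) / n
  v <- sum(p * r) / (2 * sum(r)^2) +
    sum(p * s + q * r) / (2 * sum(r) * sum(s)) +
    sum(q * s) / (2 * sum(s)^2)
  eff <- estimate_effects(corrected, level)
  het <- heterogeneity(eff)
  new_pooled(tables$model[1], "fixed_mh", eff, log_or, sqrt(v), level,
             1 / eff$variance, het)
}

#' Heterogeneity-guided pooling
#'
#' Applies the model-selection rule used throughout the pipeline: compute
#' Cochran's Q on the fixed-effect fit; if the heterogeneity p-value `p_h`
#' is below `alpha_h`, report the DerSimonian-Laird random-effects pool,
#' otherwise the fixed-effect pool. A single study (where `p_h` is undefined)
#' is always reported as fixed. The fixed-effect engine is inverse-variance
#' weighting by default; `fixed_method = "mh"` substitutes the
#' Mantel-Haenszel estimate (requires `tables`), which is what Stata's
#' `metan` computes by default on count data.
#'
#' @inheritParams pool_fixed
#' @param alpha_h heterogeneity significance threshold, default 0.05.
#' @param fixed_method `"iv"` (inverse-variance, default) or `"mh"`.
#' @param tables the uncorrected fourfold tables; required when
#'   `fixed_method = "mh"`.
#' @return A `snpmeta_pooled` object; the `method` field records the choice.
#' @export
pool_auto <- function(effects, alpha_h = 0.05, level = 0.95,
                      fixed_method = c("iv", "mh"), tables = NULL) {
  effects <- check_effects(effects)
  fixed_method <- match.arg(fixed_method)
  het <- heterogeneity(effects)
  if (!is.na(het$p_h) && het$p_h < alpha_h) {
    return(pool_random(effects, level))
  }
  if (fixed_method == "mh") {
    if (is.null(tables)) {
      stop("`tables` is required when fixed_method = \"mh\"", call. = FALSE)
    }
    return(pool_mh(tables, level))
  }
  pool_fixed(effects, level)
}

#' @export
print.snpmeta_pooled <- function(x, ...) {
  cat(sprintf(
    "Pooled odds ratio (%s, %s): %.3f [%g%% CI %.3f-%.3f], k = %d\n",
    x$model, x$method, x$or, 100 * x$level, x$ci_low, x$ci_high, x$k))
  h <- x$heterogeneity
  cat(sprintf(
    "Heterogeneity: Q = %.3f on %d df, P_h = %s, I^2 = %.1f%%, tau^2 = %.4f\n",
    h$q_statistic, h$df,
    if (is.na(h$p_h)) "NA" else sprintf("%.3f", h$p_h),
    100 * h$i_squared, h$tau_squared))
  invisible(x)
}

#' @export
print.snpmeta_heterogeneity <- function(x, ...) {
  cat(sprintf(
    "Cochran's Q = %.4f on %d df (k = %d): P_h = %s, I^2 = %.1f%%, tau^2 = %.4f\n",
    x$q_statistic, x$df, x$k,
    if (is.na(x$p_h)) "NA" else sprintf("%.4f", x$p_h),
    100 * x$i_squared, x$tau_squared))
  invisible(x)
}
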