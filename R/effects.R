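#' Per-study odds ratios from fourfold tables
#'
#' Computes, for each study, the crude odds ratio `ad/(bc)`, its natural-log
#' value, the Woolf (delta-method) variance `1/a + 1/b + 1/c + 1/d`, and an
#' asymptotic confidence interval built on the log scale and exponentiated
#' (intervals are therefore asymmetric around the odds ratio, symmetric
#' around the log odds ratio). All four cells must be positive; tables with
#' zero cells need [apply_continuity()] first.
#'
#' @param tables fourfold-table data frame from [collapse_counts()],
#'   continuity-corrected if required.
#' @param level two-sided confidence level in (0, 1); default 0.95 uses the
#'   normal quantile 1.959964.
#' @return Data frame of class `snpmeta_effects` with columns `study_id`,
#'   `model`, `log_or`, `variance`, `or`, `ci_low`, `ci_high`, `level`,
#'   `continuity_applied`.
#' @export
#' @examples
#' tab <- apply_continuity(collapse_counts(crp_studies("rs2808630"), "recessive"))
#' estimate_effects(tab)
estimate_effects <- function(tables, level = 0.95) {
  stopifnot(is.data.frame(tables),
            all(c("study_id", "model", "a", "b", "c", "d") %in% names(tables)))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  cells <- as.matrix(tables[, c("a", "b", "c", "d")])
  zero <- apply(cells == 0, 1L, any)
  if (any(zero)) {
    stop("zero cell in study ",
         paste(tables$study_id[zero], collapse = ", "),
         "; apply a continuity correction (apply_continuity) first",
         call. = FALSE)
  }
  log_or <- log(cells[, "a"] * cells[, "d"] / (cells[, "b"] * cells[, "c"]))
  variance <- rowSums(1 / cells)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    study_id = tables$study_id,
    model = tables$model,
    log_or = log_or,
    variance = variance,
    or = exp(log_or),
    ci_low = exp(log_or - z * sqrt(variance)),
    ci_high = exp(log_or + z * sqrt(variance)),
    level = level,
    continuity_applied = tables$continuity_applied,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("snpmeta_effects", "data.frame")
  out
}
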