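pool_cell <- function(studies, model, alpha_h, level, increment,
                      fixed_method) {
  tables <- collapse_counts(studies, model)
  effects <- estimate_effects(apply_continuity(tables, increment), level)
  pool_auto(effects, alpha_h = alpha_h, level = level,
            fixed_method = fixed_method, tables = tables)
}

#' Run the full genotype meta-analysis
#'
#' For every requested genetic contrast and every stratum of the chosen
#' grouping variable (plus an all-studies "Total" stratum), collapses the
#' genotype counts, applies the continuity correction, estimates per-study
#' odds ratios and pools them under the heterogeneity-guided rule of
#' [pool_auto()]: random effects when `p_h < alpha_h`, fixed effect
#' otherwise.
#'
#' @param studies a corpus data frame; all rows must share one `variant_id`.
#' @param models contrasts to analyse; default all of [contrast_models()].
#' @param stratify_by corpus column defining subgroups, default
#'   `"cancer_type"`.
#' @param alpha_h heterogeneity threshold for the fixed/random choice.
#' @param level confidence level.
#' @param increment continuity-correction increment for zero-cell tables.
#' @param fixed_method fixed-effect engine, `"iv"` (inverse-variance,
#'   default) or `"mh"` (Mantel-Haenszel, the Stata `metan` default for
#'   count data).
#' @return A `snpmeta_result`: list with `variant_id`, `stratify_by`,
#'   `strata`, `models`, `cells` (named list `"stratum|model"` of
#'   `snpmeta_pooled`), and `table`, a tidy data frame with one row per
#'   (stratum, model).
#' @export
#' @examples
#' res <- run_meta(crp_studies("rs2808630"))
#' res$table
run_meta <- function(studies, models = contrast_models(),
                     stratify_by = "cancer_type", alpha_h = 0.05,
                     level = 0.95, increment = 0.5,
                     fixed_method = c("iv", "mh")) {
  studies <- validate_studies(studies)
  fixed_method <- match.arg(fixed_method)
  if (nrow(studies) == 0L) {
    stop("`studies` must contain at least one study", call. = FALSE)
  }
  if (length(unique(studies$variant_id)) != 1L) {
    stop("all studies must share one variant_id; got: ",
         paste(unique(studies$variant_id), collapse = ", "), call. = FALSE)
  }
  if (!stratify_by %in% names(studies)) {
    stop("unknown stratification column '", stratify_by, "'", call. = FALSE)
  }
  models <- vapply(models, check_model, character(1), USE.NAMES = FALSE)
  strata <- c("Total", sort(unique(studies[[stratify_by]])))

  cells <- list()
  rows <- list()
  for (stratum in strata) {
    sub <- if (stratum == "Total") studies else
      studies[studies[[stratify_by]] == stratum, , drop = FALSE]
    for (model in models) {
      pooled <- pool_cell(sub, model, alpha_h, level, increment, fixed_method)
      cells[[paste(stratum, model, sep = "|")]] <- pooled
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, model = model, k = pooled$k,
        or = pooled$or, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
        p_h = pooled$heterogeneity$p_h,
        i_squared = pooled$heterogeneity$i_squared,
        tau_squared = pooled$heterogeneity$tau_squared,
        method = pooled$method, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(variant_id = studies$variant_id[1], stratify_by = stratify_by,
         strata = strata, models = models, cells = cells,
         table = do.call(rbind, rows)),
    class = "snpmeta_result"
  )
}

#' Extract one pooled cell from a meta-analysis result
#'
#' @param result a `snpmeta_result` from [run_meta()].
#' @param stratum stratum label (`"Total"` for the all-studies pool).
#' @param model contrast model name.
#' @return The `snpmeta_pooled` object for that cell.
#' @export
meta_cell <- function(result, stratum, model) {
  stopifnot(inherits(result, "snpmeta_result"))
  key <- paste(stratum, check_model(model), sep = "|")
  cell <- result$cells[[key]]
  if (is.null(cell)) {
    stop("no cell for stratum '", stratum, "' and model '", model, "'",
         call. = FALSE)
  }
  cell
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the corpus k times under one contrast, omitting one study each
#' time, in corpus order. The full fixed/random selection rule is re-applied
#' after each exclusion, so the reported model may differ between entries.
#'
#' @inheritParams run_meta
#' @param model a single contrast model.
#' @return A `snpmeta_loo`: list with `model`, `entries` (data frame:
#'   `excluded`, `k`, `or`, `ci_low`, `ci_high`, `p_h`, `method`) and
#'   `pooled`, the corresponding `snpmeta_pooled` objects named by the
#'   excluded study.
#' @export
#' @examples
#' leave_one_out(crp_studies("rs2808630"), "recessive")$entries
leave_one_out <- function(studies, model, alpha_h = 0.05, level = 0.95,
                          increment = 0.5, fixed_method = c("iv", "mh")) {
  studies <- validate_studies(studies)
  fixed_method <- match.arg(fixed_method)
  model <- check_model(model)
  k <- nrow(studies)
  if (k < 2L) {
    stop("leave-one-out requires at least two studies", call. = FALSE)
  }
  pooled <- lapply(seq_len(k), function(i) {
    pool_cell(studies[-i, , drop = FALSE], model, alpha_h, level, increment,
              fixed_method)
  })
  names(pooled) <- studies$study_id
  entries <- data.frame(
    excluded = studies$study_id,
    k = vapply(pooled, function(p) p$k, integer(1)),
    or = vapply(pooled, function(p) p$or, numeric(1)),
    ci_low = vapply(pooled, function(p) p$ci_low, numeric(1)),
    ci_high = vapply(pooled, function(p) p$ci_high, numeric(1)),
    p_h = vapply(pooled, function(p) p$heterogeneity$p_h, numeric(1)),
    method = vapply(pooled, function(p) p$method, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(model = model, entries = entries, pooled = pooled),
            class = "snpmeta_loo")
}

round2 <- function(x) sprintf("%.2f", round(x, 2))  # display: half-even at 2 dp

#' Format a meta-analysis result as a text table
#'
#' One row per stratum ("Total" last), two columns per contrast: the pooled
#' odds ratio with its confidence interval as `"OR (low-high)"` and the
#' heterogeneity p-value, all at two decimals (half-even rounding); `NA`
#' where `p_h` is undefined (single-study strata). Column order follows the
#' conventional reporting order of [contrast_models()].
#'
#' @param result a `snpmeta_result` from [run_meta()].
#' @return A character matrix with strata as rows; printed by
#'   `print.snpmeta_result`.
#' @export
format_report <- function(result) {
  stopifnot(inherits(result, "snpmeta_result"))
  strata <- c(setdiff(result$strata, "Total"), "Total")
  out <- matrix("", nrow = length(strata),
                ncol = 2L * length(result$models),
                dimnames = list(strata, paste(
                  rep(result$models, each = 2L), c("OR (95% CI)", "P_h"))))
  for (stratum in strata) {
    for (j in seq_along(result$models)) {
      cell <- meta_cell(result, stratum, result$models[j])
      out[stratum, 2L * j - 1L] <- sprintf(
        "%s (%s-%s)", round2(cell$or), round2(cell$ci_low),
        round2(cell$ci_high))
      p <- cell$heterogeneity$p_h
      out[stratum, 2L * j] <- if (is.na(p)) "NA" else round2(p)
    }
  }
  out
}

#' @export
print.snpmeta_result <- function(x, ...) {
  cat(sprintf("Genotype meta-analysis of %s (%d strata by %s)\n",
              x$variant_id, length(x$strata) - 1L, x$stratify_by))
  print(format_report(x), quote = FALSE)
  methods <- vapply(x$cells, function(p) p$method, character(1))
  if (all(methods == methods[1])) {
    cat("All cells pooled by", methods[1], "\n")
  } else {
    cat("Mixed pooling methods; see $table$method\n")
  }
  invisible(x)
}

#' @export
print.snpmeta_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out sensitivity analysis (%s contrast, k = %d)\n",
              x$model, nrow(x$entries)))
  print(x$entries, digits = 4)
  invisible(x)
}
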