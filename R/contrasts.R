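#' The five genetic contrast models
#'
#' Each contrast dichotomizes the three genotype classes (AA common
#' homozygote, Aa heterozygote, aa variant homozygote) into an
#' exposed/unexposed 2x2 comparison:
#'
#' * `recessive`: aa vs Aa + AA
#' * `dominant`: aa + Aa vs AA
#' * `codom_hom`: aa vs AA (heterozygotes dropped)
#' * `codom_het`: Aa vs AA (variant homozygotes dropped)
#' * `allele`: a vs A, counting two alleles per subject
#'
#' @return Character vector of the five contrast names, in conventional
#'   reporting order.
#' @export
contrast_models <- function() {
  c("recessive", "dominant", "codom_hom", "codom_het", "allele")
}

check_model <- function(model) {
  model <- as.character(model)[1]
  if (!model %in% contrast_models()) {
    stop("unknown contrast model '", model, "'; must be one of ",
         paste(contrast_models(), collapse = ", "), call. = FALSE)
  }
  model
}

#' Collapse genotype counts into 2x2 tables under a genetic contrast
#'
#' Produces, for each study, the fourfold table (a = exposed cases,
#' b = unexposed cases, c = exposed controls, d = unexposed controls) implied
#' by the chosen contrast. The allele contrast treats the two alleles carried
#' by each subject as independent observations, so its margins are twice the
#' subject totals; the codominant contrasts drop one genotype class.
#' Collapsing is total: zero cells pass through unchanged (see
#' [apply_continuity()]).
#'
#' @param studies a corpus data frame.
#' @param model one of [contrast_models()].
#' @return Data frame with columns `study_id`, `model`, `a`, `b`, `c`, `d`,
#'   `continuity_applied` (all `FALSE`), one row per study, order preserved.
#' @export
#' @examples
#' collapse_counts(crp_studies("rs2808630"), "recessive")
collapse_counts <- function(studies, model) {
  studies <- validate_studies(studies)
  model <- check_model(model)
  with(studies, {
    cells <- switch(model,
      recessive = cbind(a = case_aa, b = case_Aa + case_AA,
                        c = ctrl_aa, d = ctrl_Aa + ctrl_AA),
      dominant  = cbind(a = case_aa + case_Aa, b = case_AA,
                        c = ctrl_aa + ctrl_Aa, d = ctrl_AA),
      codom_hom = cbind(a = case_aa, b = case_AA,
                        c = ctrl_aa, d = ctrl_AA),
      codom_het = cbind(a = case_Aa, b = case_AA,
                        c = ctrl_Aa, d = ctrl_AA),
      allele    = cbind(a = 2L * case_aa + case_Aa, b = 2L * case_AA + case_Aa,
                        c = 2L * ctrl_aa + ctrl_Aa, d = 2L * ctrl_AA + ctrl_Aa)
    )
    data.frame(study_id = study_id, model = model, cells,
               continuity_applied = FALSE, stringsAsFactors = FALSE)
  })
}

#' Haldane-Anscombe continuity correction for zero cells
#'
#' Adds `increment` to all four cells of any table containing a zero, so the
#' log odds ratio and its Woolf variance are finite. The correction is
#' applied per table, not corpus-wide. A table whose case margin (a + b) or
#' control margin (c + d) is zero carries no information about the contrast
#' and raises an error: such a study must be excluded upstream.
#'
#' @param tables fourfold-table data frame from [collapse_counts()].
#' @param increment positive correction, default 0.5.
#' @return The tables, with corrected rows flagged `continuity_applied = TRUE`.
#' @export
#' @examples
#' tab <- collapse_counts(crp_studies("rs2808630"), "recessive")
#' apply_continuity(tab)
apply_continuity <- function(tables, increment = 0.5) {
  stopifnot(is.data.frame(tables),
            all(c("a", "b", "c", "d") %in% names(tables)))
  if (!is.numeric(increment) || length(increment) != 1L || increment <= 0) {
    stop("`increment` must be a single positive number", call. = FALSE)
  }
  cells <- as.matrix(tables[, c("a", "b", "c", "d")])
  degenerate <- (cells[, "a"] + cells[, "b"] == 0) |
                (cells[, "c"] + cells[, "d"] == 0)
  if (any(degenerate)) {
    stop("study ", paste(tables$study_id[degenerate], collapse = ", "),
         " has an empty case or control margin under contrast '",
         tables$model[1],
         "' and cannot contribute; exclude it before pooling", call. = FALSE)
  }
  zero <- apply(cells == 0, 1L, any)
  cells[zero, ] <- cells[zero, ] + increment
  tables[, c("a", "b", "c", "d")] <- cells
  tables$continuity_applied <- zero
  tables
}
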