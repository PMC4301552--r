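# Shared test fixtures and independent oracles.

# A tiny hand-written corpus (not the bundled one) for I/O and validation.
toy_corpus <- function() {
  data.frame(
    study_id = c("s1", "s2", "s3"),
    first_author = c("Alpha", "Beta", "Gamma"),
    year = c(2001L, 2005L, 2010L),
    country = c("USA", "China", "Italy"),
    ethnicity = c("Caucasian", "Asian", "Mixed"),
    cancer_type = c("Lung", "Lung", "Prostate"),
    variant_id = "rs1",
    case_AA = c(50L, 40L, 30L), case_Aa = c(30L, 25L, 20L),
    case_aa = c(10L, 8L, 5L),
    ctrl_AA = c(60L, 45L, 35L), ctrl_Aa = c(35L, 30L, 25L),
    ctrl_aa = c(12L, 9L, 6L),
    stringsAsFactors = FALSE
  )
}

# Independent per-table oracle: odds of exposure in each arm, then the ratio.
oracle_or <- function(a, b, c, d) (a / b) / (c / d)

oracle_log_or_var <- function(a, b, c, d) 1 / a + 1 / b + 1 / c + 1 / d

# Effects table built directly from cells, bypassing collapse_counts.
effects_from_cells <- function(a, b, c, d, model = "recessive", level = 0.95) {
  tab <- data.frame(study_id = sprintf("e%02d", seq_along(a)), model = model,
                    a = a, b = b, c = c, d = d, continuity_applied = FALSE,
                    stringsAsFactors = FALSE)
  estimate_effects(tab, level)
}

fixture_effects <- function(variant = "rs2808630", model = "recessive") {
  estimate_effects(apply_continuity(
    collapse_counts(crp_studies(variant), model)))
}
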