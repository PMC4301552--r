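#' Hardy-Weinberg genotype probabilities
#'
#' Genotype proportions implied by random mating at variant-allele frequency
#' `p`: `((1-p)^2, 2p(1-p), p^2)` for (AA, Aa, aa).
#'
#' @param p variant-allele frequency, strictly between 0 and 1.
#' @return Named numeric vector `c(AA = , Aa = , aa = )` summing to 1.
#' @export
#' @examples
#' hwe_genotype_probs(0.5)  # 0.25, 0.50, 0.25
hwe_genotype_probs <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("`p` must be a single allele frequency strictly between 0 and 1",
         call. = FALSE)
  }
  c(AA = (1 - p)^2, Aa = 2 * p * (1 - p), aa = p^2)
}

#' Case genotype probabilities under genotype-level odds ratios
#'
#' Tilts the control genotype distribution by genotype odds ratios relative
#' to the common homozygote: case probabilities proportional to
#' `(P_AA, P_Aa * psi_het, P_aa * psi_hom)`. This is the retrospective
#' equivalent of a prospective logistic disease model, so the population
#' odds ratio of any collapsed contrast is controlled exactly; in particular
#' the recessive odds ratio equals `psi_hom` exactly when `psi_het = 1`.
#'
#' @param control_probs genotype probabilities (AA, Aa, aa), summing to 1.
#' @param psi_het heterozygote odds ratio vs common homozygote, > 0.
#' @param psi_hom variant-homozygote odds ratio vs common homozygote, > 0.
#' @return Case genotype probabilities, same names, summing to 1.
#' @export
#' @examples
#' case_genotype_probs(hwe_genotype_probs(0.5), psi_het = 1, psi_hom = 2)
case_genotype_probs <- function(control_probs, psi_het, psi_hom) {
  stopifnot(length(control_probs) == 3L, all(control_probs >= 0),
            abs(sum(control_probs) - 1) < 1e-8,
            psi_het > 0, psi_hom > 0)
  raw <- control_probs * c(1, psi_het, psi_hom)
  raw / sum(raw)
}

draw_scalar <- function(x, integer = FALSE) {
  # fixed value (length 1) or uniform draw from a [lo, hi] range (length 2)
  if (length(x) == 1L) return(x)
  if (length(x) == 2L) {
    if (integer) return(sample(seq.int(x[1], x[2]), 1L))
    return(stats::runif(1L, x[1], x[2]))
  }
  stop("parameter must have length 1 (fixed) or 2 (range)", call. = FALSE)
}

#' Simulate a multi-study case-control genotype corpus with known truth
#'
#' Generates `k` studies: per study, control genotype counts are multinomial
#' under Hardy-Weinberg proportions at variant-allele frequency `p`, and case
#' counts are multinomial under the genotype distribution tilted by the
#' genotype odds ratios (see [case_genotype_probs()]). Between-study
#' heterogeneity of standard deviation `tau` perturbs the variant-homozygote
#' log odds ratio, so with `psi_het = 1` the true recessive log odds ratio of
#' study i is exactly `N(log(psi_hom), tau^2)`. An optional
#' selective-publication rule censors small studies whose crude recessive
#' odds ratio (continuity-corrected) does not exceed a threshold, the minimal
#' mechanism producing funnel asymmetry.
#'
#' `n_cases`, `n_controls` and `p` may each be a single value or a
#' `c(lo, hi)` range sampled independently per study. The seed fully
#' determines the output; the caller's random-number state is left untouched.
#'
#' @param k number of studies (0 gives an empty corpus).
#' @param n_cases,n_controls per-study arm sizes (fixed or range), >= 1.
#' @param p control variant-allele frequency (fixed or range in (0, 1)).
#' @param psi_het,psi_hom genotype odds ratios vs the common homozygote.
#' @param tau between-study standard deviation of the variant-homozygote log
#'   odds ratio; 0 (default) for a common true effect.
#' @param selection `NULL` (publish everything) or
#'   `list(or_threshold = , max_n = )`: studies with case-arm size
#'   `<= max_n` are published only if their crude recessive odds ratio
#'   exceeds `or_threshold`.
#' @param seed integer seed; required.
#' @param variant_id variant label stamped on the corpus.
#' @return A validated corpus data frame (possibly fewer than `k` rows when
#'   `selection` censors studies; an error if it censors all of them).
#' @export
#' @examples
#' sim <- simulate_corpus(k = 4, n_cases = 200, n_controls = 200,
#'                        p = 0.3, psi_hom = 1.5, seed = 1)
#' run_meta(sim, models = "recessive")
simulate_corpus <- function(k, n_cases = 500, n_controls = 500, p = 0.3,
                            psi_het = 1, psi_hom = 1, tau = 0,
                            selection = NULL, seed, variant_id = "rs0sim") {
  stopifnot(k >= 0, all(n_cases >= 1), all(n_controls >= 1),
            all(p > 0 & p < 1), psi_het > 0, psi_hom > 0, tau >= 0)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!is.null(selection) &&
      !all(c("or_threshold", "max_n") %in% names(selection))) {
    stop("`selection` must be list(or_threshold = , max_n = )", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    p_i <- draw_scalar(p)
    nca <- as.integer(draw_scalar(n_cases, integer = TRUE))
    nco <- as.integer(draw_scalar(n_controls, integer = TRUE))
    psi_hom_i <- exp(log(psi_hom) + if (tau > 0) stats::rnorm(1, 0, tau) else 0)
    ctrl_probs <- hwe_genotype_probs(p_i)
    case_probs <- case_genotype_probs(ctrl_probs, psi_het, psi_hom_i)
    ctrl <- as.integer(stats::rmultinom(1L, nco, ctrl_probs))
    case <- as.integer(stats::rmultinom(1L, nca, case_probs))
    rows[[i]] <- data.frame(
      study_id = sprintf("sim%03d", i), first_author = "Synthetic",
      year = 2020L, country = "Simulated", ethnicity = "Mixed",
      cancer_type = "Synthetic", variant_id = variant_id,
      case_AA = case[1], case_Aa = case[2], case_aa = case[3],
      ctrl_AA = ctrl[1], ctrl_Aa = ctrl[2], ctrl_aa = ctrl[3],
      stringsAsFactors = FALSE
    )
  }
  corpus <- if (k == 0L) {
    empty <- .crp_corpus[0L, ]
    empty
  } else {
    do.call(rbind, rows)
  }

  if (!is.null(selection) && k > 0L) {
    cells <- cbind(
      a = corpus$case_aa, b = corpus$case_Aa + corpus$case_AA,
      c = corpus$ctrl_aa, d = corpus$ctrl_Aa + corpus$ctrl_AA)
    zero <- apply(cells == 0, 1L, any)
    cells[zero, ] <- cells[zero, ] + 0.5
    crude_or <- cells[, "a"] * cells[, "d"] / (cells[, "b"] * cells[, "c"])
    small <- (corpus$case_AA + corpus$case_Aa + corpus$case_aa) <=
      selection$max_n
    keep <- !small | crude_or > selection$or_threshold
    if (!any(keep)) {
      stop("selection rule censored every simulated study", call. = FALSE)
    }
    corpus <- corpus[keep, , drop = FALSE]
  }
  validate_studies(corpus)
}
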