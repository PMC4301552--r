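#' @keywords internal
"_PACKAGE"

# Canonical column order of a study corpus. Counts are per genotype:
# AA = common-allele homozygote, Aa = heterozygote, aa = variant homozygote.
CORPUS_COLUMNS <- c(
  "study_id", "first_author", "year", "country", "ethnicity", "cancer_type",
  "variant_id",
  "case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa"
)

COUNT_COLUMNS <- CORPUS_COLUMNS[8:13]

ETHNICITIES <- c("Caucasian", "African", "Asian", "Mixed")

title_case <- function(x) {
  s <- tolower(trimws(x))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' Validate a study corpus
#'
#' Checks a data frame of per-study case-control genotype counts against the
#' corpus schema: all required columns present, counts non-negative integers,
#' every study contributing at least one case and one control, study
#' identifiers unique, and ethnicity drawn from the closed set
#' Caucasian/African/Asian/Mixed (studies reporting several ethnicities are
#' conventionally labelled Mixed). Ethnicity and cancer-type labels are
#' normalized to title case so that subgrouping is robust to capitalization.
#'
#' @param studies data frame with columns `study_id`, `first_author`, `year`,
#'   `country`, `ethnicity`, `cancer_type`, `variant_id`, `case_AA`,
#'   `case_Aa`, `case_aa`, `ctrl_AA`, `ctrl_Aa`, `ctrl_aa`.
#' @return The validated corpus, with label columns normalized, count columns
#'   coerced to integer, and columns in canonical order.
#' @export
#' @examples
#' validate_studies(crp_studies("rs2808630"))
validate_studies <- function(studies) {
  if (!is.data.frame(studies)) {
    stop("`studies` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(CORPUS_COLUMNS, names(studies))
  if (length(missing_cols)) {
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  studies <- studies[, CORPUS_COLUMNS]
  rownames(studies) <- NULL
  studies$study_id <- as.character(studies$study_id)
  studies$first_author <- as.character(studies$first_author)
  studies$country <- as.character(studies$country)
  studies$variant_id <- as.character(studies$variant_id)
  studies$year <- as.integer(studies$year)
  studies$ethnicity <- title_case(studies$ethnicity)
  studies$cancer_type <- title_case(studies$cancer_type)
  if (nrow(studies) == 0L) {
    for (col in COUNT_COLUMNS) studies[[col]] <- integer(0)
    return(studies)
  }

  dup <- unique(studies$study_id[duplicated(studies$study_id)])
  if (length(dup)) {
    stop("duplicate study_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_eth <- setdiff(unique(studies$ethnicity), ETHNICITIES)
  if (length(bad_eth)) {
    stop("ethnicity must be one of ", paste(ETHNICITIES, collapse = "/"),
         "; got: ", paste(bad_eth, collapse = ", "), call. = FALSE)
  }
  for (col in COUNT_COLUMNS) {
    x <- studies[[col]]
    if (!is.numeric(x) || anyNA(x)) {
      stop("count column '", col, "' must be numeric and complete",
           call. = FALSE)
    }
    bad <- which(x < 0 | x != round(x))
    if (length(bad)) {
      stop("negative or non-integer count in '", col, "' for study ",
           paste(studies$study_id[bad], collapse = ", "), call. = FALSE)
    }
    studies[[col]] <- as.integer(round(x))
  }
  case_tot <- studies$case_AA + studies$case_Aa + studies$case_aa
  ctrl_tot <- studies$ctrl_AA + studies$ctrl_Aa + studies$ctrl_aa
  bad <- which(case_tot <= 0 | ctrl_tot <= 0)
  if (length(bad)) {
    stop("genotype totals must be positive in both arms; offending study: ",
         paste(studies$study_id[bad], collapse = ", "), call. = FALSE)
  }
  studies
}

#' Read a study corpus from delimited text
#'
#' Reads a comma- or tab-separated file of per-study genotype counts (one
#' header row, one row per study arm) and validates it with
#' [validate_studies()]. The separator is auto-detected from the header line
#' unless given.
#'
#' @param path path to a delimited text file, or a connection.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A validated corpus data frame; row order preserved.
#' @seealso [write_studies()] for the inverse operation.
#' @export
read_studies <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    if (!length(header)) stop("empty input: no header row", call. = FALSE)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           colClasses = "character")
  for (col in intersect(c("year", COUNT_COLUMNS), names(raw))) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    if (nrow(raw) && anyNA(x)) {
      stop("column '", col, "' contains non-numeric values", call. = FALSE)
    }
    raw[[col]] <- x
  }
  validate_studies(raw)
}

#' Write a study corpus to delimited text
#'
#' Emits the corpus schema with integer count fields written verbatim, so
#' that [read_studies()] round-trips a corpus bit-identically.
#'
#' @param studies a corpus data frame (validated on the way out).
#' @param path output file path or connection.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path, sep = ",") {
  studies <- validate_studies(studies)
  utils::write.table(studies, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Bundled corpus: published CRP polymorphism case-control studies
#'
#' Genotype counts from the published case-control studies of the CRP
#' single-nucleotide polymorphisms rs2808630 (3407 A>G; five study arms,
#' prostate/colorectal/lung cancer) and rs1417938 (29 A>T; six study arms).
#' One publication genotyped two ethnic strata separately; following the
#' source convention these enter as two study arms. Counts are stored exactly
#' as published, with the variant allele (G, respectively T) as the exposure.
#'
#' @param variant_id `"rs2808630"` or `"rs1417938"`.
#' @return A validated corpus data frame with 5 or 6 rows.
#' @export
#' @examples
#' total_counts(crp_studies("rs2808630"))  # 888 cases, 3167 controls
crp_studies <- function(variant_id = c("rs2808630", "rs1417938")) {
  variant_id <- as.character(variant_id)[1]
  if (!variant_id %in% c("rs2808630", "rs1417938")) {
    stop("unknown variant_id '", variant_id,
         "'; bundled variants are rs2808630 and rs1417938", call. = FALSE)
  }
  validate_studies(.crp_corpus[.crp_corpus$variant_id == variant_id, ])
}

.crp_corpus <- local({
  txt <- "study_id|first_author|year|country|ethnicity|cancer_type|variant_id|case_AA|case_Aa|case_aa|ctrl_AA|ctrl_Aa|ctrl_aa
pierce2009_cauc_rs2808630|Pierce|2009|USA|Caucasian|Prostate|rs2808630|89|73|13|1026|760|148
pierce2009_afr_rs2808630|Pierce|2009|USA|African|Prostate|rs2808630|24|16|0|184|107|9
tsilidis2009_rs2808630|Tsilidis|2009|USA|Caucasian|Colorectal|rs2808630|96|84|19|204|124|34
chaturvedi2010_rs2808630|Chaturvedi|2010|USA|Mixed|Lung|rs2808630|206|153|19|242|172|33
xu2012_rs2808630|Xu|2012|China|Asian|Lung|rs2808630|52|38|6|65|51|8
pierce2009_cauc_rs1417938|Pierce|2009|USA|Caucasian|Prostate|rs1417938|83|69|23|921|830|183
pierce2009_afr_rs1417938|Pierce|2009|USA|African|Prostate|rs1417938|31|8|1|230|66|4
tsilidis2009_rs1417938|Tsilidis|2009|USA|Caucasian|Colorectal|rs1417938|15|74|109|43|140|177
chaturvedi2010_rs1417938|Chaturvedi|2010|USA|Mixed|Lung|rs1417938|186|149|42|221|177|49
slattery2011_rs1417938|Slattery|2011|USA|Mixed|Colorectal|rs1417938|186|918|1120|238|1175|1373
xu2012_rs1417938|Xu|2012|China|Asian|Lung|rs1417938|49|38|9|59|50|15"
  utils::read.table(text = txt, sep = "|", header = TRUE,
                    stringsAsFactors = FALSE)
})

#' Total numbers of cases and controls in a corpus
#'
#' @param studies a corpus data frame.
#' @return Named integer vector `c(cases = ..., controls = ...)` summing all
#'   genotype counts over the case and control arms respectively.
#' @export
total_counts <- function(studies) {
  studies <- validate_studies(studies)
  if (nrow(studies) == 0L) {
    stop("`studies` must contain at least one study", call. = FALSE)
  }
  c(cases = sum(studies$case_AA + studies$case_Aa + studies$case_aa),
    controls = sum(studies$ctrl_AA + studies$ctrl_Aa + studies$ctrl_aa))
}
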