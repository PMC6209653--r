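#' @title Study-level data model and tabular IO
#' @description
#' One input row describes one study's genotype counts for one variant:
#' study metadata (author-year label, ethnicity, country, Newcastle-Ottawa
#' quality score) plus the six genotype counts (risk homozygote /
#' heterozygote / other homozygote, for cases and controls). Rows are
#' validated, harmonised to a single risk allele per variant, grouped by
#' variant, and overlapping cohorts marked via `superseded_by` are excluded
#' from analysis totals.
#' @name data_model_io
NULL

#' The five recognised ethnicity groups
#' @export
ETHNICITY_LEVELS <- c("European", "East Asian", "Latino", "West Asian",
                      "Mixed")

#' Expected input columns, in order
#' @export
INPUT_COLUMNS <- c("study_id", "author_year", "ethnicity", "country", "nos",
                   "variant_id", "risk_allele", "other_allele",
                   "case_hom_risk", "case_het", "case_hom_other",
                   "ctrl_hom_risk", "ctrl_het", "ctrl_hom_other")

OPTIONAL_COLUMNS <- c("superseded_by", "af_gnomad")

COUNT_COLUMNS <- c("case_hom_risk", "case_het", "case_hom_other",
                   "ctrl_hom_risk", "ctrl_het", "ctrl_hom_other")

#' Construct and validate one study record
#'
#' @param study_id Opaque study identifier, unique within a variant.
#' @param author_year Label such as `"2006Mizuta I"`.
#' @param ethnicity One of [ETHNICITY_LEVELS].
#' @param country Country name (used for country subgrouping).
#' @param nos Newcastle-Ottawa Scale score, integer 0-9 (metadata only).
#' @param variant_id rsID of the variant.
#' @param risk_allele,other_allele Single-character allele symbols; must
#'   differ.
#' @param case_counts,control_counts Genotype triples
#'   (hom_risk, het, hom_other), see [genotype_counts()].
#' @param superseded_by Optional study_id of a later study on an
#'   overlapping cohort; a record named here is excluded from analysis.
#' @param af_gnomad Optional externally supplied general-population allele
#'   frequency (annotation pass-through, never computed).
#' @return A list of class `study_record`.
#' @export
study_record <- function(study_id, author_year, ethnicity, country, nos,
                         variant_id, risk_allele, other_allele,
                         case_counts, control_counts,
                         superseded_by = NA_character_,
                         af_gnomad = NA_real_) {
  if (!ethnicity %in% ETHNICITY_LEVELS) {
    stop(sprintf("unknown ethnicity '%s'", ethnicity), call. = FALSE)
  }
  if (!is.na(nos) && (nos < 0 || nos > 9 || nos != round(nos))) {
    stop("nos must be an integer between 0 and 9", call. = FALSE)
  }
  if (identical(risk_allele, other_allele)) {
    stop("risk and other allele must differ", call. = FALSE)
  }
  structure(list(
    study_id = as.character(study_id), author_year = author_year,
    ethnicity = ethnicity, country = country, nos = as.integer(nos),
    variant_id = variant_id,
    risk_allele = risk_allele, other_allele = other_allele,
    case_counts = as_genotype_counts(case_counts),
    control_counts = as_genotype_counts(control_counts),
    superseded_by = superseded_by, af_gnomad = af_gnomad),
    class = "study_record")
}

validate_row <- function(row, i) {
  problems <- character()
  counts <- suppressWarnings(as.numeric(row[COUNT_COLUMNS]))
  if (any(is.na(counts))) {
    problems <- c(problems, "non-numeric genotype count")
  } else {
    if (any(counts < 0)) problems <- c(problems, "negative genotype count")
    if (any(counts != round(counts))) {
      problems <- c(problems, "non-integer genotype count")
    }
    if (!any(is.na(counts))) {
      if (sum(counts[1:3]) < 1) problems <- c(problems, "empty case arm")
      if (sum(counts[4:6]) < 1) problems <- c(problems, "empty control arm")
    }
  }
  if (!row[["ethnicity"]] %in% ETHNICITY_LEVELS) {
    problems <- c(problems,
                  sprintf("unknown ethnicity '%s'", row[["ethnicity"]]))
  }
  if (identical(row[["risk_allele"]], row[["other_allele"]])) {
    problems <- c(problems, "risk allele equals other allele")
  }
  if (length(problems) == 0) return(NULL)
  sprintf("row %d (study_id=%s, variant=%s): %s", i,
          row[["study_id"]], row[["variant_id"]],
          paste(problems, collapse = "; "))
}

#' Read and validate a study-level genotype count table
#'
#' Reads the tab- (or comma-) separated input, validates every row,
#' harmonises allele orientation within each variant to the risk allele of
#' the first accepted row (flipped rows have their genotype triples
#' reversed), excludes records superseded by an overlapping cohort, and
#' groups the remainder by variant.
#'
#' @param path Input file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A list of class `variant_collection`: one element per variant,
#'   each a list of class `variant_dataset` with `variant_id`,
#'   `risk_allele`, `other_allele` and `records` (a data frame of accepted,
#'   analysis-eligible rows with a logical `flipped` column). Attributes:
#'   `rejected` (character vector of row-addressed messages), `superseded`
#'   (data frame of excluded overlapping-cohort rows), `n_input`,
#'   `n_accepted`.
#' @export
read_dataset <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(INPUT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in OPTIONAL_COLUMNS) if (!col %in% names(df)) df[[col]] <- NA
  if (nrow(df) == 0) {
    warning("input file contains a valid header but no data rows")
    return(structure(list(), class = "variant_collection",
                     rejected = character(), superseded = df,
                     n_input = 0L, n_accepted = 0L))
  }

  rejected <- character()
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    msg <- validate_row(as.list(df[i, ]), i)
    if (is.null(msg)) ok[i] <- TRUE else rejected <- c(rejected, msg)
  }
  if (length(rejected) > 0) {
    warning(sprintf("rejected %d row(s):\n%s", length(rejected),
                    paste(rejected, collapse = "\n")))
  }
  acc <- df[ok, , drop = FALSE]
  for (col in COUNT_COLUMNS) acc[[col]] <- as.integer(acc[[col]])
  acc$nos <- suppressWarnings(as.integer(acc$nos))
  acc$af_gnomad <- suppressWarnings(as.numeric(acc$af_gnomad))
  acc$superseded_by[acc$superseded_by %in% c("", "NA")] <- NA

  # duplicate study_id within a variant: keep the first, reject the rest
  dup <- duplicated(acc[, c("variant_id", "study_id")])
  if (any(dup)) {
    msgs <- sprintf("duplicate study_id %s for variant %s",
                    acc$study_id[dup], acc$variant_id[dup])
    warning(paste(msgs, collapse = "\n"))
    rejected <- c(rejected, msgs)
    acc <- acc[!dup, , drop = FALSE]
  }

  # overlapping cohorts: exclude any record named in a superseded_by field
  # of another record for the same variant
  superseded_idx <- logical(nrow(acc))
  for (v in unique(acc$variant_id)) {
    in_v <- acc$variant_id == v
    named <- stats::na.omit(acc$superseded_by[in_v])
    superseded_idx[in_v] <- acc$study_id[in_v] %in% named
  }
  superseded <- acc[superseded_idx, , drop = FALSE]
  acc <- acc[!superseded_idx, , drop = FALSE]

  datasets <- list()
  for (v in unique(acc$variant_id)) {
    rows <- acc[acc$variant_id == v, , drop = FALSE]
    ref_risk <- rows$risk_allele[1]
    ref_other <- rows$other_allele[1]
    flipped <- rows$risk_allele != ref_risk
    bad <- flipped & (rows$risk_allele != ref_other |
                        rows$other_allele != ref_risk)
    if (any(bad)) {
      msgs <- sprintf(
        "variant %s study %s: alleles %s/%s incompatible with %s/%s",
        v, rows$study_id[bad], rows$risk_allele[bad],
        rows$other_allele[bad], ref_risk, ref_other)
      warning(paste(msgs, collapse = "\n"))
      rejected <- c(rejected, msgs)
      rows <- rows[!bad, , drop = FALSE]
      flipped <- flipped[!bad]
      if (nrow(rows) == 0) next
    }
    if (any(flipped)) {
      swap <- function(x, y, f) {
        tmp <- x[f]; x[f] <- y[f]; y[f] <- tmp
        list(x, y)
      }
      s <- swap(rows$case_hom_risk, rows$case_hom_other, flipped)
      rows$case_hom_risk <- s[[1]]; rows$case_hom_other <- s[[2]]
      s <- swap(rows$ctrl_hom_risk, rows$ctrl_hom_other, flipped)
      rows$ctrl_hom_risk <- s[[1]]; rows$ctrl_hom_other <- s[[2]]
      rows$risk_allele <- ref_risk
      rows$other_allele <- ref_other
    }
    rows$flipped <- flipped
    datasets[[v]] <- structure(
      list(variant_id = v, risk_allele = ref_risk, other_allele = ref_other,
           records = rows),
      class = "variant_dataset")
  }
  datasets <- datasets[order(names(datasets))]
  structure(datasets, class = "variant_collection",
            rejected = rejected, superseded = superseded,
            n_input = nrow(df), n_accepted = sum(vapply(
              datasets, function(d) nrow(d$records), integer(1))))
}

#' Write a study-level genotype count table
#'
#' Inverse of [read_dataset()] for simulated or programmatically built data
#' frames using the documented column schema.
#'
#' @param records Data frame with the [INPUT_COLUMNS] (optional columns
#'   allowed).
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_dataset <- function(records, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  cols <- c(INPUT_COLUMNS, intersect(OPTIONAL_COLUMNS, names(records)))
  utils::write.table(records[, cols], path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Presentation floor for small p-values
#'
#' Values below the floor are displayed as `"<0.00001"`; classification and
#' all stored numeric columns always use the raw double.
#'
#' @param p Numeric p-value(s).
#' @param floor Display floor (default 1e-5).
#' @return Character vector.
#' @export
format_p <- function(p, floor = 1e-5) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < floor) sprintf("<%s", format(floor, scientific = FALSE))
    else format(pi, digits = 3, scientific = FALSE)
  }, character(1))
}

RESULT_NUMERIC <- c("k", "pooled_or", "ci_low", "ci_high", "z", "p", "Q",
                    "df", "p_Q", "i_squared", "tau_squared", "af_cases",
                    "af_controls", "af_population")

#' Write pooled results with classification to TSV or JSON
#'
#' One row per variant x group x genetic model. Numeric columns are
#' serialized at full precision; a separate `p_display` column applies the
#' `"<0.00001"` floor convention for presentation.
#'
#' @param results Result data frame as produced by [run_pipeline()] or
#'   [results_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(results) || nrow(results) == 0) {
    stop("results must be non-empty", call. = FALSE)
  }
  results$p_display <- format_p(results$p)
  if (format == "tsv") {
    num <- intersect(RESULT_NUMERIC, names(results))
    out <- results
    for (col in num) out[[col]] <- format(out[[col]], digits = 17,
                                          scientific = TRUE, trim = TRUE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return Data frame with numeric columns restored to doubles.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            na.strings = "NA")
    for (col in intersect(RESULT_NUMERIC, names(df))) {
      df[[col]] <- as.numeric(df[[col]])
    }
    df
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
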