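#' Published overall allele-model summary for 16 SNCA variants
#'
#' Loads the packaged table of published overall-population allele-model
#' summary estimates for 16 synuclein-gene (SNCA) variants tested for
#' association with Parkinson's disease: pooled odds ratio, 95 percent
#' confidence interval, the printed p-value (with the `"<0.00001"` floor
#' convention), and risk-allele frequencies in patients, controls, and a
#' general-population reference. Printed p-values below the floor are
#' left-censored: for them only the bound, not the exact value, is known.
#'
#' @return Data frame with columns `variant_id`, `risk_allele`,
#'   `pooled_or`, `ci_low`, `ci_high`, `p_display`, `p_upper` (the printed
#'   value, or the censoring bound), `p_censored` (logical), `af_cases`,
#'   `af_controls`, `af_population`.
#' @export
snca_reference <- function() {
  path <- system.file("extdata", "snca_overall_allele_meta.tsv",
                      package = "genemeta")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$p_censored <- startsWith(df$p_display, "<")
  df$p_upper <- as.numeric(sub("^<", "", df$p_display))
  df
}

#' Classify published summary rows
#'
#' Applies the two-tier classification to a table of printed summary
#' estimates, honouring left-censored p-values: a value printed as below a
#' bound is treated as strictly below it, which determines the tier
#' whenever the bound does not exceed the cutoff being tested.
#'
#' @param reference Data frame as returned by [snca_reference()].
#' @param tier1,tier2 Classification cutoffs (see [classify()]).
#' @return The input with `tier` and `direction` columns appended.
#' @export
classify_printed <- function(reference, tier1 = 0.05, tier2 = 1e-5) {
  stopifnot(all(c("p_upper", "p_censored", "pooled_or") %in%
                  names(reference)))
  if (any(reference$p_censored & reference$p_upper > tier2)) {
    stop("censored p-value with bound above tier2: tier undetermined",
         call. = FALSE)
  }
  # a censored "<bound" value is strictly below its bound
  p_eff <- ifelse(reference$p_censored,
                  reference$p_upper * (1 - 1e-9), reference$p_upper)
  cls <- lapply(seq_len(nrow(reference)), function(i) {
    classify(list(variant_id = reference$variant_id[i], group = "overall",
                  p = p_eff[i], pooled_or = reference$pooled_or[i]),
             tier1 = tier1, tier2 = tier2)
  })
  reference$tier <- vapply(cls, `[[`, character(1), "tier")
  reference$direction <- vapply(cls, `[[`, character(1), "direction")
  reference
}
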