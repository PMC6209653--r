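#' @title Variant-screening meta-analysis pipeline
#' @description
#' Orchestrates the full procedure: eligibility filtering (at least four
#' studies per variant for the overall pooled analysis), allele-model
#' pooling per group with heterogeneity-driven method selection, two-tier
#' significance classification (screening recommendation), dominant /
#' recessive decomposition attributing effects to heterozygotes or
#' homozygotes, and counts-weighted allele-frequency summaries.
#' @name pipeline
NULL

group_rows <- function(records, group) {
  if (group == "overall") return(records)
  if (startsWith(group, "country:")) {
    return(records[records$country == sub("^country:", "", group), ,
                   drop = FALSE])
  }
  records[records$ethnicity == group, , drop = FALSE]
}

record_tables <- function(records, model) {
  lapply(seq_len(nrow(records)), function(i) {
    model_table(
      c(records$case_hom_risk[i], records$case_het[i],
        records$case_hom_other[i]),
      c(records$ctrl_hom_risk[i], records$ctrl_het[i],
        records$ctrl_hom_other[i]),
      model = model)
  })
}

#' Variants eligible for pooled analysis
#'
#' A variant enters the pooled analysis only if at least `min_studies`
#' accepted, non-superseded studies report it.
#'
#' @param datasets A `variant_collection` from [read_dataset()] or a list of
#'   `variant_dataset` objects.
#' @param min_studies Minimum number of studies (default 4).
#' @return Character vector of variant IDs, lexicographically sorted.
#' @export
eligible_variants <- function(datasets, min_studies = 4) {
  if (length(datasets) == 0) return(character())
  k <- vapply(datasets, function(d) nrow(d$records), integer(1))
  sort(names(datasets)[k >= min_studies])
}

groups_for <- function(records, grouping) {
  switch(grouping,
         overall = "overall",
         by_ethnicity = sort(unique(records$ethnicity)),
         by_country = paste0("country:", sort(unique(records$country))),
         stop(sprintf("unknown grouping '%s'", grouping), call. = FALSE))
}

#' Pool one variant within one group under one genetic model
#'
#' @param dataset A `variant_dataset`.
#' @param group `"overall"`, an ethnicity name, or `"country:<name>"`.
#' @param model Genetic model.
#' @param method Pooling method passed to [pool_tables()].
#' @return A `pooled_result` with identity fields filled, or `NULL` if the
#'   group is empty.
#' @export
pool_variant <- function(dataset, group = "overall",
                         model = c("allele", "dominant", "recessive"),
                         method = "auto") {
  model <- match.arg(model)
  rows <- group_rows(dataset$records, group)
  if (nrow(rows) == 0) return(NULL)
  res <- pool_tables(record_tables(rows, model), rows$study_id,
                     method = method)
  res$variant_id <- dataset$variant_id
  res$group <- group
  res$genetic_model <- model
  res
}

#' Grouped meta-analysis across variants
#'
#' Runs the pooled analysis for every variant in `datasets` under the given
#' grouping and genetic model. Within subgroups, a result is only produced
#' when the subgroup holds at least `subgroup_min_studies` studies; thinner
#' subgroups are silently omitted (they are logged as messages).
#'
#' @param datasets A `variant_collection` (eligibility should already have
#'   been applied for the overall analysis, see [eligible_variants()]).
#' @param grouping `"overall"`, `"by_ethnicity"` or `"by_country"`.
#' @param model Genetic model.
#' @param subgroup_min_studies Minimum studies per subgroup (default 2).
#' @return List of `pooled_result` objects.
#' @export
run_group_meta <- function(datasets,
                           grouping = c("overall", "by_ethnicity",
                                        "by_country"),
                           model = c("allele", "dominant", "recessive"),
                           subgroup_min_studies = 2) {
  grouping <- match.arg(grouping)
  model <- match.arg(model)
  out <- list()
  for (d in datasets) {
    for (g in groups_for(d$records, grouping)) {
      rows <- group_rows(d$records, g)
      if (g != "overall" && nrow(rows) < subgroup_min_studies) {
        message(sprintf("omitting %s / %s: only %d stud%s", d$variant_id, g,
                        nrow(rows), if (nrow(rows) == 1) "y" else "ies"))
        next
      }
      out[[length(out) + 1]] <- pool_variant(d, g, model)
    }
  }
  out
}

#' Two-tier screening classification of a pooled result
#'
#' The allele-model p-value is compared against two strict cutoffs: below
#' `tier2` (default 1e-5, the floor of the tool the procedure emulates) the
#' variant is "most recommended" for genetic screening; below `tier1`
#' (default 0.05) it is "recommended"; otherwise "not recommended".
#' Direction is read off the pooled odds ratio (risk if above 1) and is
#' reported only for recommended tiers.
#'
#' @param result A `pooled_result` (allele model), or a list with numeric
#'   `p` and `pooled_or` fields.
#' @param tier1,tier2 Significance cutoffs, `tier2 < tier1`.
#' @return A list of class `classification_result` with `variant_id`,
#'   `group`, `tier`, `direction` and `contribution` (initially
#'   `"not_assessed"`).
#' @export
classify <- function(result, tier1 = 0.05, tier2 = 1e-5) {
  stopifnot(tier2 < tier1)
  p <- result$p
  tier <- if (p < tier2) "most_recommended"
          else if (p < tier1) "recommended"
          else "not_recommended"
  direction <- if (tier == "not_recommended") "none"
               else if (result$pooled_or > 1) "risk"
               else if (result$pooled_or < 1) "protective"
               else "none"
  structure(list(variant_id = result$variant_id, group = result$group,
                 tier = tier, direction = direction,
                 contribution = "not_assessed"),
            class = "classification_result")
}

#' Attribute a most-recommended variant's effect to genotype classes
#'
#' Runs the dominant and recessive pooled analyses for the variant within
#' the group and calls the contribution: dominant-only significance (at
#' `tier2`) implicates heterozygotes, recessive-only implicates risk-allele
#' homozygotes, both models significant implicates both, neither implicates
#' neither. Only meaningful for variants already classified as most
#' recommended on the allele model (enforced by [run_pipeline()]).
#'
#' @param dataset A `variant_dataset`.
#' @param group Group label.
#' @param tier2 Significance cutoff for the dominant/recessive models.
#' @return List with `contribution` plus the `dominant` and `recessive`
#'   `pooled_result` objects.
#' @export
decompose_contributions <- function(dataset, group = "overall",
                                    tier2 = 1e-5) {
  dom <- pool_variant(dataset, group, "dominant")
  rec <- pool_variant(dataset, group, "recessive")
  dom_sig <- !is.null(dom) && dom$p < tier2
  rec_sig <- !is.null(rec) && rec$p < tier2
  contribution <- if (dom_sig && rec_sig) "both"
                  else if (dom_sig) "heterozygote"
                  else if (rec_sig) "homozygote"
                  else "neither"
  list(contribution = contribution, dominant = dom, recessive = rec)
}

#' Counts-weighted pooled allele frequencies
#'
#' Pools risk-allele frequencies across a group's studies by total allele
#' counts (not by averaging per-study frequencies). The general-population
#' frequency, when present in the input annotation, is passed through
#' unchanged (first non-missing value).
#'
#' @param dataset A `variant_dataset`.
#' @param group Group label.
#' @return A list of class `af_summary` with `variant_id`, `group`,
#'   `af_cases`, `af_controls`, `af_population`.
#' @export
pooled_af <- function(dataset, group = "overall") {
  rows <- group_rows(dataset$records, group)
  if (nrow(rows) == 0) stop("no studies in group", call. = FALSE)
  case_risk <- sum(2 * rows$case_hom_risk + rows$case_het)
  case_tot <- 2 * sum(rows$case_hom_risk + rows$case_het +
                        rows$case_hom_other)
  ctrl_risk <- sum(2 * rows$ctrl_hom_risk + rows$ctrl_het)
  ctrl_tot <- 2 * sum(rows$ctrl_hom_risk + rows$ctrl_het +
                        rows$ctrl_hom_other)
  afg <- rows$af_gnomad[!is.na(rows$af_gnomad)]
  structure(list(variant_id = dataset$variant_id, group = group,
                 af_cases = case_risk / case_tot,
                 af_controls = ctrl_risk / ctrl_tot,
                 af_population = if (length(afg)) afg[1] else NA_real_),
            class = "af_summary")
}

#' Bonferroni-adjusted cutoff utility
#'
#' Provided for completeness; the pipeline's classification deliberately
#' uses the two-tier scheme rather than formal multiplicity adjustment.
#'
#' @param alpha Family-wise level.
#' @param m Number of tests.
#' @return Per-test cutoff `alpha / m`.
#' @export
bonferroni_cutoff <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

result_row <- function(res) {
  data.frame(variant_id = res$variant_id, group = res$group,
             genetic_model = res$genetic_model, method = res$method,
             k = res$k, pooled_or = res$pooled_or, ci_low = res$ci_low,
             ci_high = res$ci_high, z = res$z, p = res$p, Q = res$Q,
             df = res$df, p_Q = res$p_Q, i_squared = res$i_squared,
             tau_squared = res$tau_squared,
             stringsAsFactors = FALSE)
}

#' Flatten pooled results into a data frame
#'
#' @param results List of `pooled_result` objects (or a single one).
#' @return Data frame, one row per result.
#' @export
results_table <- function(results) {
  if (inherits(results, "pooled_result")) results <- list(results)
  do.call(rbind, lapply(results, result_row))
}

#' Run the complete screening meta-analysis
#'
#' Applies eligibility, runs the allele-model pooled analysis overall and
#' within the requested subgroupings, classifies every result into the
#' two-tier screening recommendation, decomposes most-recommended variants
#' into dominant/recessive contributions, and attaches pooled allele
#' frequencies.
#'
#' @param datasets A `variant_collection` from [read_dataset()].
#' @param groupings Subset of `c("overall", "by_ethnicity", "by_country")`.
#' @param tier1,tier2 Classification cutoffs.
#' @param min_studies Eligibility threshold for the pooled analysis
#'   (default 4 studies).
#' @param subgroup_min_studies Minimum studies per subgroup (default 2).
#' @param apply_min_to_subgroups If TRUE, subgroups are also held to
#'   `min_studies`; by default only `subgroup_min_studies` applies.
#' @return A list of class `genemeta_run`:
#'   \describe{
#'     \item{results}{allele-model data frame: pooled statistics plus
#'       `af_cases`, `af_controls`, `af_population`, `tier`, `direction`,
#'       `contribution`.}
#'     \item{contributions}{dominant/recessive data frame for
#'       most-recommended variant x group pairs.}
#'     \item{eligible}{variant IDs that passed eligibility.}
#'     \item{excluded}{variant IDs that failed eligibility.}
#'     \item{params}{the thresholds used.}
#'   }
#' @export
run_pipeline <- function(datasets,
                         groupings = c("overall", "by_ethnicity"),
                         tier1 = 0.05, tier2 = 1e-5,
                         min_studies = 4, subgroup_min_studies = 2,
                         apply_min_to_subgroups = FALSE) {
  groupings <- match.arg(groupings,
                         c("overall", "by_ethnicity", "by_country"),
                         several.ok = TRUE)
  elig <- eligible_variants(datasets, min_studies)
  excluded <- setdiff(sort(names(datasets)), elig)
  datasets <- datasets[elig]
  sub_min <- if (apply_min_to_subgroups) max(min_studies,
                                             subgroup_min_studies)
             else subgroup_min_studies

  pooled <- list()
  for (g in groupings) {
    pooled <- c(pooled, run_group_meta(datasets, g, "allele",
                                       subgroup_min_studies = sub_min))
  }
  if (length(pooled) == 0) {
    return(structure(list(results = NULL, contributions = NULL,
                          eligible = elig, excluded = excluded,
                          params = list(tier1 = tier1, tier2 = tier2,
                                        min_studies = min_studies,
                                        subgroup_min_studies = sub_min)),
                     class = "genemeta_run"))
  }

  rows <- list()
  contrib_rows <- list()
  for (res in pooled) {
    cls <- classify(res, tier1, tier2)
    af <- pooled_af(datasets[[res$variant_id]], res$group)
    row <- result_row(res)
    row$af_cases <- af$af_cases
    row$af_controls <- af$af_controls
    row$af_population <- af$af_population
    row$tier <- cls$tier
    row$direction <- cls$direction
    if (cls$tier == "most_recommended") {
      dec <- decompose_contributions(datasets[[res$variant_id]], res$group,
                                     tier2)
      row$contribution <- dec$contribution
      for (m in c("dominant", "recessive")) {
        if (!is.null(dec[[m]])) {
          contrib_rows[[length(contrib_rows) + 1]] <- result_row(dec[[m]])
        }
      }
    } else {
      row$contribution <- "not_assessed"
    }
    rows[[length(rows) + 1]] <- row
  }
  results <- do.call(rbind, rows)
  contributions <- if (length(contrib_rows)) do.call(rbind, contrib_rows)
                   else NULL
  structure(list(results = results, contributions = contributions,
                 eligible = elig, excluded = excluded,
                 params = list(tier1 = tier1, tier2 = tier2,
                               min_studies = min_studies,
                               subgroup_min_studies = sub_min)),
            class = "genemeta_run")
}

#' @export
print.genemeta_run <- function(x, ...) {
  cat(sprintf("genemeta run: %d eligible variant(s), %d excluded\n",
              length(x$eligible), length(x$excluded)))
  if (!is.null(x$results)) {
    ov <- x$results[x$results$group == "overall", ]
    tiers <- table(factor(ov$tier, levels = c("most_recommended",
                                              "recommended",
                                              "not_recommended")))
    cat(sprintf("overall: %d most recommended, %d recommended, %d not recommended\n",
                tiers[1], tiers[2], tiers[3]))
  }
  invisible(x)
}
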