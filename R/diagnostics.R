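#' @title Sensitivity and publication-bias diagnostics
#' @description
#' Leave-one-out sensitivity analysis (re-pooling with each study deleted
#' in turn, including re-selection of the fixed/random method) and
#' publication-bias assessment via exported funnel-plot coordinates and
#' Egger's regression test for funnel asymmetry.
#' @name diagnostics
NULL

#' Leave-one-out sensitivity analysis
#'
#' Re-runs the full pooling (including heterogeneity-driven method
#' re-selection) k times, each time omitting one study. The pooled estimate
#' is called stable when every leave-one-out odds ratio stays on the same
#' side of 1 as the baseline and deviates from it by at most
#' `stability_tolerance` in relative terms.
#'
#' @param dataset A `variant_dataset`.
#' @param group Group label (see [pool_variant()]).
#' @param model Genetic model.
#' @param stability_tolerance Maximum relative change in the pooled OR still
#'   considered stable (default 0.2 = 20 percent; reported, never silently
#'   applied).
#' @return A list of class `sensitivity_report`: `variant_id`, `group`,
#'   `baseline_or`, `loo` (data frame with `left_out`, `pooled_or`,
#'   `ci_low`, `ci_high`, `p`, `method`), `or_range`, `stable`.
#' @export
leave_one_out <- function(dataset, group = "overall",
                          model = c("allele", "dominant", "recessive"),
                          stability_tolerance = 0.2) {
  model <- match.arg(model)
  rows <- group_rows(dataset$records, group)
  k <- nrow(rows)
  if (k < 2) stop("sensitivity undefined: fewer than 2 studies",
                  call. = FALSE)
  tables <- record_tables(rows, model)
  baseline <- pool_tables(tables, rows$study_id)
  loo <- lapply(seq_len(k), function(i) {
    res <- pool_tables(tables[-i], rows$study_id[-i])
    data.frame(left_out = rows$study_id[i], pooled_or = res$pooled_or,
               ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
               method = res$method, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, loo)
  or_range <- range(loo$pooled_or)
  same_side <- all(sign(log(loo$pooled_or)) == sign(log(baseline$pooled_or))) ||
    baseline$pooled_or == 1
  rel_change <- abs(loo$pooled_or - baseline$pooled_or) / baseline$pooled_or
  structure(list(variant_id = dataset$variant_id, group = group,
                 genetic_model = model,
                 baseline_or = baseline$pooled_or, loo = loo,
                 or_range = or_range,
                 stable = same_side && all(rel_change <= stability_tolerance),
                 stability_tolerance = stability_tolerance),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out for %s / %s: baseline OR %.4f, range [%.4f, %.4f], %s\n",
    x$variant_id, x$group, x$baseline_or, x$or_range[1], x$or_range[2],
    if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' Plot-ready (log OR, SE) pairs, one per informative study, ordered by
#' standard error ascending (most precise studies first, i.e. from the top
#' of the funnel downwards).
#'
#' @param effects List of `effect_estimate` objects.
#' @return Data frame with `study_id`, `log_or`, `se`.
#' @export
funnel_data <- function(effects) {
  if (length(effects) == 0) {
    return(data.frame(study_id = character(), log_or = numeric(),
                      se = numeric(), stringsAsFactors = FALSE))
  }
  em <- effects_matrix(effects)
  ord <- order(em$se)
  data.frame(study_id = em$ids[ord], log_or = em$y[ord], se = em$se[ord],
             stringsAsFactors = FALSE)
}

#' Write funnel coordinates to CSV
#'
#' @param effects List of `effect_estimate` objects.
#' @param path Output path.
#' @export
write_funnel_csv <- function(effects, path) {
  utils::write.csv(funnel_data(effects), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect (log OR / SE) on precision (1 / SE) by
#' ordinary least squares; under symmetry the intercept is zero. The
#' intercept is tested with a t statistic on k - 2 degrees of freedom. This
#' is the standard quantitative surrogate for visual funnel-plot symmetry
#' assessment.
#'
#' @param effects List of `effect_estimate` objects, at least 3.
#' @return A list of class `egger_result` with `intercept`, `intercept_se`,
#'   `slope`, `t_statistic`, `p`, `k`.
#' @export
egger_test <- function(effects) {
  em <- effects_matrix(effects)
  if (em$k < 3) stop("Egger test requires at least 3 studies",
                     call. = FALSE)
  z <- em$y / em$se
  prec <- 1 / em$se
  if (stats::sd(prec) < .Machine$double.eps^0.5) {
    # constant precision: the slope is unidentifiable, so the funnel is
    # decomposed as pure effect (line through the origin) and the residual
    # scatter of z carries all asymmetry evidence; with exactly equal
    # effects the intercept is exactly 0
    slope <- mean(z) / prec[1]
    resid <- z - mean(z)
    return(structure(list(intercept = 0,
                          intercept_se = stats::sd(z) / sqrt(em$k),
                          slope = slope,
                          t_statistic = 0, p = 1, k = em$k),
                     class = "egger_result"))
  }
  fit <- stats::lm(z ~ prec)
  coefs <- summary(fit)$coefficients
  intercept <- coefs[1, 1]
  intercept_se <- coefs[1, 2]
  t_stat <- intercept / intercept_se
  structure(list(intercept = intercept, intercept_se = intercept_se,
                 slope = coefs[2, 1], t_statistic = t_stat,
                 p = 2 * stats::pt(abs(t_stat), df = em$k - 2,
                                   lower.tail = FALSE),
                 k = em$k),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger test (k = %d): intercept %.4f (SE %.4f), t = %.3f, p = %.4f\n",
              x$k, x$intercept, x$intercept_se, x$t_statistic, x$p))
  invisible(x)
}

#' Per-study effects for a variant within a group
#'
#' Convenience bridge from a `variant_dataset` to the effect list consumed
#' by [funnel_data()] and [egger_test()].
#'
#' @param dataset A `variant_dataset`.
#' @param group Group label.
#' @param model Genetic model.
#' @return List of `effect_estimate` objects.
#' @export
dataset_effects <- function(dataset, group = "overall",
                            model = c("allele", "dominant", "recessive")) {
  model <- match.arg(model)
  rows <- group_rows(dataset$records, group)
  tables <- record_tables(rows, model)
  mapply(study_effect, tables, rows$study_id, SIMPLIFY = FALSE)
}
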