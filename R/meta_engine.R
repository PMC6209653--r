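#' @title Per-study and pooled effect estimation
#' @description
#' The engine mirrors the defaults of standard meta-analysis software for
#' dichotomous outcomes: per-study odds ratios with Woolf standard errors,
#' Mantel-Haenszel fixed-effects pooling with the Robins-Breslow-Greenland
#' variance, DerSimonian-Laird random-effects pooling on inverse-variance
#' log odds ratios, and Cochran's Q / I-squared heterogeneity statistics.
#' @name meta_engine
NULL

correct_cells <- function(table) {
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

is_informative <- function(table) {
  !((table$a == 0 && table$c == 0) || (table$b == 0 && table$d == 0))
}

#' Per-study log odds ratio with Woolf standard error
#'
#' Computes the crude odds ratio ad/bc of a 2x2 table together with the
#' Woolf standard error sqrt(1/a + 1/b + 1/c + 1/d) of its logarithm. If any
#' cell is zero, 0.5 is added to all four cells first (continuity
#' correction) and the estimate is flagged as corrected. Tables in which
#' both exposed cells or both unexposed cells are zero carry no information
#' about the odds ratio and are returned as excluded sentinels, never NaN.
#'
#' @param table A `contingency_table`.
#' @param study_id Optional study identifier carried into the estimate.
#' @return An object of class `effect_estimate`: a list with `study_id`,
#'   `log_or`, `se`, `or_value`, `weight` (inverse-variance, 1/se^2),
#'   `corrected`, and `excluded` (TRUE for non-informative tables, in which
#'   case the numeric fields are NA).
#' @examples
#' study_effect(new_table(20, 10, 10, 20))  # OR = 4
#' @export
study_effect <- function(table, study_id = NA_character_) {
  stopifnot(inherits(table, "contingency_table"))
  if (!is_informative(table)) {
    return(structure(list(study_id = study_id, log_or = NA_real_,
                          se = NA_real_, or_value = NA_real_,
                          weight = NA_real_, corrected = FALSE,
                          excluded = TRUE),
                     class = "effect_estimate"))
  }
  cc <- correct_cells(table)
  a <- cc$cells[1]; b <- cc$cells[2]; c <- cc$cells[3]; d <- cc$cells[4]
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(study_id = study_id, log_or = log_or, se = se,
                 or_value = exp(log_or), weight = 1 / se^2,
                 corrected = cc$corrected, excluded = FALSE),
            class = "effect_estimate")
}

#' Construct a bare 2x2 table
#'
#' Convenience constructor used when genotype counts are not involved, e.g.
#' in tests and worked examples. `a`/`b` are case exposed/unexposed counts,
#' `c`/`d` the control counts.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param unit Count unit label.
#' @return A `contingency_table`.
#' @export
new_table <- function(a, b, c, d, unit = "persons") {
  if (any(c(a, b, c, d) < 0)) stop("cells must be non-negative", call. = FALSE)
  if (a + b <= 0 || c + d <= 0) {
    stop("each arm must contain at least one observation", call. = FALSE)
  }
  new_contingency_table(a, b, c, d, unit = unit)
}

effects_matrix <- function(effects) {
  effects <- effects[!vapply(effects, `[[`, logical(1), "excluded")]
  y <- vapply(effects, `[[`, numeric(1), "log_or")
  se <- vapply(effects, `[[`, numeric(1), "se")
  ids <- vapply(effects, `[[`, character(1), "study_id")
  list(y = y, se = se, w = 1 / se^2, ids = ids, k = length(y))
}

#' Two-sided Wald test for a log odds ratio
#'
#' @param log_or Log odds ratio.
#' @param se Standard error of `log_or`.
#' @return A list with the z statistic and the two-sided normal p-value.
#' @export
wald_p <- function(log_or, se) {
  z <- log_or / se
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

new_pooled_result <- function(method, k, log_or, se, Q, df, p_Q, i_squared,
                              tau_squared, corrected_any = FALSE) {
  wp <- wald_p(log_or, se)
  structure(list(
    variant_id = NA_character_, group = NA_character_,
    genetic_model = NA_character_,
    method = method, k = k,
    pooled_or = exp(log_or), log_or = log_or, se = se,
    ci_low = exp(log_or - 1.96 * se), ci_high = exp(log_or + 1.96 * se),
    z = wp$z, p = wp$p,
    Q = Q, df = df, p_Q = p_Q, i_squared = i_squared,
    tau_squared = tau_squared, corrected_any = corrected_any),
    class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled OR %.4f [%.4f, %.4f], p = %.3g (%s, k = %d)\n",
              x$pooled_or, x$ci_low, x$ci_high, x$p, x$method, x$k))
  cat(sprintf("Heterogeneity: Q = %.3f (df = %d, p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
              x$Q, x$df, x$p_Q, x$i_squared, x$tau_squared))
  invisible(x)
}

#' Cochran's Q, I-squared and the heterogeneity p-value
#'
#' Q is the weighted sum of squared deviations of the study log odds ratios
#' from their inverse-variance weighted mean, referred to a chi-square
#' distribution on k - 1 degrees of freedom. I-squared is
#' max(0, (Q - df)/Q) * 100; it is defined as 0 for a single study.
#'
#' @param effects List of `effect_estimate` objects (excluded ones are
#'   dropped).
#' @return A list with `Q`, `df`, `p_Q`, `i_squared`.
#' @export
heterogeneity <- function(effects) {
  em <- effects_matrix(effects)
  if (em$k == 0) stop("no informative studies", call. = FALSE)
  if (em$k == 1) {
    return(list(Q = 0, df = 0L, p_Q = 1, i_squared = 0))
  }
  ybar <- sum(em$w * em$y) / sum(em$w)
  Q <- sum(em$w * (em$y - ybar)^2)
  df <- em$k - 1L
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, p_Q = p_Q, i_squared = i2)
}

#' Heterogeneity-driven choice of pooling method
#'
#' Fixed effects are used when the heterogeneity test is non-significant
#' (p_Q > 0.1) or I-squared is at most 50 percent; otherwise random effects.
#'
#' @param p_Q Heterogeneity p-value from [heterogeneity()].
#' @param i_squared I-squared percentage, 0-100.
#' @return `"fixed_MH"` or `"random_DL"`.
#' @export
select_method <- function(p_Q, i_squared) {
  if (p_Q > 0.1 || i_squared <= 50) "fixed_MH" else "random_DL"
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' Pools 2x2 tables by the Mantel-Haenszel weighting
#' OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i), with the
#' Robins-Breslow-Greenland variance of the log pooled odds ratio. The
#' per-study continuity correction (+0.5 to every cell of a table with a
#' zero cell) is applied to the MH sums as well; tables that are
#' non-informative (both exposed or both unexposed cells zero) are dropped.
#' Heterogeneity statistics are computed from the inverse-variance study
#' effects on the same tables.
#'
#' @param tables List of `contingency_table` objects.
#' @param study_ids Optional character vector of identifiers.
#' @return A `pooled_result` with `method = "fixed_MH"` and
#'   `tau_squared = 0`.
#' @examples
#' pool_fixed_mh(list(new_table(10, 10, 5, 15), new_table(8, 12, 4, 16)))
#' @export
pool_fixed_mh <- function(tables, study_ids = NULL) {
  if (length(tables) == 0) stop("no tables to pool", call. = FALSE)
  if (is.null(study_ids)) study_ids <- paste0("study_", seq_along(tables))
  keep <- vapply(tables, is_informative, logical(1))
  if (!any(keep)) stop("all tables are non-informative", call. = FALSE)
  tables <- tables[keep]
  study_ids <- study_ids[keep]

  cc <- lapply(tables, correct_cells)
  cells <- do.call(rbind, lapply(cc, `[[`, "cells"))
  a <- cells[, 1]; b <- cells[, 2]; c <- cells[, 3]; d <- cells[, 4]
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  log_or <- log(sum(R) / sum(S))
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / n
  Q <- (b + c) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(v)

  effects <- mapply(study_effect, tables, study_ids, SIMPLIFY = FALSE)
  het <- heterogeneity(effects)
  new_pooled_result("fixed_MH", length(tables), log_or, se,
                    het$Q, het$df, het$p_Q, het$i_squared,
                    tau_squared = 0,
                    corrected_any = any(vapply(cc, `[[`, logical(1),
                                               "corrected")))
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Estimates the between-study variance tau^2 by the method of moments,
#' tau^2 = max(0, (Q - df)/C) with C = sum(w) - sum(w^2)/sum(w) on
#' inverse-variance weights, re-weights each study by
#' 1/(se_i^2 + tau^2) and pools the log odds ratios. A single study is
#' returned unchanged with tau^2 = 0.
#'
#' @param effects List of `effect_estimate` objects.
#' @return A `pooled_result` with `method = "random_DL"`.
#' @export
pool_random_dl <- function(effects) {
  em <- effects_matrix(effects)
  if (em$k == 0) stop("no informative studies", call. = FALSE)
  het <- heterogeneity(effects)
  if (em$k == 1) {
    return(new_pooled_result("random_DL", 1L, em$y, em$se,
                             0, 0L, 1, 0, tau_squared = 0))
  }
  C <- sum(em$w) - sum(em$w^2) / sum(em$w)
  tau2 <- max(0, (het$Q - het$df) / C)
  w_star <- 1 / (em$se^2 + tau2)
  log_or <- sum(w_star * em$y) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  new_pooled_result("random_DL", em$k, log_or, se,
                    het$Q, het$df, het$p_Q, het$i_squared,
                    tau_squared = tau2)
}

#' Inverse-variance fixed-effects pooling of log odds ratios
#'
#' Companion estimator to [pool_fixed_mh()], provided so results can be
#' re-run with inverse-variance fixed weights for comparison.
#'
#' @param effects List of `effect_estimate` objects.
#' @return A `pooled_result` with `method = "fixed_IV"`.
#' @export
pool_fixed_iv <- function(effects) {
  em <- effects_matrix(effects)
  if (em$k == 0) stop("no informative studies", call. = FALSE)
  het <- heterogeneity(effects)
  log_or <- sum(em$w * em$y) / sum(em$w)
  se <- 1 / sqrt(sum(em$w))
  new_pooled_result("fixed_IV", em$k, log_or, se,
                    het$Q, het$df, het$p_Q, het$i_squared, tau_squared = 0)
}

#' Pool 2x2 tables with heterogeneity-driven method selection
#'
#' Computes per-study effects and heterogeneity, chooses the pooling method
#' by [select_method()] (or uses the method forced by `method`), and pools.
#'
#' @param tables List of `contingency_table` objects.
#' @param study_ids Optional identifiers.
#' @param method `"auto"` (default, heterogeneity-driven), `"fixed_MH"` or
#'   `"random_DL"`.
#' @return A `pooled_result`.
#' @export
pool_tables <- function(tables, study_ids = NULL,
                        method = c("auto", "fixed_MH", "random_DL")) {
  method <- match.arg(method)
  if (length(tables) == 0) stop("no tables to pool", call. = FALSE)
  if (is.null(study_ids)) study_ids <- paste0("study_", seq_along(tables))
  effects <- mapply(study_effect, tables, study_ids, SIMPLIFY = FALSE)
  informative <- !vapply(effects, `[[`, logical(1), "excluded")
  if (!any(informative)) stop("all tables are non-informative", call. = FALSE)
  if (method == "auto") {
    het <- heterogeneity(effects)
    method <- select_method(het$p_Q, het$i_squared)
  }
  if (method == "fixed_MH") {
    pool_fixed_mh(tables[informative], study_ids[informative])
  } else {
    pool_random_dl(effects)
  }
}
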