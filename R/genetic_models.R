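#' Genotype counts for one study arm
#'
#' Constructs and validates a genotype count triple for one arm (cases or
#' controls) of a case-control study: carriers of two copies of the risk
#' allele, heterozygotes, and carriers of two copies of the other allele.
#'
#' @param hom_risk Number of risk-allele homozygotes (persons).
#' @param het Number of heterozygotes (persons).
#' @param hom_other Number of other-allele homozygotes (persons).
#' @return A named integer vector of class `genotype_counts` with elements
#'   `hom_risk`, `het`, `hom_other`.
#' @examples
#' genotype_counts(25, 50, 25)
#' @export
genotype_counts <- function(hom_risk, het, hom_other) {
  x <- c(hom_risk = hom_risk, het = het, hom_other = hom_other)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  if (sum(x) < 1) {
    stop("genotype counts must total at least one person", call. = FALSE)
  }
  structure(as.integer(round(x)),
            names = c("hom_risk", "het", "hom_other"),
            class = "genotype_counts")
}

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  if (length(x) != 3) stop("expected a genotype triple", call. = FALSE)
  genotype_counts(x[[1]], x[[2]], x[[3]])
}

new_contingency_table <- function(a, b, c, d, unit, corrected = FALSE) {
  structure(list(a = a, b = b, c = c, d = d,
                 unit = unit, corrected = corrected),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table (%s%s)\n", x$unit,
              if (x$corrected) ", continuity-corrected" else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

check_arms <- function(cases, controls) {
  cases <- as_genotype_counts(cases)
  controls <- as_genotype_counts(controls)
  list(cases = cases, controls = controls)
}

#' Allele-model 2x2 table
#'
#' Each person contributes two alleles: a heterozygote counts once toward the
#' risk-allele column and once toward the other-allele column. The resulting
#' table compares risk-allele counts between case and control chromosomes.
#'
#' @param cases,controls Genotype triples (see [genotype_counts()]).
#' @return A `contingency_table` with `unit = "alleles"`.
#' @examples
#' allele_table(genotype_counts(25, 50, 25), genotype_counts(16, 48, 36))
#' @export
allele_table <- function(cases, controls) {
  arms <- check_arms(cases, controls)
  ca <- arms$cases; co <- arms$controls
  new_contingency_table(
    a = 2 * ca[["hom_risk"]] + ca[["het"]],
    b = 2 * ca[["hom_other"]] + ca[["het"]],
    c = 2 * co[["hom_risk"]] + co[["het"]],
    d = 2 * co[["hom_other"]] + co[["het"]],
    unit = "alleles")
}

#' Dominant-model 2x2 table
#'
#' Compares risk-allele carriers (heterozygotes plus risk homozygotes)
#' against non-carriers, at the person level.
#'
#' @inheritParams allele_table
#' @return A `contingency_table` with `unit = "persons"`.
#' @export
dominant_table <- function(cases, controls) {
  arms <- check_arms(cases, controls)
  ca <- arms$cases; co <- arms$controls
  new_contingency_table(
    a = ca[["hom_risk"]] + ca[["het"]],
    b = ca[["hom_other"]],
    c = co[["hom_risk"]] + co[["het"]],
    d = co[["hom_other"]],
    unit = "persons")
}

#' Recessive-model 2x2 table
#'
#' Compares risk-allele homozygotes against all other genotypes, at the
#' person level.
#'
#' @inheritParams allele_table
#' @return A `contingency_table` with `unit = "persons"`.
#' @export
recessive_table <- function(cases, controls) {
  arms <- check_arms(cases, controls)
  ca <- arms$cases; co <- arms$controls
  new_contingency_table(
    a = ca[["hom_risk"]],
    b = ca[["het"]] + ca[["hom_other"]],
    c = co[["hom_risk"]],
    d = co[["het"]] + co[["hom_other"]],
    unit = "persons")
}

#' Build a model-specific 2x2 table
#'
#' @param cases,controls Genotype triples.
#' @param model One of `"allele"`, `"dominant"`, `"recessive"`.
#' @return A `contingency_table`.
#' @export
model_table <- function(cases, controls,
                        model = c("allele", "dominant", "recessive")) {
  model <- match.arg(model)
  switch(model,
         allele = allele_table(cases, controls),
         dominant = dominant_table(cases, controls),
         recessive = recessive_table(cases, controls))
}

#' Risk-allele frequency of a genotype triple
#'
#' @param counts A genotype triple.
#' @return Frequency of the risk allele in `[0, 1]`.
#' @examples
#' allele_frequency(genotype_counts(25, 50, 25))  # 0.5
#' @export
allele_frequency <- function(counts) {
  counts <- as_genotype_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("allele frequency undefined for zero persons", call. = FALSE)
  (2 * counts[["hom_risk"]] + counts[["het"]]) / (2 * n)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions q^2, 2q(1-q), (1-q)^2 implied by the sample
#' allele frequency. Provided as a diagnostic only; it is never used as an
#' exclusion criterion by the pipeline.
#'
#' @param counts A genotype triple (typically the control arm).
#' @return A list with `chisq`, `df` (always 1) and `p`.
#' @export
hwe_test <- function(counts) {
  counts <- as_genotype_counts(counts)
  n <- sum(counts)
  q <- allele_frequency(counts)
  expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  if (any(expected == 0)) {
    # monomorphic sample: perfectly consistent with HWE
    return(list(chisq = 0, df = 1L, p = 1))
  }
  chisq <- sum((as.numeric(counts) - expected)^2 / expected)
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}
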