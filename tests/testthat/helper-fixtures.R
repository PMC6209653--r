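# builders shared across the suite; everything is generated in code

mk_effect <- function(log_or, se, id = "x") {
  structure(list(study_id = id, log_or = log_or, se = se,
                 or_value = exp(log_or), weight = 1 / se^2,
                 corrected = FALSE, excluded = FALSE),
            class = "effect_estimate")
}

mk_record_row <- function(study_id, variant_id, case_counts, ctrl_counts,
                          ethnicity = "European", country = "Testland",
                          risk_allele = "T", other_allele = "C",
                          superseded_by = NA_character_,
                          af_gnomad = NA_real_) {
  data.frame(study_id = study_id, author_year = paste0("2010", study_id),
             ethnicity = ethnicity, country = country, nos = 7L,
             variant_id = variant_id,
             risk_allele = risk_allele, other_allele = other_allele,
             case_hom_risk = case_counts[1], case_het = case_counts[2],
             case_hom_other = case_counts[3],
             ctrl_hom_risk = ctrl_counts[1], ctrl_het = ctrl_counts[2],
             ctrl_hom_other = ctrl_counts[3],
             superseded_by = superseded_by, af_gnomad = af_gnomad,
             stringsAsFactors = FALSE)
}

# deterministic multi-study records for one variant: mild risk effect,
# different sizes, no randomness
mk_variant_records <- function(variant_id = "rs1", k = 4,
                               ethnicity = rep("European", k),
                               country = rep("Testland", k)) {
  do.call(rbind, lapply(seq_len(k), function(i) {
    n <- 100 + 40 * i
    mk_record_row(sprintf("%s_S%d", variant_id, i), variant_id,
                  case_counts = c(round(0.16 * n), round(0.50 * n),
                                  n - round(0.16 * n) - round(0.50 * n)),
                  ctrl_counts = c(round(0.12 * n), round(0.46 * n),
                                  n - round(0.12 * n) - round(0.46 * n)),
                  ethnicity = ethnicity[i], country = country[i])
  }))
}

write_records_tsv <- function(records, path = tempfile(fileext = ".tsv")) {
  write_dataset(records, path)
  path
}

# the 36-study roster (author-year / ethnicity / country / quality score of
# a published Parkinson's disease study base); genotype counts synthetic
roster36 <- function(variant_id = "rs1", seed = 42) {
  meta <- rbind(
    c("2006Mizuta I", "East Asian", "Japan", 7),
    c("2008Mizuta I", "East Asian", "Japan", 8),
    c("2010Chang XL", "East Asian", "China", 9),
    c("2010Hu FY", "East Asian", "China", 7),
    c("2010Yu L", "East Asian", "China", 8),
    c("2012Gan R", "East Asian", "China", 6),
    c("2012Hu Y", "East Asian", "China", 7),
    c("2012Li NN", "East Asian", "China", 7),
    c("2012Miyake Y", "East Asian", "Japan", 8),
    c("2012Pan F", "East Asian", "China", 7),
    c("2013Liu B", "East Asian", "China", 6),
    c("2013Liu J", "East Asian", "China", 7),
    c("2013Pan F", "East Asian", "China", 8),
    c("2013Wu-Chou YH", "East Asian", "China", 8),
    c("2014Guo XY", "East Asian", "China", 7),
    c("2015Chen YP", "East Asian", "China", 7),
    c("2015Guo JF", "East Asian", "China", 8),
    c("2015Wu GP", "East Asian", "China", 6),
    c("2016Fang J", "East Asian", "China", 8),
    c("2017Chen WJ", "East Asian", "China", 7),
    c("2007Goris A", "European", "UK", 7),
    c("2007Parsian AJ", "European", "America", 8),
    c("2007Ross OA", "European", "Ireland", 9),
    c("2007Winkler S", "European", "Germany", 7),
    c("2008Myhre R", "European", "Norway", 8),
    c("2008Westerlund M", "European", "Sweden", 9),
    c("2009Chung SJ", "European", "America", 7),
    c("2009Pankratz N", "European", "America", 7),
    c("2010Mata IF", "European", "America", 8),
    c("2011Elbaz A", "European", "Multi-country", 7),
    c("2012Cardo LF", "European", "Spain", 6),
    c("2012Trotta L", "European", "Italy", 6),
    c("2013Emelyanov A", "European", "Russia", 7),
    c("2017Campelo CL", "Latino", "Brazil", 7),
    c("2014Lee PC", "Mixed", "America", 8),
    c("2016Shahmohammadibeni N", "West Asian", "Iran", 7))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(meta)), function(i) {
      n_case <- sample(104:5302, 1)
      n_ctrl <- sample(98:4161, 1)
      q <- if (meta[i, 2] == "East Asian") 0.55 else 0.30
      pc <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
      cases <- as.integer(stats::rmultinom(1, n_case, pc))
      ctrls <- as.integer(stats::rmultinom(1, n_ctrl, pc))
      row <- mk_record_row(sprintf("S%02d", i), variant_id, cases, ctrls,
                           ethnicity = meta[i, 2], country = meta[i, 3])
      row$author_year <- meta[i, 1]
      row$nos <- as.integer(meta[i, 4])
      row
    })
  })
  do.call(rbind, rows)
}

# deterministic result data frame for IO tests
mk_results_df <- function(n = 2) {
  data.frame(variant_id = paste0("rs", seq_len(n)), group = "overall",
             genetic_model = "allele", method = "fixed_MH", k = 4 + seq_len(n),
             pooled_or = 1.2 + 0.1 * seq_len(n), ci_low = 1.1, ci_high = 1.4,
             z = 3.1, p = c(3e-7, 0.02)[seq_len(n)], Q = 2.5, df = 3,
             p_Q = 0.47, i_squared = 0, tau_squared = 0,
             af_cases = 0.31, af_controls = 0.27, af_population = NA_real_,
             tier = "recommended", direction = "risk",
             contribution = "not_assessed", stringsAsFactors = FALSE)
}
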