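# independent brute-force oracles, written against the formulas directly
# (plain loops on numeric 4-vectors; no shared code with the package)

oracle_mh <- function(cells_list) {
  sum_R <- 0; sum_S <- 0
  sum_PR <- 0; sum_PSQR <- 0; sum_QS <- 0
  for (cl in cells_list) {
    if (any(cl == 0)) cl <- cl + 0.5
    a <- cl[1]; b <- cl[2]; c <- cl[3]; d <- cl[4]
    n <- a + b + c + d
    R <- a * d / n; S <- b * c / n
    P <- (a + d) / n; Q <- (b + c) / n
    sum_R <- sum_R + R; sum_S <- sum_S + S
    sum_PR <- sum_PR + P * R
    sum_PSQR <- sum_PSQR + P * S + Q * R
    sum_QS <- sum_QS + Q * S
  }
  log_or <- log(sum_R / sum_S)
  v <- sum_PR / (2 * sum_R^2) + sum_PSQR / (2 * sum_R * sum_S) +
    sum_QS / (2 * sum_S^2)
  list(or = exp(log_or), log_or = log_or, se = sqrt(v))
}

oracle_dl <- function(y, se) {
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  list(tau2 = tau2, mu = mu, se = 1 / sqrt(sum(ws)), Q = Q)
}

test_that("study_effect matches hand arithmetic, including continuity correction", {
  e <- study_effect(new_table(10, 10, 10, 10))
  expect_equal(e$or_value, 1)
  expect_equal(e$log_or, 0)
  expect_equal(e$se, sqrt(0.4))

  e <- study_effect(new_table(20, 10, 10, 20))
  expect_equal(e$or_value, 4)
  expect_equal(e$log_or, log(4))
  expect_equal(e$se, sqrt(0.3))
  expect_false(e$corrected)
  expect_equal(e$weight, 1 / e$se^2)

  e0 <- study_effect(new_table(0, 10, 10, 10))
  expect_true(e0$corrected)
  expect_equal(e0$or_value, 0.5 * 10.5 / (10.5 * 10.5))
  expect_equal(e0$se, sqrt(1 / 0.5 + 3 / 10.5))

  # non-informative: both exposed cells zero -> excluded sentinel, not NaN
  ni <- study_effect(new_contingency_table(0, 10, 0, 10, unit = "persons"))
  expect_true(ni$excluded)
  expect_true(is.na(ni$log_or))
})

test_that("MH pooling matches single-study identity and hand-computed sums", {
  single <- pool_fixed_mh(list(new_table(20, 10, 10, 20)))
  expect_equal(single$pooled_or, 4)
  expect_equal(single$k, 1)
  expect_equal(single$tau_squared, 0)

  dup <- pool_fixed_mh(list(new_table(20, 10, 10, 20),
                            new_table(20, 10, 10, 20)))
  expect_equal(dup$pooled_or, 4)

  two <- pool_fixed_mh(list(new_table(10, 10, 5, 15),
                            new_table(8, 12, 4, 16)))
  expect_equal(two$pooled_or, (3.75 + 3.2) / (1.25 + 1.2))
})

test_that("DL pooling matches the worked moment-estimator example", {
  dl <- pool_random_dl(list(mk_effect(0.2, 0.1), mk_effect(0.6, 0.1)))
  expect_equal(dl$Q, 8)
  expect_equal(dl$tau_squared, 0.07)
  expect_equal(dl$log_or, 0.4)
  expect_equal(dl$se, 0.2)
  expect_equal(dl$i_squared, 87.5)
  expect_equal(dl$df, 1)

  # homogeneity limit: identical effects -> tau2 = 0, equals IV fixed
  eff <- list(mk_effect(0.3, 0.15, "a"), mk_effect(0.3, 0.15, "b"),
              mk_effect(0.3, 0.15, "c"))
  dl0 <- pool_random_dl(eff)
  iv <- pool_fixed_iv(eff)
  expect_equal(dl0$tau_squared, 0)
  expect_equal(dl0$log_or, iv$log_or)
  expect_equal(dl0$se, iv$se)
  expect_equal(dl0$Q, 0)
  expect_equal(dl0$i_squared, 0)

  # single effect passes through with tau2 = 0
  one <- pool_random_dl(list(mk_effect(0.5, 0.2)))
  expect_equal(one$log_or, 0.5)
  expect_equal(one$se, 0.2)
  expect_equal(one$tau_squared, 0)
})

test_that("MH and DL match brute-force oracles to 1e-10 on random small instances", {
  set.seed(11)
  for (rep in 1:30) {
    k <- sample(1:3, 1)
    cells <- lapply(seq_len(k), function(i) sample(5:60, 4, replace = TRUE))
    tables <- lapply(cells, function(cl) new_table(cl[1], cl[2], cl[3], cl[4]))
    mh <- pool_fixed_mh(tables)
    omh <- oracle_mh(cells)
    expect_equal(mh$pooled_or, omh$or, tolerance = 1e-10)
    expect_equal(mh$se, omh$se, tolerance = 1e-10)

    eff <- lapply(tables, study_effect)
    y <- vapply(eff, `[[`, numeric(1), "log_or")
    se <- vapply(eff, `[[`, numeric(1), "se")
    if (k >= 2) {
      dl <- pool_random_dl(eff)
      odl <- oracle_dl(y, se)
      expect_equal(dl$tau_squared, odl$tau2, tolerance = 1e-10)
      expect_equal(dl$log_or, odl$mu, tolerance = 1e-10)
      expect_equal(dl$se, odl$se, tolerance = 1e-10)
    }
  }
})

test_that("case/control transposition inverts the pooled OR and negates z", {
  set.seed(13)
  cells <- lapply(1:4, function(i) sample(5:80, 4, replace = TRUE))
  tables <- lapply(cells, function(cl) new_table(cl[1], cl[2], cl[3], cl[4]))
  flipped <- lapply(cells, function(cl) new_table(cl[3], cl[4], cl[1], cl[2]))
  for (pool in list(pool_fixed_mh,
                    function(tt) pool_random_dl(lapply(tt, study_effect)))) {
    a <- pool(tables); b <- pool(flipped)
    expect_equal(b$pooled_or, 1 / a$pooled_or, tolerance = 1e-12)
    expect_equal(b$z, -a$z, tolerance = 1e-12)
  }
})

test_that("random-effects CI is never narrower than fixed IV on the same data", {
  set.seed(17)
  for (rep in 1:10) {
    eff <- lapply(1:6, function(i) mk_effect(rnorm(1, 0.3, 0.4),
                                             runif(1, 0.05, 0.4),
                                             paste0("s", i)))
    dl <- pool_random_dl(eff)
    iv <- pool_fixed_iv(eff)
    expect_gte(dl$se, iv$se - 1e-12)
  }
})

test_that("heterogeneity statistics follow the Q/I2 definitions", {
  het <- heterogeneity(list(mk_effect(0.2, 0.1), mk_effect(0.6, 0.1)))
  expect_equal(het$Q, 8)
  expect_equal(het$df, 1)
  expect_equal(het$i_squared, 87.5)
  expect_equal(het$p_Q, pchisq(8, 1, lower.tail = FALSE))

  same <- heterogeneity(list(mk_effect(0.3, 0.2), mk_effect(0.3, 0.2)))
  expect_equal(same$Q, 0)
  expect_equal(same$i_squared, 0)

  # Q < df floors I2 at zero
  near <- heterogeneity(list(mk_effect(0.30, 0.3), mk_effect(0.31, 0.3),
                             mk_effect(0.32, 0.3)))
  expect_lt(near$Q, near$df)
  expect_equal(near$i_squared, 0)

  expect_equal(heterogeneity(list(mk_effect(0.3, 0.2)))$i_squared, 0)
})

test_that("select_method implements the disjunctive heterogeneity rule", {
  expect_identical(select_method(0.5, 0), "fixed_MH")
  expect_identical(select_method(0.05, 40), "fixed_MH")
  expect_identical(select_method(0.05, 60), "random_DL")
  expect_identical(select_method(0.5, 80), "fixed_MH")
  # boundaries: p_Q > 0.1 strict, I2 <= 50 inclusive
  expect_identical(select_method(0.1, 60), "random_DL")
  expect_identical(select_method(0.09, 50), "fixed_MH")
})

test_that("wald_p matches the normal CDF and is monotone in |z|", {
  expect_equal(wald_p(0, 1)$p, 1)
  wp <- wald_p(1.3863, 0.5477)
  expect_equal(wp$z, 1.3863 / 0.5477)
  expect_equal(wp$p, 2 * pnorm(abs(wp$z), lower.tail = FALSE))
  expect_equal(round(wp$p, 4), 0.0114)
  ps <- vapply(seq(0, 3, 0.5), function(z) wald_p(z, 1)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("pool_tables applies the selection rule and degenerate-input errors", {
  # homogeneous tables -> fixed MH chosen
  tabs <- lapply(1:4, function(i) new_table(30, 20, 20, 30))
  expect_identical(pool_tables(tabs)$method, "fixed_MH")
  # grossly heterogeneous -> random selected
  tabs2 <- list(new_table(200, 50, 50, 200), new_table(50, 200, 200, 50),
                new_table(220, 40, 40, 220), new_table(40, 220, 220, 40))
  expect_identical(pool_tables(tabs2)$method, "random_DL")
  expect_error(pool_tables(list()), "no tables")
  expect_error(pool_fixed_mh(list()), "no tables")
  both_zero <- new_contingency_table(0, 10, 0, 10, unit = "persons")
  expect_error(pool_fixed_mh(list(both_zero)), "non-informative")
})
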