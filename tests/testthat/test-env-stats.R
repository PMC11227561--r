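test_that("stress-adaptation correlation on constructed vectors", {
  ef <- tibble::tibble(F_ratio = c(1, 2, 3), f_over_F_mean = c(3, 2, 1))
  r <- stress_adaptation_correlation(ef)
  expect_equal(r$coefficient, -1)
  expect_error(stress_adaptation_correlation(
    tibble::tibble(F_ratio = c(1, 1, 1), f_over_F_mean = 1:3)),
    "variance")
  expect_error(stress_adaptation_correlation(ef[1:2, ]), "3")
})

test_that("the replicate split removes the shared-error artifact", {
  # no adaptation anywhere: evolved rate == progenitor rate; every
  # measurement carries independent multiplicative noise. The naive
  # estimator shares the progenitor-mean error between F_i/F_SC and
  # the f/F denominator and goes spuriously negative; the split
  # estimator is centered on zero.
  set.seed(90)
  n_env <- 200; true_rate <- 0.005; noise <- 0.05
  meas <- function(n) true_rate * rlnorm(n, 0, noise)
  prog <- dplyr::bind_rows(lapply(seq_len(n_env), function(i)
    tibble::tibble(environment_id = sprintf("e%03d", i), replicate = 1:3,
                   rate = meas(3))))
  evo <- dplyr::bind_rows(lapply(seq_len(n_env), function(i)
    tibble::tibble(environment_id = sprintf("e%03d", i),
                   population = 1:5, rate = meas(5))))
  naive <- environment_fitness_summary(prog, evo, true_rate, "none")
  split <- environment_fitness_summary(prog, evo, true_rate,
                                       "first_two_vs_third")
  r_naive <- stress_adaptation_correlation(naive)$coefficient
  r_split <- stress_adaptation_correlation(split)$coefficient
  expect_lt(r_naive, -0.3)
  expect_lt(abs(r_split), 0.2)   # ~3 standard errors at n = 200
})

test_that("partial rank correlation matches its formula and edge cases", {
  set.seed(91)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3) + 0.1 * (1:10)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8) + 0.1 * (10:1)
  z <- c(9, 9, 8, 2, 6, 5, 3, 5, 8, 9) + 0.05 * (1:10)
  got <- partial_rank_correlation(x, y, z)
  # brute force from the definition
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  want <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(got$coefficient, want, tolerance = 1e-12)
  # y == x gives partial 1 whenever |rxz| < 1
  expect_equal(partial_rank_correlation(x, x, z)$coefficient, 1)
  # control identical to y is degenerate
  expect_error(partial_rank_correlation(x, y, y), "undefined")
  expect_error(partial_rank_correlation(x[1:3], y[1:3], z[1:3]), "4")
})

test_that("partial correlation reduces to plain Spearman for unrelated control", {
  # constructed so the control has exactly zero rank correlation with
  # x and y: z ranks orthogonal by symmetry
  x <- 1:8
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  z <- c(1, 8, 2, 7, 3, 6, 4, 5)   # rank-correlation ~ 0 with x
  rxz <- cor(rank(x), rank(z))
  if (abs(rxz) < 1e-9 && abs(cor(rank(y), rank(z))) < 1e-9) {
    expect_equal(partial_rank_correlation(x, y, z)$coefficient,
                 cor(rank(x), rank(y)))
  }
  succeed()
})

test_that("fitness-gain extrapolation is exact and linear", {
  expect_equal(round(fitness_gain_extrapolation(23.5, 70, 550, 800), 1),
               39.2)
  expect_equal(fitness_gain_extrapolation(100, 0, 1000, 1000), 100)
  expect_equal(fitness_gain_extrapolation(10, 0, 100, 50), 5)
  # linear in both the observed fraction and the target generation
  expect_equal(fitness_gain_extrapolation(47, 70, 550, 800),
               2 * fitness_gain_extrapolation(23.5, 70, 550, 800))
  expect_equal(fitness_gain_extrapolation(23.5, 70, 550, 1600),
               2 * fitness_gain_extrapolation(23.5, 70, 550, 800))
  expect_error(fitness_gain_extrapolation(10, 100, 100, 50), "gen_end")
})

test_that("two-tailed binomial sign test: anchors and symmetry", {
  expect_equal(binomial_sign_test(8, 8), 2 * 0.5^8)
  expect_equal(binomial_sign_test(0, 8), 2 * 0.5^8)
  expect_equal(binomial_sign_test(4, 8), 1)
  for (n in 1:12) for (k in 0:n) {
    expect_equal(binomial_sign_test(k, n), binomial_sign_test(n - k, n),
                 tolerance = 1e-12)
  }
})

test_that("benefit-stress trend: perfect linear panels and the filter", {
  stress <- seq(0.6, 1.05, length.out = 10)
  panel <- dplyr::bind_rows(lapply(seq_along(stress), function(i)
    tibble::tibble(environment_id = sprintf("e%02d", i),
                   effect = rep(1.5 - 0.4 * stress[i], 3),
                   stress = stress[i])))
  r <- benefit_stress_trend(panel)
  expect_equal(r$coefficient, -1, tolerance = 1e-9)
  expect_equal(r$n_excluded, 0)
  # an environment with tight significantly-deleterious replicates is
  # dropped by the filter
  bad <- tibble::tibble(environment_id = "e_bad",
                        effect = c(0.79, 0.80, 0.81), stress = 0.9)
  r2 <- benefit_stress_trend(dplyr::bind_rows(panel, bad))
  expect_equal(r2$n_excluded, 1)
  expect_equal(r2$n, 10)
})

test_that("trend sign is recovered under replicate noise", {
  set.seed(92)
  recovered <- 0
  for (rep in 1:200) {
    stress <- runif(10, 0.6, 1.05)
    panel <- dplyr::bind_rows(lapply(seq_along(stress), function(i)
      tibble::tibble(environment_id = sprintf("e%02d", i),
                     effect = 1.5 - 0.4 * stress[i] + rnorm(3, 0, 0.05),
                     stress = stress[i])))
    r <- try(benefit_stress_trend(panel), silent = TRUE)
    if (!inherits(r, "try-error") && r$coefficient < 0) {
      recovered <- recovered + 1
    }
  }
  expect_gte(recovered, 190)   # >= 95% of 200 panels
})

test_that("sign concordance table and one-tailed exact test", {
  mk <- function(env, eff, hf) tibble::tibble(
    environment_id = env, effect = eff, home_or_foreign = hf)
  # 10 home all beneficial, 10 foreign all deleterious
  panel <- dplyr::bind_rows(
    mk(sprintf("h%02d", 1:10), 1.2, "home"),
    mk(sprintf("f%02d", 1:10), 0.8, "foreign"))
  res <- sign_concordance_table(panel)
  expect_equal(unname(res$table["home", "gt1"]), 10)
  expect_equal(unname(res$table["foreign", "lt1"]), 10)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # effects above 1 everywhere: no association
  all_up <- dplyr::bind_rows(mk(sprintf("h%02d", 1:5), 1.1, "home"),
                             mk(sprintf("f%02d", 1:5), 1.1, "foreign"))
  expect_equal(sign_concordance_table(all_up)$p_value, 1)
  # exact ties are excluded from both columns
  with_tie <- dplyr::bind_rows(all_up, mk("t1", 1, "home"))
  res_tie <- sign_concordance_table(with_tie)
  expect_equal(res_tie$n_ties, 1)
  expect_equal(sum(res_tie$table), 10)
})

test_that("concordance counts add across mutation panels", {
  mk <- function(env, eff, hf) tibble::tibble(
    environment_id = env, effect = eff, home_or_foreign = hf)
  p1 <- dplyr::bind_rows(mk("a", 1.3, "home"), mk("b", 0.7, "foreign"))
  p2 <- dplyr::bind_rows(mk("c", 1.1, "home"), mk("d", 0.9, "foreign"))
  t_comb <- sign_concordance_table(dplyr::bind_rows(p1, p2))$table
  expect_equal(t_comb, sign_concordance_table(p1)$table +
                 sign_concordance_table(p2)$table)
})
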