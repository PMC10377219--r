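test_that("Welch t-test handles identical, separated and degenerate samples", {
  r <- two_sample_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- two_sample_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(r$p_value, 0.001)

  expect_error(two_sample_t_test(c(1), c(1, 2)), "degeneracy")
  expect_error(two_sample_t_test(c(2, 2, 2), c(1, 2, 3)), "degeneracy")
})

test_that("Welch t-test agrees with the closed-form oracle and is antisymmetric", {
  a <- c(0, 1, 2, 3, 4)
  b <- c(2, 3, 4, 5, 6)
  got <- two_sample_t_test(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-6)

  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- two_sample_t_test(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-6)
    swapped <- two_sample_t_test(y, x)
    expect_equal(swapped$statistic, -got$statistic, tolerance = 1e-12)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
  }
})

test_that("uncorrected chi-square reproduces the published contingency p-values", {
  gender <- matrix(c(289, 351, 228, 405), nrow = 2)
  drinking <- matrix(c(338, 290, 287, 341), nrow = 2)
  smoking <- matrix(c(542, 98, 474, 162), nrow = 2)
  expect_equal(round(chi_square_test(gender)$p_value, 3), 0.001)
  expect_equal(round(chi_square_test(drinking)$p_value, 3), 0.004)
  expect_equal(round(chi_square_test(smoking)$p_value, 3), 0.000)
  expect_equal(chi_square_test(smoking)$statistic, 20.3, tolerance = 0.005)
})

test_that("chi-square is symmetric, nonnegative and zero only at independence", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_square_test(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  tab <- matrix(c(30, 12, 18, 40), 2)
  r <- chi_square_test(tab)
  expect_equal(chi_square_test(t(tab))$statistic, r$statistic)
  expect_equal(chi_square_test(tab[2:1, 2:1])$statistic, r$statistic)
  expect_gt(r$statistic, 0)
  expect_true(r$p_value >= 0 && r$p_value <= 1)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("chi-square p agrees with a permutation null on large random tables", {
  # smoking-style table: asymptotic p is far beyond permutation resolution
  smoking <- matrix(c(542, 98, 474, 162), nrow = 2)
  expect_lt(perm_chisq_p(smoking, nsim = 1e5), 3e-5)

  set.seed(11)
  for (i in 1:4) {
    n <- 5000
    p_row <- runif(1, 0.3, 0.7)
    eff <- runif(1, 0, 0.04)
    x <- rbinom(1, n, p_row)
    tab <- matrix(c(rbinom(1, x, 0.5 + eff), 0, rbinom(1, n - x, 0.5), 0), 2)
    tab[1, 2] <- x - tab[1, 1]
    tab[2, 2] <- (n - x) - tab[2, 1]
    p_asym <- chi_square_test(tab)$p_value
    p_perm <- perm_chisq_p(tab, nsim = 1e5, seed = i)
    mc_se <- sqrt(p_perm * (1 - p_perm) / 1e5)
    expect_lt(abs(p_asym - p_perm), 3 * mc_se + 0.004)
  }
})

test_that("group_summary lays out per-group means, counts and p-values", {
  co <- generate_cohort(default_cohort_spec(), 2)
  gs <- group_summary(co)
  expect_equal(gs$variable, cohort_schema())
  expect_equal(gs$kind[gs$variable == "gender"], "chi-square")
  expect_equal(gs$low[gs$variable == "age"],
               mean(co$age[co$stress == "low"]))
  expect_equal(gs$high[gs$variable == "smoking"],
               sum(co$smoking == "yes" & co$stress == "high"))
  expect_true(all(gs$p_value >= 0 & gs$p_value <= 1))

  # default-spec calibration at large n: mean SBP(low) near its target
  spec <- default_cohort_spec(); spec$n_low <- spec$n_high <- 10000L
  gs_big <- group_summary(generate_cohort(spec, 4))
  expect_lt(abs(gs_big$low[gs_big$variable == "sbp"] - 120.92), 0.5)

  expect_error(group_summary(co[co$stress == "low", ]), "both")
  expect_error(group_summary(co[0, ]), "empty")
})

test_that("screen_features selects by p < alpha in schema order", {
  co <- generate_cohort(default_cohort_spec(), 2)
  rep <- screen_features(co, alpha = 0.05)
  expect_equal(rep$tests$variable, cohort_schema())
  expect_identical(rep$tests$selected, rep$tests$p_value < 0.05)

  all_in <- screen_features(co, alpha = 1.0)
  expect_equal(length(all_in$selected), 11)

  co$dbp <- 75  # constant in both groups
  expect_error(screen_features(co), "dbp")
})

test_that("screening finds every variable on a strongly separated cohort", {
  co <- generate_cohort(separable_cohort_spec(300, 300), 8)
  rep <- screen_features(co)
  expect_setequal(rep$selected, cohort_schema())
})
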