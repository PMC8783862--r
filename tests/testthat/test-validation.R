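# validation statistics: partial correlation, count reconstruction,
# odds ratio, chi-square, Wilks normalization, carrier comparison

test_that("partial correlation reduces to plain Pearson without covariates", {
  set.seed(67)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  res <- partial_correlation(x, y)
  ref <- stats::cor.test(x, y)
  expect_lt(abs(res$r - unname(ref$estimate)), 1e-12)
  expect_lt(abs(res$p - ref$p.value), 1e-12)
  expect_equal(partial_correlation(x, x)$r, 1)
  expect_error(partial_correlation(x, rep(1, 40)), "constant")
})

test_that("single-covariate adjustment matches the closed-form partial r", {
  set.seed(71)
  z <- rnorm(60)
  x <- 0.7 * z + rnorm(60)
  y <- -0.4 * z + rnorm(60)
  res <- partial_correlation(x, y, data.frame(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_lt(abs(res$r - oracle), 1e-12)
  expect_equal(res$df, 60 - 2 - 1)
})

test_that("correlation estimates are unbiased at the study's effect size", {
  set.seed(73)
  rho <- 0.28; n <- 49; B <- 500
  ests <- replicate(B, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    partial_correlation(x, y)$r
  })
  expect_lt(abs(mean(ests) - rho), 0.03)
})

test_that("counts reconstructed from printed percentages round half away from zero", {
  expect_equal(unname(reconstruct_counts(222, 68.9)), c(153, 69))
  expect_equal(unname(reconstruct_counts(151, 55.6)), c(84, 67))
  expect_equal(unname(reconstruct_counts(100, 0)), c(0, 100))
  expect_equal(unname(reconstruct_counts(10, 25)), c(3, 7))  # 2.5 -> 3
  expect_error(reconstruct_counts(10, 120), "percentage")
})

test_that("odds ratio follows (ad)/(bc) with a Woolf interval", {
  t <- two_by_two(153, 69, 84, 67)
  res <- odds_ratio(t)
  expect_lt(abs(res$or - (153 * 67) / (69 * 84)), 1e-12)
  expect_equal(round(res$or, 1), 1.8)
  se <- sqrt(1 / 153 + 1 / 69 + 1 / 84 + 1 / 67)
  expect_lt(abs(res$ci[1] - exp(log(res$or) - qnorm(0.975) * se)), 1e-12)

  # ad = bc gives exactly 1; swapping rows gives the reciprocal
  expect_equal(odds_ratio(two_by_two(10, 20, 5, 10))$or, 1)
  sw <- odds_ratio(two_by_two(84, 67, 153, 69))
  expect_lt(abs(res$or * sw$or - 1), 1e-12)

  expect_message(z <- odds_ratio(two_by_two(5, 0, 3, 4)), "Haldane")
  expect_true(z$corrected && is.finite(z$or))
  expect_error(odds_ratio(two_by_two(0, 0, 3, 4)), "margin")
})

test_that("chi-square agrees with the closed-form statistic on all small tables", {
  oracle <- function(m, yates) {
    N <- sum(m); E <- outer(rowSums(m), colSums(m)) / N
    adj <- if (yates) min(0.5, abs(m[1, 1] - E[1, 1])) else 0
    sum((abs(m - E) - adj)^2 / E)
  }
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    t <- two_by_two(a, b, c, d)
    plain <- chi_square_2x2(t, yates = FALSE)
    corr <- chi_square_2x2(t, yates = TRUE)
    expect_lt(abs(plain$statistic - oracle(m, FALSE)), 1e-10)
    expect_lt(abs(corr$statistic - oracle(m, TRUE)), 1e-10)
    expect_lte(corr$statistic, plain$statistic + 1e-12)
  }
})

test_that("chi-square on the reconstructed study table gives the printed p", {
  t <- two_by_two(153, 69, 84, 67)
  res <- chi_square_2x2(t, yates = TRUE)
  expect_equal(round(res$p, 3), 0.012)
  plain <- chi_square_2x2(t, yates = FALSE)
  expect_equal(round(plain$p, 3), 0.009)
  expect_equal(chi_square_2x2(two_by_two(30, 10, 60, 20),
                              yates = FALSE)$statistic, 0)
  expect_error(chi_square_2x2(two_by_two(0, 0, 5, 5)), "margin")
})

test_that("Wilks normalization evaluates the published polynomial", {
  # independent evaluation of the fifth-order polynomial
  coef_m <- c(-216.0475144, 16.2606339, -0.002388645, -0.00113732,
              7.01863e-06, -1.291e-08)
  x <- 80
  oracle <- 500 / sum(coef_m * x^(0:5))
  expect_lt(abs(wilks_coefficient(80, wilks_params("male")) - oracle), 1e-10)
  expect_equal(round(wilks_coefficient(80, wilks_params("male")), 2), 0.68)

  expect_equal(wilks_points(0, 80, "male"), 0)
  # equal totals, heavier lifter (same sex) scores fewer points
  for (sx in c("male", "female")) {
    prm <- wilks_params(sx)
    grid <- seq(prm$bw_range[1], prm$bw_range[2], by = 1)
    co <- wilks_coefficient(grid, prm)
    expect_true(all(diff(co) < 0))
  }
  expect_gt(wilks_points(200, 70, "male"), wilks_points(200, 100, "male"))
  expect_error(wilks_points(100, 30, "male"), "range")
})

test_that("carrier comparison builds the table and statistics from scores", {
  set.seed(79)
  cc <- simulate_case_control(study_panel("athletes"),
                              study_panel("controls"),
                              5000, 5000, seed = 83)
  sc <- allele_count_score(cc$genotypes)
  res <- carrier_case_control(cc$group, sc)
  expect_equal(sum(res$table), 10000)
  expect_gt(res$odds_ratio$or, 1)
  expect_gt(res$proportions["case"], res$proportions["control"])

  # identical allele frequencies: no systematic enrichment
  null <- simulate_case_control(study_panel("controls"),
                                study_panel("controls"),
                                5000, 5000, seed = 89)
  sc0 <- allele_count_score(null$genotypes)
  res0 <- carrier_case_control(null$group, sc0)
  expect_lt(abs(log(res0$odds_ratio$or)), 0.2)

  expect_error(carrier_case_control(rep("one", nrow(sc)), sc), "two")
})
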