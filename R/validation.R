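## Validation statistics for the selected score: covariate-adjusted
## correlation with quantitative phenotypes, the carrier 2x2 case-control
## comparison (odds ratio with Woolf CI, chi-square with Yates
## correction), reconstruction of integer counts from printed group
## percentages, and Wilks normalization of weightlifting totals.

#' 2x2 contingency table for carrier comparisons
#'
#' Rows are groups (e.g. athletes / controls), columns carrier /
#' non-carrier: `a` and `b` are row-1 carriers and non-carriers, `c` and
#' `d` row 2.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A 2x2 integer matrix of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0))
    stop("all counts must be non-negative")
  m <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("group1", "group2"),
                              carrier = c("carrier", "non_carrier")))
  if (sum(m) == 0) stop("table has no observations")
  class(m) <- c("two_by_two", class(m))
  m
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' With covariates, `x` and `y` are each residualized on the covariate
#' columns by least squares and the Pearson correlation of the residuals
#' is returned, with the significance test on `n - 2 - k` degrees of
#' freedom for `k` covariate regressors. With no covariates this reduces
#' exactly to the plain Pearson correlation and its usual t test.
#' Incomplete rows are dropped listwise.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional `data.frame` (or matrix) of covariate
#'   columns; factors are expanded through the usual model matrix.
#' @return A list of class `correlation_result`: `r`, `p`, `df`, `n`,
#'   `covariates_used`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  dat <- data.frame(.x = x, .y = y)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = dat[, -(1:2), drop = FALSE])
    k <- ncol(mm) - 1L  # regressors beyond the intercept
    rx <- stats::lm.fit(mm, dat$.x)$residuals
    ry <- stats::lm.fit(mm, dat$.y)$residuals
  } else {
    rx <- dat$.x
    ry <- dat$.y
  }
  if (n < 4 + k) stop("need at least ", 4 + k, " complete cases")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("x or y is constant after residualization")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(r = r, p = p, df = df, n = n,
                 covariates_used = if (is.null(covariates)) character()
                 else names(covariates)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, P = %.4g (n = %d, df = %d%s)\n", x$r, x$p, x$n,
              x$df,
              if (length(x$covariates_used))
                paste0("; adjusted for ",
                       paste(x$covariates_used, collapse = ", "))
              else ""))
  invisible(x)
}

#' Reconstruct integer counts from a printed percentage
#'
#' Given a group size and a percentage reported to limited precision,
#' returns the implied count (rounded half away from zero) and its
#' complement.
#'
#' @param n Group size.
#' @param proportion Percentage in `[0, 100]`.
#' @return Integer vector `c(count, complement)`.
#' @examples
#' reconstruct_counts(222, 68.9)  # 153 carriers, 69 non-carriers
#' @export
reconstruct_counts <- function(n, proportion) {
  if (proportion < 0 || proportion > 100)
    stop("proportion must be a percentage in [0, 100]")
  count <- as.integer(floor(n * proportion / 100 + 0.5))
  c(count = count, complement = as.integer(n) - count)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' `OR = (a d) / (b c)`. If any cell is zero (but no margin is), the
#' Haldane-Anscombe correction adds 0.5 to every cell, with a message.
#' The 95% CI is Woolf's log-based interval,
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table A [two_by_two()].
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `odds_ratio_result`: `or`, `ci` (length 2),
#'   `log_se`, `corrected` (whether Haldane-Anscombe was applied).
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("odds ratio undefined: a table margin is zero")
  m <- unclass(table)
  corrected <- any(m == 0)
  if (corrected) {
    message("zero cell: applying Haldane-Anscombe 0.5 correction")
    m <- m + 0.5
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  log_se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * log_se)
  structure(list(or = or, ci = ci, log_se = log_se, corrected = corrected),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR = %.1f (95%% CI %.2f-%.2f)\n", x$or, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' With `yates = TRUE` (the default) the continuity correction is applied
#' as in [stats::chisq.test()], i.e. capped at the observed-expected
#' deviation so the corrected statistic never exceeds the uncorrected one.
#'
#' @param table A [two_by_two()].
#' @param yates Apply the continuity correction.
#' @return List with `statistic`, `p`, `df` (= 1), `yates`.
#' @export
chi_square_2x2 <- function(table, yates = TRUE) {
  stopifnot(inherits(table, "two_by_two"))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: a table margin is zero")
  ht <- suppressWarnings(stats::chisq.test(unclass(table), correct = yates))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), yates = yates)
}

#' Wilks coefficient parameters
#'
#' The published fifth-order bodyweight polynomial constants (1994
#' formulation) for the configured sex; held in a parameter object so
#' alternative coefficient tables can be swapped in.
#'
#' @param sex `"male"` or `"female"`.
#' @return List of class `wilks_params`: `sex`, coefficients `a`..`f`,
#'   `scale` (= 500), `bw_range` (validity range in kg).
#' @export
wilks_params <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  coefs <- switch(sex,
    male = c(a = -216.0475144, b = 16.2606339, c = -0.002388645,
             d = -0.00113732, e = 7.01863e-06, f = -1.291e-08),
    female = c(a = 594.31747775582, b = -27.23842536447,
               c = 0.82112226871, d = -0.00930733913,
               e = 4.731582e-05, f = -9.054e-08))
  # validity range of the published coefficient tables; beyond it the
  # polynomials stop decreasing (male ~202 kg, female ~155 kg)
  rng <- if (sex == "male") c(40, 201) else c(40, 150)
  structure(c(list(sex = sex), as.list(coefs),
              list(scale = 500, bw_range = rng)),
            class = "wilks_params")
}

#' Wilks coefficient for a bodyweight
#'
#' `scale / (a + b x + c x^2 + d x^3 + e x^4 + f x^5)` with `x` the
#' bodyweight in kg.
#'
#' @param bodyweight_kg Bodyweight in kg, within the formula's validity
#'   range (roughly 40-205 kg).
#' @param params A [wilks_params()].
#' @return The coefficient (dimensionless multiplier).
#' @export
wilks_coefficient <- function(bodyweight_kg, params = wilks_params("male")) {
  stopifnot(inherits(params, "wilks_params"))
  rng <- params$bw_range
  if (any(bodyweight_kg < rng[1] | bodyweight_kg > rng[2]))
    stop("bodyweight outside the formula's validity range (",
         rng[1], "-", rng[2], " kg)")
  x <- bodyweight_kg
  denom <- params$a + params$b * x + params$c * x^2 + params$d * x^3 +
    params$e * x^4 + params$f * x^5
  params$scale / denom
}

#' Wilks points for a weightlifting total
#'
#' The total weight lifted (kg) multiplied by the sex- and
#' bodyweight-specific Wilks coefficient, normalizing strength performance
#' across body weights.
#'
#' @param total_kg Total weight lifted (>= 0).
#' @param bodyweight_kg Bodyweight in kg.
#' @param sex `"male"` or `"female"`.
#' @param params Optional [wilks_params()] overriding `sex`.
#' @return Wilks points.
#' @export
wilks_points <- function(total_kg, bodyweight_kg,
                         sex = c("male", "female"), params = NULL) {
  if (any(total_kg < 0)) stop("total_kg must be >= 0")
  if (is.null(params)) params <- wilks_params(match.arg(sex))
  total_kg * wilks_coefficient(bodyweight_kg, params)
}

#' Carrier case-control comparison
#'
#' Dichotomizes scores at the carrier threshold, builds the group-by-
#' carrier 2x2 table, and reports carrier proportions, the odds ratio and
#' the chi-square test. Individuals with an `NA` score are dropped.
#'
#' @param group Factor or character vector of two group labels, aligned
#'   with `scores` rows (first level / first-seen label becomes row 1).
#' @param scores A [allele_count_score()] result.
#' @param threshold Carrier threshold (default 2).
#' @param yates Continuity correction for the chi-square (default TRUE).
#' @return List of class `carrier_comparison`: `table`, `proportions`
#'   (carrier fraction per group), `odds_ratio`, `chi_square`, `n`.
#' @export
carrier_case_control <- function(group, scores, threshold = 2,
                                 yates = TRUE) {
  if (length(group) != nrow(scores))
    stop("group labels and scores differ in length")
  sc <- dichotomize(scores, threshold)
  keep <- !is.na(sc$score)
  group <- factor(group[keep])
  carrier <- sc$carrier[keep]
  if (nlevels(group) != 2)
    stop("need exactly two non-empty groups, got ", nlevels(group))
  tab <- table(group, factor(carrier, levels = c(TRUE, FALSE)))
  t22 <- two_by_two(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  dimnames(t22) <- list(group = levels(group),
                        carrier = c("carrier", "non_carrier"))
  props <- stats::setNames(t22[, 1] / rowSums(t22), levels(group))
  structure(list(table = t22, proportions = props,
                 odds_ratio = odds_ratio(t22),
                 chi_square = chi_square_2x2(t22, yates = yates),
                 n = sum(tab)),
            class = "carrier_comparison")
}

#' @export
print.carrier_comparison <- function(x, ...) {
  cat("carrier comparison (threshold split)\n")
  print(unclass(x$table))
  cat(sprintf("carrier proportions: %s\n",
              paste(sprintf("%s %.1f%%", names(x$proportions),
                            100 * x$proportions), collapse = ", ")))
  cat(sprintf("OR = %.2f (95%% CI %.2f-%.2f); chi-square = %.2f, P = %.4g\n",
              x$odds_ratio$or, x$odds_ratio$ci[1], x$odds_ratio$ci[2],
              x$chi_square$statistic, x$chi_square$p))
  invisible(x)
}
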