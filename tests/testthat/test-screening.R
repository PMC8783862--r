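# the four-stage selection cascade and the Bonferroni threshold

test_that("sex-concordance filter keeps sign-concordant variants only", {
  stats <- data.frame(
    rsid = rep(c("rs1", "rs2", "rs3"), each = 2),
    sex = rep(c("male", "female"), 3),
    beta = c(0.1, 0.2,    # concordant positive
             0.1, -0.1,   # discordant
             -0.3, -0.1)) # concordant negative
  expect_equal(sex_concordance_filter(stats, verbose = FALSE),
               c("rs1", "rs3"))

  # zero beta in one stratum is conservatively excluded
  stats$beta[6] <- 0
  expect_equal(sex_concordance_filter(stats, verbose = FALSE), "rs1")

  # a missing stratum is an error naming the variant
  expect_error(sex_concordance_filter(stats[-2, ], verbose = FALSE), "rs1")
})

test_that("association scan matches a normal-equations oracle on small data", {
  set.seed(31)
  n <- 18
  panel <- tiny_panel(1, maf = 0.4)
  g <- genotype_table(sprintf("i%02d", 1:n), panel,
                      matrix(rbinom(n, 2, 0.4), ncol = 1))
  ph <- data.frame(id = g$individual_ids,
                   age = rnorm(n, 30, 5), pc1 = rnorm(n))
  ph$y <- 2 + 0.8 * g$dosages[, 1] + 0.1 * ph$age + rnorm(n, 0, 0.5)

  cfg <- screen_config(covariates = c("age", "pc1"))
  res <- per_variant_association(g, ph, "y", cfg, min_n = 5)

  X <- cbind(1, g$dosages[, 1], ph$age, ph$pc1)
  beta_hat <- solve(crossprod(X), crossprod(X, ph$y))
  expect_lt(abs(res$beta - beta_hat[2]) / abs(beta_hat[2]), 1e-8)
  expect_equal(res$n_used, n)
})

test_that("a noiseless linear trait gives the exact slope and a floor p", {
  set.seed(37)
  n <- 60
  g <- genotype_table(sprintf("i%02d", 1:n), tiny_panel(1),
                      matrix(rbinom(n, 2, 0.5), ncol = 1))
  ph <- data.frame(id = g$individual_ids, y = 3 + 1.5 * g$dosages[, 1])
  res <- suppressWarnings(  # lm flags the perfect fit
    per_variant_association(g, ph, "y", screen_config()))
  expect_lt(abs(res$beta - 1.5), 1e-8)
  expect_lt(res$p, 1e-20)
})

test_that("constant dosage is flagged untestable, collinearity is an error", {
  n <- 30
  g <- genotype_table(sprintf("i%02d", 1:n), tiny_panel(2),
                      cbind(rep(1L, n), rbinom(n, 2, 0.5)))
  ph <- data.frame(id = g$individual_ids, y = rnorm(n), age = rnorm(n))
  res <- per_variant_association(g, ph, "y", screen_config())
  expect_true(res$untestable[1])
  expect_false(res$untestable[2])
  expect_true(is.na(res$p[1]))

  ph$age2 <- 2 * ph$age
  cfg <- screen_config(covariates = c("age", "age2"))
  expect_error(per_variant_association(g, ph, "y", cfg), "age2")
})

test_that("logistic model recovers effect direction on a strong signal", {
  set.seed(41)
  n <- 400
  g <- genotype_table(sprintf("i%03d", 1:n), tiny_panel(1),
                      matrix(rbinom(n, 2, 0.4), ncol = 1))
  ph <- data.frame(id = g$individual_ids,
                   y = 10 + 3 * g$dosages[, 1] + rnorm(n))
  res <- per_variant_association(g, ph, "y",
                                 screen_config(model = "logistic"))
  expect_gt(res$beta, 0)
  expect_lt(res$p, 0.05)
})

test_that("nominal+direction filter applies strict threshold and sign rule", {
  csa <- study_associations()
  csa <- csa[csa$trait == "csa_fast_twitch", ]
  res <- data.frame(rsid = csa$rsid, beta = csa$beta, se = NA, p = csa$p,
                    n_used = 148, untestable = FALSE)
  expect_equal(nominal_direction_filter(res, verbose = FALSE), csa$rsid)

  res2 <- data.frame(
    rsid = c("up_sig", "down_sig", "boundary", "untest"),
    beta = c(1, -1, 1, NA), se = NA,
    p = c(0.001, 0.001, 0.05, NA), n_used = 100,
    untestable = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(nominal_direction_filter(res2, verbose = FALSE), "up_sig")
})

test_that("autosome filter drops X under any label spelling", {
  v <- data.frame(rsid = sprintf("rs%02d", 1:31),
                  chrom = c(as.character(rep(1:22, length.out = 28)),
                            "X", "chrX", "x"))
  kept <- autosome_filter(v, verbose = FALSE)
  expect_length(kept, 28)
  expect_false(any(c("rs29", "rs30", "rs31") %in% kept))
  expect_equal(autosome_filter(data.frame(rsid = "a", chrom = "7"),
                               verbose = FALSE), "a")
  expect_error(autosome_filter(data.frame(rsid = "a", chrom = "Z")),
               "unrecognized")
})

test_that("lookup filter requires replication in every trait", {
  st <- study_associations()
  rsids <- unique(st$rsid)
  kept <- lookup_filter(rsids, st, c("handgrip", "fat_free_mass"),
                        verbose = FALSE)
  expect_equal(kept, rsids)  # all five replicate

  st2 <- st
  st2$p[st2$rsid == "rs850294" & st2$trait == "handgrip"] <- 0.2
  expect_equal(lookup_filter(rsids, st2, c("handgrip", "fat_free_mass"),
                             verbose = FALSE),
               setdiff(rsids, "rs850294"))

  st3 <- st[!(st$rsid == "rs850294" & st$trait == "handgrip"), ]
  expect_warning(
    kept3 <- lookup_filter(rsids, st3, c("handgrip", "fat_free_mass"),
                           verbose = FALSE),
    "rs850294")
  expect_equal(kept3, setdiff(rsids, "rs850294"))

  expect_error(lookup_filter(rsids, st, "grip_strength", verbose = FALSE),
               "grip_strength")
})

test_that("Bonferroni threshold follows the closed form", {
  expect_equal(bonferroni_threshold(0.05, 822, 3), 0.05 / 2466)
  expect_equal(round(bonferroni_threshold(0.05, 822, 3), 5), 2e-05)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10, 2), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0, 3), "positive")
})

test_that("every filter stage is idempotent and subsetting", {
  set.seed(43)
  stats <- simulate_discovery_panel(60, 10, seed = 47)
  kept <- sex_concordance_filter(stats, verbose = FALSE)
  expect_true(all(kept %in% unique(stats$rsid)))
  again <- sex_concordance_filter(stats[stats$rsid %in% kept, ],
                                  verbose = FALSE)
  expect_identical(again, kept)

  v <- data.frame(rsid = sprintf("r%02d", 1:20),
                  chrom = sample(c(1:22, "X"), 20, replace = TRUE))
  a1 <- autosome_filter(v, verbose = FALSE)
  a2 <- autosome_filter(v[v$rsid %in% a1, , drop = FALSE], verbose = FALSE)
  expect_identical(a2, a1)

  st <- study_associations()
  l1 <- lookup_filter(unique(st$rsid), st, "handgrip", verbose = FALSE)
  l2 <- lookup_filter(l1, st, "handgrip", verbose = FALSE)
  expect_identical(l2, l1)
})

test_that("full cascade reports monotone per-stage counts", {
  cfg <- demo_pipeline_config(seed = 3)
  cfg$association$n <- 400L
  cfg$case_control <- list(n_cases = 500L, n_controls = 500L)
  rep <- suppressMessages(run_pipeline(cfg, verbose = FALSE))
  expect_true(all(diff(as.integer(rep$counts)) <= 0))
  expect_equal(unname(rep$counts["sex_concordant"]), 822L)
  expect_true(all(rep$selected %in% study_panel()$rsid))
})
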