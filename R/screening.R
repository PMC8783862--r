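## The four-stage variant selection cascade:
##   1. sex-concordance filter on sex-stratified discovery statistics
##   2. covariate-adjusted per-variant association with the discovery
##      trait, keeping nominally significant effects in the required
##      direction
##   3. autosome restriction
##   4. summary-statistic lookup across additional traits, keeping
##      variants that replicate direction and nominal significance in
##      every one
## plus the Bonferroni family-wise threshold reported alongside.

#' Screening configuration
#'
#' @param alpha Nominal significance level for every filter stage,
#'   strictly between 0 and 1. Comparisons use strict `p < alpha`.
#' @param direction Required sign of the trait effect (`+1`: the effect
#'   allele must increase the trait; `-1`: decrease). A beta of exactly
#'   zero fails either direction.
#' @param autosomes_only Restrict to chromosomes 1-22.
#' @param model `"linear"` (ordinary least squares on the continuous
#'   trait) or `"logistic"` (trait median-dichotomized, logistic
#'   regression).
#' @param covariates Covariate column names entered into the design
#'   matrix alongside dosage.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, direction = 1,
                          autosomes_only = TRUE,
                          model = c("linear", "logistic"),
                          covariates = character()) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(list(alpha = alpha, direction = direction,
                 autosomes_only = autosomes_only,
                 model = match.arg(model), covariates = covariates),
            class = "screen_config")
}

#' Sex-concordance filter on stratified summary statistics
#'
#' Variants whose male and female effect estimates disagree in sign are
#' removed: a direction that flips between sexes cannot define a single
#' trait-increasing allele. A zero beta in either stratum is treated as
#' discordant (conservative).
#'
#' @param stats Long-format `data.frame` with columns `rsid`, `sex`
#'   (`"male"`/`"female"`) and `beta`; exactly one record per variant and
#'   stratum.
#' @param verbose Log input/retained counts.
#' @return Character vector of retained rsids, in input order.
#' @export
sex_concordance_filter <- function(stats, verbose = TRUE) {
  need <- c("rsid", "sex", "beta")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("stats missing column(s): ", paste(miss, collapse = ", "))
  rsids <- unique(stats$rsid)
  m <- stats[stats$sex == "male", ]
  f <- stats[stats$sex == "female", ]
  bad <- rsids[!(rsids %in% m$rsid & rsids %in% f$rsid) |
                 rsids %in% m$rsid[duplicated(m$rsid)] |
                 rsids %in% f$rsid[duplicated(f$rsid)]]
  if (length(bad))
    stop("need exactly one male and one female record per variant; ",
         "offending rsid(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bm <- m$beta[match(rsids, m$rsid)]
  bf <- f$beta[match(rsids, f$rsid)]
  keep <- sign(bm) == sign(bf) & bm != 0 & bf != 0
  if (verbose)
    message("sex-concordance filter: ", length(rsids), " -> ", sum(keep),
            " variants (", sum(!keep), " direction-discordant removed)")
  rsids[keep]
}

#' Covariate-adjusted per-variant association scan
#'
#' For each variant, the trait is regressed on effect-allele dosage with
#' the configured covariates in the design matrix. With `model = "linear"`
#' this is ordinary least squares and a Wald test on the dosage
#' coefficient; with `model = "logistic"` the trait is first
#' median-dichotomized (above the median = 1) and a binomial GLM is fit.
#' Individuals with a missing trait, covariate, or dosage are dropped
#' listwise per variant. Variants with a constant dosage column or fewer
#' than `min_n` complete cases are flagged untestable rather than raising.
#'
#' @param genotypes A [genotype_table()].
#' @param phenotypes `data.frame` with `id`, the trait column, and any
#'   covariate columns.
#' @param trait Name of the trait column.
#' @param config A [screen_config()].
#' @param min_n Minimum complete cases per variant (default 10).
#' @return A `data.frame` with one row per variant, in input order:
#'   `rsid`, `beta`, `se`, `p`, `n_used`, `untestable`.
#' @export
per_variant_association <- function(genotypes, phenotypes, trait,
                                    config = screen_config(), min_n = 10L) {
  if (!trait %in% names(phenotypes))
    stop("trait column '", trait, "' not in phenotypes")
  miss_cov <- setdiff(config$covariates, names(phenotypes))
  if (length(miss_cov))
    stop("covariate column(s) missing from phenotypes: ",
         paste(miss_cov, collapse = ", "))
  ord <- match(genotypes$individual_ids, phenotypes$id)
  if (anyNA(ord))
    stop("phenotypes missing ", sum(is.na(ord)), " genotyped individual(s)")
  ph <- phenotypes[ord, , drop = FALSE]

  y_all <- ph[[trait]]
  if (config$model == "logistic") {
    med <- stats::median(y_all, na.rm = TRUE)
    y_all <- as.integer(y_all > med)
  }
  covs <- ph[, config$covariates, drop = FALSE]
  check_collinearity(covs, config$covariates)

  res <- lapply(seq_len(nrow(genotypes$panel)), function(j) {
    d <- genotypes$dosages[, j]
    dat <- data.frame(.y = y_all, .dosage = as.numeric(d), covs)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    n_used <- nrow(dat)
    if (n_used < min_n || length(unique(dat$.dosage)) < 2)
      return(data.frame(rsid = genotypes$panel$rsid[j], beta = NA_real_,
                        se = NA_real_, p = NA_real_, n_used = n_used,
                        untestable = TRUE))
    fit <- if (config$model == "linear")
      stats::lm(.y ~ ., data = dat)
    else
      stats::glm(.y ~ ., data = dat, family = stats::binomial())
    cf <- summary(fit)$coefficients
    data.frame(rsid = genotypes$panel$rsid[j],
               beta = cf[".dosage", 1], se = cf[".dosage", 2],
               p = cf[".dosage", 4], n_used = n_used, untestable = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# a singular covariate block is a user error worth naming, unlike a
# constant dosage which is a property of the data
check_collinearity <- function(covs, names_cov) {
  if (!length(names_cov)) return(invisible())
  mm <- stats::model.matrix(~ ., data = covs[stats::complete.cases(covs), ,
                                             drop = FALSE])
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
  }
  invisible()
}

#' Nominal significance + direction filter
#'
#' Retains variants with `p < alpha` (strict) and a beta whose sign
#' matches the required direction. Untestable variants never pass.
#'
#' @param results Output of [per_variant_association()].
#' @param config A [screen_config()].
#' @param verbose Log counts.
#' @return Character vector of retained rsids, in input order.
#' @export
nominal_direction_filter <- function(results, config = screen_config(),
                                     verbose = TRUE) {
  keep <- !is.na(results$p) & results$p < config$alpha &
    !is.na(results$beta) & sign(results$beta) == config$direction
  if (verbose)
    message("nominal+direction filter (alpha = ", config$alpha, "): ",
            nrow(results), " -> ", sum(keep), " variants")
  results$rsid[keep]
}

#' Autosome filter
#'
#' Retains variants on chromosomes 1-22 only; `"X"` and `"chrX"` compare
#' equal after label normalization. An unrecognized label is an error.
#'
#' @param variants A `data.frame` with `rsid` and `chrom` columns (a
#'   [variant_panel()] works).
#' @param verbose Log counts.
#' @return Character vector of retained rsids, in input order.
#' @export
autosome_filter <- function(variants, verbose = TRUE) {
  chrom <- normalize_chrom(variants$chrom)
  keep <- chrom %in% as.character(1:22)
  if (verbose)
    message("autosome filter: ", nrow(variants), " -> ", sum(keep),
            " variants (", sum(!keep), " non-autosomal removed)")
  variants$rsid[keep]
}

#' Multi-trait summary-statistic lookup filter
#'
#' Retains variants that are nominally significant (`p < alpha`) with the
#' required effect direction in *every* listed trait of an external
#' summary-statistics table. A variant missing from any trait's records is
#' excluded with a warning; a trait entirely absent from the table is an
#' error.
#'
#' @param rsids Candidate variants.
#' @param stats Summary-statistics `data.frame` (`rsid`, `trait`, `beta`,
#'   `p`).
#' @param traits Traits that must all replicate.
#' @param config A [screen_config()].
#' @param verbose Log counts.
#' @return Character vector of retained rsids, in input order.
#' @export
lookup_filter <- function(rsids, stats, traits,
                          config = screen_config(), verbose = TRUE) {
  absent_traits <- setdiff(traits, unique(stats$trait))
  if (length(absent_traits))
    stop("trait(s) absent from summary statistics: ",
         paste(absent_traits, collapse = ", "))
  keep <- rep(TRUE, length(rsids))
  unmatched <- character(0)
  for (tr in traits) {
    st <- stats[stats$trait == tr, ]
    i <- match(rsids, st$rsid)
    unmatched <- union(unmatched, rsids[is.na(i)])
    ok <- !is.na(i) & st$p[i] < config$alpha & st$beta[i] != 0 &
      sign(st$beta[i]) == config$direction
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  if (length(unmatched))
    warning("variant(s) missing from summary statistics for >=1 trait, ",
            "excluded: ", paste(unmatched, collapse = ", "))
  if (verbose)
    message("lookup filter over {", paste(traits, collapse = ", "),
            "}: ", length(rsids), " -> ", sum(keep), " variants")
  rsids[keep]
}

#' Bonferroni family-wise significance threshold
#'
#' `alpha / (n_variants * n_traits)`: the threshold reported alongside the
#' nominal cascade (which itself selects at the nominal level).
#'
#' @param alpha Family-wise level.
#' @param n_variants,n_traits Positive test counts.
#' @return The corrected per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 822, 3)  # ~2e-05, printed as 0.00002
#' @export
bonferroni_threshold <- function(alpha, n_variants, n_traits = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_variants < 1 || n_traits < 1)
    stop("n_variants and n_traits must be positive counts")
  alpha / (n_variants * n_traits)
}

#' Run the full screening cascade
#'
#' Applies, in order: sex-concordance filter on the discovery summary
#' statistics, covariate-adjusted per-variant association with the
#' discovery trait plus the nominal+direction filter, the autosome filter,
#' and the multi-trait lookup filter. Per-stage retained counts are
#' logged and returned, emulating the published 855 -> 822 -> 31 -> 28 -> 5
#' style cascade on whatever inputs are supplied.
#'
#' @param discovery_stats Sex-stratified summary statistics (see
#'   [sex_concordance_filter()]); `NULL` skips stage 1.
#' @param genotypes A [genotype_table()] covering the surviving variants.
#' @param phenotypes Phenotype/covariate table.
#' @param trait Discovery trait column name.
#' @param lookup_stats Summary statistics for the replication traits;
#'   `NULL` skips stage 4.
#' @param lookup_traits Traits that must all replicate in stage 4.
#' @param config A [screen_config()].
#' @param verbose Log per-stage counts.
#' @return A list of class `screen_result`: `selected` (rsids surviving
#'   all stages), `counts` (named integer vector per stage),
#'   `association` (the stage-2 per-variant results), `stages` (rsids
#'   retained after each stage), `bonferroni` (threshold implied by the
#'   stage-2 variant count and number of cascade traits).
#' @export
screen_cascade <- function(discovery_stats = NULL, genotypes, phenotypes,
                           trait, lookup_stats = NULL,
                           lookup_traits = character(),
                           config = screen_config(), verbose = TRUE) {
  counts <- c(input = nrow(genotypes$panel))
  stages <- list()

  current <- genotypes$panel$rsid
  if (!is.null(discovery_stats)) {
    counts["input"] <- length(unique(discovery_stats$rsid))
    current <- sex_concordance_filter(discovery_stats, verbose = verbose)
    current <- intersect(current, genotypes$panel$rsid)
    stages$sex_concordant <- current
    counts["sex_concordant"] <- length(current)
  }
  geno <- subset_variants(genotypes, current)
  assoc <- per_variant_association(geno, phenotypes, trait, config)
  current <- nominal_direction_filter(assoc, config, verbose = verbose)
  stages$associated <- current
  counts["associated"] <- length(current)

  if (config$autosomes_only) {
    panel_now <- geno$panel[match(current, geno$panel$rsid), , drop = FALSE]
    current <- autosome_filter(panel_now, verbose = verbose)
    stages$autosomal <- current
    counts["autosomal"] <- length(current)
  }

  if (!is.null(lookup_stats) && length(lookup_traits)) {
    current <- lookup_filter(current, lookup_stats, lookup_traits, config,
                             verbose = verbose)
    stages$replicated <- current
    counts["replicated"] <- length(current)
  }

  n_traits <- 1L + length(lookup_traits)
  bonf <- bonferroni_threshold(config$alpha,
                               max(1L, nrow(geno$panel)), n_traits)
  if (verbose)
    message("cascade counts: ",
            paste(names(counts), counts, sep = "=", collapse = " -> "),
            "; Bonferroni threshold ", signif(bonf, 3))
  structure(list(selected = current, counts = counts,
                 association = assoc, stages = stages, bonferroni = bonf),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result\n  cascade: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = " -> "),
      "\n  selected: ", paste(x$selected, collapse = ", "),
      "\n  Bonferroni threshold: ", signif(x$bonferroni, 3), "\n", sep = "")
  invisible(x)
}
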