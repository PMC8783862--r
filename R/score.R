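## The unweighted allele-count polygenic score: each individual's score is
## the number of effect alleles carried over a fixed variant set (0..2m,
## heterozygotes contribute 1), dichotomized at a carrier threshold.
## The exact score distribution implied by Hardy-Weinberg equilibrium is a
## Poisson-binomial over per-locus genotype triples, computed by
## sequential convolution.

#' Allele-count polygenic score
#'
#' Sums effect-allele dosages over a variant set: a homozygous effect
#' genotype adds 2, a heterozygote 1. No beta weighting is applied; the
#' score is a raw allele count in `[0, 2m]`.
#'
#' @param genotypes A [genotype_table()].
#' @param variant_set Variants to score (default: all in the table). All
#'   must be present.
#' @param missing_policy `"exclude"`: any missing dosage makes the
#'   individual's score `NA` (and excludes them downstream);
#'   `"maf_impute"`: a missing dosage contributes its expectation
#'   `2 * maf` (requires panel `maf`; scores are then non-integer for
#'   affected individuals).
#' @return A `data.frame` of class `score_vector` with columns `id`,
#'   `score`, `n_missing`.
#' @examples
#' g <- genotype_table(c("a", "b"), study_panel(),
#'                     rbind(rep(2L, 5), rep(0L, 5)))
#' allele_count_score(g)$score  # 10 and 0
#' @export
allele_count_score <- function(genotypes, variant_set = NULL,
                               missing_policy = c("exclude", "maf_impute")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(variant_set)) variant_set <- genotypes$panel$rsid
  geno <- subset_variants(genotypes, variant_set)
  dos <- geno$dosages
  n_missing <- rowSums(is.na(dos))
  if (missing_policy == "maf_impute") {
    if (anyNA(geno$panel$maf) && any(n_missing > 0))
      stop("maf_impute needs a maf for every scored variant")
    exp_d <- matrix(2 * geno$panel$maf, nrow = nrow(dos),
                    ncol = ncol(dos), byrow = TRUE)
    d <- ifelse(is.na(dos), exp_d, dos)
    score <- rowSums(d)
  } else {
    score <- rowSums(dos)  # NA if any dosage missing
  }
  out <- data.frame(id = geno$individual_ids, score = score,
                    n_missing = n_missing, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Dichotomize scores into carrier / non-carrier groups
#'
#' @param scores A [allele_count_score()] result (or any `data.frame` with
#'   a `score` column).
#' @param threshold Minimum score for the carrier ("high") group; the
#'   default 2 splits `>= 2` alleles vs `0-1`.
#' @return `scores` with a logical `carrier` column (`NA` score gives
#'   `NA` carrier status).
#' @export
dichotomize <- function(scores, threshold = 2) {
  if (threshold < 0) stop("threshold must be >= 0")
  scores$carrier <- scores$score >= threshold
  scores
}

#' Exact allele-count score distribution under Hardy-Weinberg equilibrium
#'
#' The score over m independent loci with effect-allele frequencies
#' `p_i` is a sum of independent Binomial(2, p_i) variables (a
#' Poisson-binomial on genotype triples). The exact distribution is
#' computed by sequentially convolving the per-locus genotype
#' distributions `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param mafs Effect-allele frequencies, each in `[0, 1]`. A frequency of
#'   0 contributes a point mass at dosage 0 (the distribution is still
#'   defined over `0..2m`).
#' @return Numeric vector of probabilities named `"0"` .. `"2m"`, summing
#'   to 1.
#' @examples
#' score_distribution_hwe(0.5)                   # (0.25, 0.5, 0.25)
#' d <- score_distribution_hwe(study_panel("controls")$maf)
#' sum(d[as.integer(names(d)) >= 2])             # carrier probability
#' @export
score_distribution_hwe <- function(mafs) {
  if (any(is.na(mafs)) || any(mafs < 0 | mafs > 1))
    stop("every maf must lie in [0, 1]")
  dist <- 1
  for (p in mafs) {
    locus <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    new <- numeric(length(dist) + 2)
    for (k in 0:2)
      new[seq_along(dist) + k] <- new[seq_along(dist) + k] + dist * locus[k + 1]
    dist <- new
  }
  names(dist) <- 0:(length(dist) - 1)
  dist
}

#' Carrier probability implied by Hardy-Weinberg equilibrium
#'
#' `P(score >= threshold)` under [score_distribution_hwe()].
#'
#' @inheritParams score_distribution_hwe
#' @param threshold Carrier threshold (default 2).
#' @return A probability.
#' @export
carrier_probability_hwe <- function(mafs, threshold = 2) {
  d <- score_distribution_hwe(mafs)
  sum(d[as.integer(names(d)) >= threshold])
}

#' Tabulate a score histogram
#'
#' @param scores A [allele_count_score()] result.
#' @param max_score Upper bound of the support (default: observed max).
#' @return `data.frame` with `score` and `count` (NA scores dropped).
#' @export
score_histogram <- function(scores, max_score = NULL) {
  s <- scores$score[!is.na(scores$score)]
  if (is.null(max_score)) max_score <- if (length(s)) max(s) else 0
  counts <- table(factor(floor(s), levels = 0:max_score))
  data.frame(score = as.integer(names(counts)),
             count = as.integer(counts))
}
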