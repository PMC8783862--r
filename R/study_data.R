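#' The five selected testosterone-increasing variants
#'
#' The published five-SNP panel that survives the full screening cascade:
#' *DOCK3* rs77031559 (G), *ESR1* rs190930099 (G), *GLIS3* rs34706136
#' (TG insertion), *GRAMD1B* rs850294 (T) and *TRAIP* rs62260729 (C).
#' Effect-allele frequencies are given separately for the power-athlete and
#' control groups, as fractions.
#'
#' @param group `"athletes"` or `"controls"`: which group's allele
#'   frequencies to place in the `maf` column.
#' @return A [variant_panel()] with an extra `gene` column.
#' @examples
#' study_panel("controls")$maf  # note the zero-frequency ESR1 allele
#' @export
study_panel <- function(group = c("athletes", "controls")) {
  group <- match.arg(group)
  maf_ath <- c(0.060, 0.016, 0.450, 0.107, 0.396)
  maf_ctl <- c(0.063, 0.000, 0.430, 0.093, 0.351)
  panel <- variant_panel(
    rsid = c("rs77031559", "rs190930099", "rs34706136", "rs850294",
             "rs62260729"),
    chrom = c("3", "6", "9", "11", "3"),
    pos = c(51417310L, 152061341L, 4288250L, 123393838L, 49869051L),
    effect_allele = c("G", "G", "TG", "T", "C"),
    other_allele = c("A", "A", "T", "C", "T"),
    maf = if (group == "athletes") maf_ath else maf_ctl
  )
  panel$gene <- c("DOCK3", "ESR1", "GLIS3", "GRAMD1B", "TRAIP")
  panel
}

#' Published per-variant association statistics for the five variants
#'
#' Effect sizes and P values of the five testosterone-increasing alleles
#' against four traits: serum testosterone (nmol/l per allele, from the
#' source GWAS), cross-sectional area of fast-twitch muscle fibers
#' (um^2 per allele), handgrip strength and fat-free mass (UK Biobank
#' summary statistics). Every beta is positive: the effect allele is by
#' construction the trait-increasing allele.
#'
#' @return A `data.frame` with columns `rsid`, `gene`, `trait`,
#'   `effect_allele`, `beta`, `p` (20 rows: 5 variants x 4 traits).
#' @examples
#' subset(study_associations(), trait == "csa_fast_twitch")
#' @export
study_associations <- function() {
  panel <- study_panel()
  traits <- c("testosterone", "csa_fast_twitch", "handgrip", "fat_free_mass")
  beta <- rbind(
    rs77031559  = c(0.027, 939.5, 0.072, 0.101),
    rs190930099 = c(0.135, 2123.1, 0.367, 0.485),
    rs34706136  = c(0.012, 361.1, 0.090, 0.020),
    rs850294    = c(0.034, 824.8, 0.055, 0.025),
    rs62260729  = c(0.014, 407.8, 0.048, 0.054)
  )
  p <- rbind(
    rs77031559  = c(9.2e-09, 0.016, 0.0450, 0.00070),
    rs190930099 = c(8.1e-11, 0.028, 0.0024, 0.0000013),
    rs34706136  = c(2.7e-08, 0.044, 0.0000015, 0.011),
    rs850294    = c(5.2e-18, 0.011, 0.0499, 0.038),
    rs62260729  = c(3.0e-10, 0.033, 0.0110, 0.00067)
  )
  out <- expand.grid(rsid = rownames(beta), trait = traits,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(out$rsid, rownames(beta)), match(out$trait, traits))
  out$gene <- panel$gene[match(out$rsid, panel$rsid)]
  out$effect_allele <- panel$effect_allele[match(out$rsid, panel$rsid)]
  out$beta <- beta[idx]
  out$p <- p[idx]
  out[, c("rsid", "gene", "trait", "effect_allele", "beta", "p")]
}

#' Published cohort sizes and carrier proportions
#'
#' Group sizes of the case-control validation cohorts (international-level
#' power athletes vs non-athlete controls) and the published percentage of
#' each group carrying two or more testosterone-increasing alleles.
#'
#' @return A list with `n_athletes`, `n_controls`, `carrier_pct_athletes`,
#'   `carrier_pct_controls`.
#' @export
study_cohorts <- function() {
  list(
    n_athletes = 222L,
    n_controls = 151L,
    carrier_pct_athletes = 68.9,
    carrier_pct_controls = 55.6
  )
}
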