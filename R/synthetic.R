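## Synthetic cohorts with the statistical structure the screen assumes:
## Hardy-Weinberg genotypes in linkage equilibrium, additive-linear traits
## with Gaussian noise, sex-stratified discovery panels, and two-group
## case-control samples drawn at group-specific allele frequencies.

# Derive a per-stream seed from a global seed, so stream j always sees the
# same draws no matter how many other streams exist (adding variants to a
# panel does not perturb earlier columns). Lehmer-style mixing, kept < 2^31.
substream_seed <- function(seed, stream) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(stream) * 69621) %% 2147483647)
}

#' Specify a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: size, variant panel, trait
#' models, sex ratio, covariate distributions, and the seed that makes the
#' cohort reproducible.
#'
#' @param n Number of individuals (>= 1).
#' @param panel A [variant_panel()] with allele frequencies in `maf`.
#' @param trait_models List of [trait_model()] objects.
#' @param sex_ratio Fraction of males in `[0, 1]`.
#' @param covariates Named list describing covariate distributions: numeric
#'   covariates as `c(mean = , sd = )`, categorical ones as a named vector
#'   of category weights.
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, panel, trait_models = list(), sex_ratio = 0.5,
                        covariates = default_covariates(), seed = 1L) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a positive count")
  validate_panel(panel)
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  for (m in trait_models) {
    missing <- setdiff(names(m$betas), panel$rsid)
    if (length(missing))
      stop("trait model '", m$trait_name, "' references variant(s) not in ",
           "the panel: ", paste(missing, collapse = ", "))
  }
  structure(list(n = as.integer(n), panel = panel,
                 trait_models = trait_models, sex_ratio = sex_ratio,
                 covariates = covariates, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_covariates <- function() {
  list(
    age = c(mean = 30, sd = 8),
    pc1 = c(mean = 0, sd = 1),
    pc2 = c(mean = 0, sd = 1),
    pc3 = c(mean = 0, sd = 1),
    activity = c(mild = 0.2, moderate = 0.4, high = 0.3, extreme = 0.1),
    training = c(mixed = 0.6, resistance = 0.25, endurance = 0.15)
  )
}

#' Specify an additive trait model
#'
#' Traits are generated as
#' `intercept + sum(beta_j * dosage_j) + sum(covariate effects) + N(0, sd)`.
#' The intercept may be sex-specific (named vector with `female` and `male`
#' entries), which is how baseline fiber-size differences between sexes are
#' emulated; per-variant effects themselves are shared across sexes.
#'
#' @param trait_name Trait label (becomes the phenotype column name).
#' @param intercept Scalar intercept, or `c(female = , male = )`.
#' @param betas Named numeric vector, rsid -> trait units per effect-allele
#'   copy.
#' @param covariate_betas Named numeric vector of effects for numeric
#'   covariate columns.
#' @param residual_sd Residual standard deviation (>= 0), trait units.
#' @return A list of class `trait_model`.
#' @export
trait_model <- function(trait_name, intercept = 0, betas = numeric(),
                        covariate_betas = numeric(), residual_sd = 1) {
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  if (length(intercept) > 1 &&
      !all(c("female", "male") %in% names(intercept)))
    stop("a sex-specific intercept needs 'female' and 'male' entries")
  structure(list(trait_name = trait_name, intercept = intercept,
                 betas = betas, covariate_betas = covariate_betas,
                 residual_sd = residual_sd),
            class = "trait_model")
}

#' Default fast-twitch fiber cross-sectional area model
#'
#' CSA in um^2 with sex-specific baselines (males ~5925, females ~4305) and
#' the published per-allele effects of the five-variant panel. The residual
#' SD defaults to 1000 um^2, large enough that each variant explains well
#' under 5% of trait variance at its study allele frequency.
#'
#' @param panel Panel whose variants receive effects; defaults to
#'   [study_panel()].
#' @param residual_sd Residual SD in um^2.
#' @return A [trait_model()].
#' @export
csa_trait_model <- function(panel = study_panel(), residual_sd = 1000) {
  assoc <- study_associations()
  csa <- assoc[assoc$trait == "csa_fast_twitch", ]
  betas <- stats::setNames(csa$beta, csa$rsid)
  betas <- betas[names(betas) %in% panel$rsid]
  trait_model("csa_fast_twitch",
              intercept = c(female = 4305, male = 5925),
              betas = betas, residual_sd = residual_sd)
}

# shared sampler: one Binomial(2, maf) column per variant, each on its own
# seed sub-stream
sample_hwe_dosages <- function(panel, n, seed) {
  dos <- matrix(NA_integer_, nrow = n, ncol = nrow(panel))
  for (j in seq_len(nrow(panel))) {
    set.seed(substream_seed(seed, j))
    dos[, j] <- stats::rbinom(n, 2L, panel$maf[j])
  }
  dos
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each variant's dosage column is drawn independently as Binomial(2, maf):
#' Hardy-Weinberg proportions within variants, linkage equilibrium between
#' them. Each variant uses its own seed sub-stream derived from the spec
#' seed, so extending the panel leaves earlier columns untouched.
#'
#' @param spec A [cohort_spec()] (its `panel` must carry non-missing `maf`).
#' @param id_prefix Prefix for generated individual ids.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(spec, id_prefix = "ind") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (anyNA(spec$panel$maf))
    stop("all panel variants need a maf to simulate genotypes")
  ids <- sprintf("%s_%05d", id_prefix, seq_len(spec$n))
  dos <- sample_hwe_dosages(spec$panel, spec$n, spec$seed)
  genotype_table(ids, spec$panel, dos)
}

#' Simulate covariate columns
#'
#' Sex is drawn from the spec's `sex_ratio`; numeric covariates from their
#' configured normal distributions; categorical covariates from their
#' category weights. Age is truncated below at 18.
#'
#' @param spec A [cohort_spec()].
#' @param ids Individual ids (defaults to the ids [simulate_genotypes()]
#'   would generate).
#' @return A `data.frame` with an `id` column, a `sex` column
#'   (`"female"`/`"male"`), and one column per configured covariate.
#' @export
simulate_covariates <- function(spec, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("ind_%05d", seq_len(spec$n))
  n <- length(ids)
  set.seed(substream_seed(spec$seed, 100003L))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
  for (nm in names(spec$covariates)) {
    d <- spec$covariates[[nm]]
    if (!is.null(names(d)) && all(c("mean", "sd") %in% names(d))) {
      x <- stats::rnorm(n, d[["mean"]], d[["sd"]])
      if (nm == "age") x <- pmax(18, x)
      out[[nm]] <- x
    } else {
      out[[nm]] <- sample(names(d), n, replace = TRUE,
                          prob = d / sum(d))
    }
  }
  out
}

#' Simulate phenotypes from genotypes under an additive trait model
#'
#' @param genotypes A [genotype_table()] containing every variant the model
#'   references.
#' @param model A [trait_model()].
#' @param covariates Optional covariate `data.frame` (with `id` and, for
#'   sex-specific intercepts, a `sex` column) aligned to the genotype table
#'   by `id`.
#' @param seed Integer seed for the residual noise.
#' @return A `data.frame` with `id` and one column named after the trait.
#' @export
simulate_phenotypes <- function(genotypes, model, covariates = NULL,
                                seed = 1L) {
  stopifnot(inherits(model, "trait_model"))
  missing <- setdiff(names(model$betas), genotypes$panel$rsid)
  if (length(missing))
    stop("variant(s) in trait model absent from genotypes: ",
         paste(missing, collapse = ", "))
  n <- length(genotypes$individual_ids)
  if (length(model$intercept) > 1) {
    if (is.null(covariates) || is.null(covariates$sex))
      stop("a sex-specific intercept needs a covariate table with a ",
           "'sex' column")
    sex <- covariates$sex[match(genotypes$individual_ids, covariates$id)]
    base <- unname(model$intercept[sex])
  } else {
    base <- rep(unname(model$intercept), n)
  }
  y <- base
  if (length(model$betas)) {
    dos <- genotypes$dosages[, names(model$betas), drop = FALSE]
    y <- y + as.vector(dos %*% model$betas)
  }
  if (length(model$covariate_betas)) {
    for (nm in names(model$covariate_betas)) {
      if (is.null(covariates[[nm]]))
        stop("covariate '", nm, "' not found in covariate table")
      y <- y + model$covariate_betas[[nm]] *
        covariates[[nm]][match(genotypes$individual_ids, covariates$id)]
    }
  }
  set.seed(substream_seed(seed, 200003L))
  y <- y + stats::rnorm(n, 0, model$residual_sd)
  out <- data.frame(id = genotypes$individual_ids, stringsAsFactors = FALSE)
  out[[model$trait_name]] <- y
  out
}

#' Simulate a full cohort (genotypes, covariates, phenotypes)
#'
#' @param spec A [cohort_spec()].
#' @return A list with `genotypes` ([genotype_table()]) and `phenotypes`
#'   (a `data.frame` of id, sex, covariates and one column per trait model).
#' @export
simulate_cohort <- function(spec) {
  geno <- simulate_genotypes(spec)
  covar <- simulate_covariates(spec, geno$individual_ids)
  pheno <- covar
  for (k in seq_along(spec$trait_models)) {
    m <- spec$trait_models[[k]]
    tr <- simulate_phenotypes(geno, m, covar,
                              seed = substream_seed(spec$seed, 300007L + k))
    pheno[[m$trait_name]] <- tr[[m$trait_name]][match(pheno$id, tr$id)]
  }
  list(genotypes = geno, phenotypes = pheno)
}

#' Simulate a sex-stratified discovery panel of summary statistics
#'
#' Builds the input the sex-concordance filter consumes: per-variant male
#' and female effect estimates where exactly `n_discordant` variants have
#' opposite-signed effects between sexes and the rest agree in sign.
#' A small fraction of variants is placed on the X chromosome so the
#' autosome filter also has something to act on downstream.
#'
#' @param n_total Total number of variants.
#' @param n_discordant Number of direction-discordant variants
#'   (`0 <= n_discordant <= n_total`).
#' @param seed Integer seed.
#' @param trait Trait label for the records.
#' @return A `data.frame` in long format: two rows per variant (`sex`
#'   `"male"` and `"female"`), with `rsid`, `chrom`, `effect_allele`,
#'   `beta`, `p`.
#' @export
simulate_discovery_panel <- function(n_total, n_discordant, seed = 1L,
                                     trait = "testosterone") {
  if (n_total < 0 || n_discordant < 0 || n_discordant > n_total)
    stop("need 0 <= n_discordant <= n_total")
  set.seed(substream_seed(seed, 400009L))
  rsid <- sprintf("snp%05d", seq_len(n_total))
  chrom <- sample(c(as.character(1:22), "X"), n_total, replace = TRUE,
                  prob = c(rep(0.96 / 22, 22), 0.04))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_total, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  base_sign <- sample(c(-1, 1), n_total, replace = TRUE)
  mag_m <- stats::rlnorm(n_total, meanlog = -3.5, sdlog = 0.5)
  mag_f <- stats::rlnorm(n_total, meanlog = -3.5, sdlog = 0.5)
  flip <- rep(1, n_total)
  if (n_discordant > 0)
    flip[sample.int(n_total, n_discordant)] <- -1
  p_m <- 10^stats::runif(n_total, -15, -8)
  p_f <- 10^stats::runif(n_total, -15, -8)
  rbind(
    data.frame(rsid = rsid, chrom = chrom, trait = trait, sex = "male",
               effect_allele = ea, other_allele = oa,
               beta = base_sign * mag_m, p = p_m,
               stringsAsFactors = FALSE),
    data.frame(rsid = rsid, chrom = chrom, trait = trait, sex = "female",
               effect_allele = ea, other_allele = oa,
               beta = base_sign * flip * mag_f, p = p_f,
               stringsAsFactors = FALSE)
  )
}

#' Simulate a case-control genotype sample
#'
#' Cases and controls are drawn under Hardy-Weinberg equilibrium at their
#' own group's allele frequencies, which is how carrier enrichment arises
#' in the simulated data.
#'
#' @param panel_cases,panel_controls [variant_panel()]s covering the same
#'   rsids (frequencies may differ; this is the point).
#' @param n_cases,n_controls Group sizes.
#' @param seed Integer seed.
#' @return A list with `genotypes` (a combined [genotype_table()], cases
#'   first) and `group` (factor with levels `case`, `control`).
#' @export
simulate_case_control <- function(panel_cases, panel_controls,
                                  n_cases, n_controls, seed = 1L) {
  if (!setequal(panel_cases$rsid, panel_controls$rsid))
    stop("case and control panels must cover the same rsids")
  panel_controls <- panel_controls[match(panel_cases$rsid,
                                         panel_controls$rsid), ,
                                   drop = FALSE]
  spec_ca <- cohort_spec(n_cases, panel_cases, seed = substream_seed(seed, 1L))
  spec_co <- cohort_spec(n_controls, panel_controls,
                         seed = substream_seed(seed, 2L))
  g_ca <- simulate_genotypes(spec_ca, id_prefix = "case")
  g_co <- simulate_genotypes(spec_co, id_prefix = "ctrl")
  geno <- genotype_table(c(g_ca$individual_ids, g_co$individual_ids),
                         panel_cases,
                         rbind(g_ca$dosages, g_co$dosages))
  group <- factor(rep(c("case", "control"), c(n_cases, n_controls)),
                  levels = c("case", "control"))
  list(genotypes = geno, group = group)
}
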