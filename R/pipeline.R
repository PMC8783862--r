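## End-to-end orchestration: simulate a discovery panel and cohort, run
## the screening cascade, score a case-control sample over the selected
## variants, and compute the validation statistics, writing per-stage TSV
## outputs and returning a summary report.

#' Demo pipeline configuration
#'
#' The bundled configuration runs the whole cascade on synthetic data
#' shaped like the study: an 855-variant sex-stratified discovery panel
#' with 33 direction-discordant variants, a fiber cross-sectional-area
#' cohort in which the five published variants carry their published
#' effects (all other variants are null), and a case-control sample drawn
#' at the published athlete/control allele frequencies. The case-control
#' groups default to 2000 per arm so carrier enrichment is reliably
#' visible above sampling noise; the published study itself had 222
#' athletes and 151 controls.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory for result TSVs.
#' @return A nested list understood by [run_pipeline()]; serializable
#'   with [write_pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = tempfile("polyscreen_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    discovery = list(n_total = 855L, n_discordant = 33L),
    association = list(n = 600L, residual_sd = 1000,
                       alpha = 0.05, model = "linear",
                       covariates = c("age", "sex")),
    lookup = list(traits = c("handgrip", "fat_free_mass")),
    score = list(threshold = 2L),
    case_control = list(n_cases = 2000L, n_controls = 2000L),
    correlation = list(trait = "testosterone", covariates = "age",
                       residual_sd = 4.6)
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through YAML unchanged.
#'
#' @param config A configuration list.
#' @param path YAML file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: the configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# discovery statistics: synthetic variants plus the five published
# variants appended as sign-concordant rows, so the published panel can
# survive stage 1 of the cascade
build_discovery_stats <- function(n_total, n_discordant, seed) {
  panel5 <- study_panel("athletes")
  assoc <- study_associations()
  tst <- assoc[assoc$trait == "testosterone", ]
  n_synth <- n_total - nrow(panel5)
  if (n_synth < 0) stop("n_total smaller than the built-in panel")
  synth <- simulate_discovery_panel(n_synth, n_discordant, seed)
  b <- tst$beta[match(panel5$rsid, tst$rsid)]
  p <- tst$p[match(panel5$rsid, tst$rsid)]
  real <- do.call(rbind, lapply(c("male", "female"), function(sx)
    data.frame(rsid = panel5$rsid, chrom = panel5$chrom,
               trait = "testosterone", sex = sx,
               effect_allele = panel5$effect_allele,
               other_allele = panel5$other_allele,
               beta = b, p = p, stringsAsFactors = FALSE)))
  rbind(synth, real)
}

# cohort panel for the association stage: retained synthetic variants get
# random common frequencies and no trait effect; the five published
# variants keep their published frequencies and effects
build_association_cohort <- function(retained, discovery_stats, cfg, seed) {
  panel5 <- study_panel("athletes")
  synth_ids <- setdiff(retained, panel5$rsid)
  d <- discovery_stats[discovery_stats$sex == "male", ]
  d <- d[match(synth_ids, d$rsid), , drop = FALSE]
  set.seed(substream_seed(seed, 500009L))
  synth_panel <- if (length(synth_ids))
    variant_panel(synth_ids, d$chrom, seq_along(synth_ids) * 1000L,
                  d$effect_allele, d$other_allele,
                  maf = stats::runif(length(synth_ids), 0.05, 0.5))
  else NULL
  keep5 <- panel5[panel5$rsid %in% retained,
                  c("rsid", "chrom", "pos", "effect_allele",
                    "other_allele", "maf")]
  panel <- rbind(synth_panel, keep5)
  class(panel) <- c("variant_panel", "data.frame")
  spec <- cohort_spec(cfg$n, panel,
                      trait_models = list(
                        csa_trait_model(panel,
                                        residual_sd = cfg$residual_sd)),
                      seed = substream_seed(seed, 600011L))
  simulate_cohort(spec)
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes, with one master seed: discovery-panel simulation ->
#' sex-concordance filter -> cohort simulation -> covariate-adjusted
#' association scan with nominal+direction filter -> autosome filter ->
#' multi-trait summary-statistic lookup -> allele-count scoring of a
#' simulated case-control sample -> carrier odds-ratio / chi-square
#' comparison and score-phenotype correlation. Per-stage tables are
#' written to `config$out_dir` and a summary report is returned.
#'
#' @param config A configuration list (see [demo_pipeline_config()]) or
#'   the path to its YAML serialization.
#' @param verbose Log per-stage counts.
#' @return A list of class `pipeline_report`: `counts`, `selected`,
#'   `bonferroni`, `carrier` (a `carrier_comparison`), `correlation`
#'   (a `correlation_result`), `files`, `seed`.
#' @export
run_pipeline <- function(config = demo_pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(config$seed)

  disc <- build_discovery_stats(config$discovery$n_total,
                                config$discovery$n_discordant, seed)
  cohort_cfg <- config$association
  retained <- sex_concordance_filter(disc, verbose = FALSE)
  cohort <- build_association_cohort(retained, disc, cohort_cfg, seed)

  scr_cfg <- screen_config(alpha = cohort_cfg$alpha,
                           model = cohort_cfg$model,
                           covariates = cohort_cfg$covariates)
  screen <- withCallingHandlers(
    screen_cascade(discovery_stats = disc,
                   genotypes = cohort$genotypes,
                   phenotypes = cohort$phenotypes,
                   trait = "csa_fast_twitch",
                   lookup_stats = study_associations(),
                   lookup_traits = config$lookup$traits,
                   config = scr_cfg, verbose = verbose),
    warning = function(w) {
      # variants absent from the lookup table are excluded by design here:
      # the external summary statistics only cover the published panel
      if (grepl("missing from summary statistics", conditionMessage(w))) {
        if (verbose) message("note: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  if (!length(screen$selected))
    stop("screening stage selected no variants")

  cc <- simulate_case_control(study_panel("athletes"),
                              study_panel("controls"),
                              config$case_control$n_cases,
                              config$case_control$n_controls,
                              seed = substream_seed(seed, 700003L))
  scores <- allele_count_score(cc$genotypes, screen$selected)
  carrier <- carrier_case_control(cc$group, scores,
                                  threshold = config$score$threshold)

  # score-phenotype correlation inside the case group, as in the athlete
  # validation cohorts
  case_idx <- cc$group == "case"
  case_geno <- genotype_table(
    cc$genotypes$individual_ids[case_idx],
    cc$genotypes$panel,
    cc$genotypes$dosages[case_idx, , drop = FALSE])
  assoc <- study_associations()
  tr <- config$correlation$trait
  tb <- assoc[assoc$trait == tr, ]
  t_model <- trait_model(tr, intercept = 22,
                         betas = stats::setNames(tb$beta, tb$rsid),
                         residual_sd = config$correlation$residual_sd)
  cov_spec <- cohort_spec(length(case_geno$individual_ids),
                          case_geno$panel,
                          seed = substream_seed(seed, 800003L))
  covar <- simulate_covariates(cov_spec, case_geno$individual_ids)
  pheno <- simulate_phenotypes(case_geno, t_model, covar,
                               seed = substream_seed(seed, 900001L))
  case_scores <- scores[case_idx, ]
  corr <- partial_correlation(
    case_scores$score, pheno[[tr]],
    covariates = covar[, config$correlation$covariates, drop = FALSE])

  tab <- as.data.frame.matrix(unclass(carrier$table))
  tab <- cbind(group = rownames(tab), tab)
  files <- write_results(
    list(association = screen$association,
         selected = data.frame(rsid = screen$selected),
         cascade_counts = data.frame(stage = names(screen$counts),
                                     n = as.integer(screen$counts)),
         scores = dichotomize(scores, config$score$threshold),
         score_histogram = score_histogram(scores,
                                           2 * length(screen$selected)),
         carrier_table = tab,
         statistics = data.frame(
           measure = c("odds_ratio", "or_ci_low", "or_ci_high",
                       "chi_square", "chi_square_p", "bonferroni",
                       "correlation_r", "correlation_p"),
           value = c(carrier$odds_ratio$or, carrier$odds_ratio$ci,
                     carrier$chi_square$statistic, carrier$chi_square$p,
                     screen$bonferroni, corr$r, corr$p))),
    config$out_dir, verbose = verbose)

  structure(list(counts = screen$counts, selected = screen$selected,
                 bonferroni = screen$bonferroni, carrier = carrier,
                 correlation = corr, files = files, seed = seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$seed, ")\n  cascade: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = " -> "),
      "\n  selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  print(x$carrier)
  print(x$correlation)
  invisible(x)
}

#' Write the bundled fixtures
#'
#' Materializes the package's built-in inputs as plain-text files: the
#' published five-variant association table as a summary-statistics TSV,
#' the athlete and control variant panels with their allele frequencies,
#' a small synthetic cohort (VCF, dosage TSV and phenotype TSV), and a
#' demo pipeline configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic cohort.
#' @param n Cohort size of the synthetic genotype fixture.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n = 60L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", out_dir)
  paths <- c(
    summary_stats = file.path(out_dir, "summary_stats.tsv"),
    panel_athletes = file.path(out_dir, "panel_athletes.tsv"),
    panel_controls = file.path(out_dir, "panel_controls.tsv"),
    genotypes_vcf = file.path(out_dir, "cohort.vcf"),
    dosages = file.path(out_dir, "cohort_dosages.tsv"),
    phenotypes = file.path(out_dir, "cohort_phenotypes.tsv"),
    config = file.path(out_dir, "pipeline_config.yaml")
  )
  utils::write.table(study_associations(), paths["summary_stats"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_panel_tsv(study_panel("athletes"), paths["panel_athletes"])
  write_panel_tsv(study_panel("controls"), paths["panel_controls"])

  spec <- cohort_spec(n, study_panel("athletes"),
                      trait_models = list(csa_trait_model()), seed = seed)
  cohort <- simulate_cohort(spec)
  write_vcf(cohort$genotypes, paths["genotypes_vcf"])
  write_dosage_tsv(cohort$genotypes, paths["dosages"])
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pipeline_config(
    demo_pipeline_config(seed = seed, out_dir = "polyscreen_output"),
    paths["config"])
  invisible(paths)
}
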