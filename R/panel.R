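#' Construct a variant panel
#'
#' A variant panel describes the SNPs (or short indels) a screen or score
#' operates on: identifier, genomic location, which allele is the *effect*
#' allele (the allele whose dosage the score counts), and its population
#' frequency.
#'
#' @param rsid Character vector of unique variant identifiers.
#' @param chrom Chromosome labels (`"1"`--`"22"` or `"X"`; a `"chr"` prefix
#'   is tolerated and stripped).
#' @param pos 1-based positions.
#' @param effect_allele Allele whose copies are counted as dosage. May be
#'   multi-base (e.g. `"TG"` for an insertion allele).
#' @param other_allele The non-effect allele.
#' @param maf Effect-allele frequency in `[0, 1]`. Usually the minor-allele
#'   frequency, but may exceed 0.5 when the effect allele is the major one.
#' @return A `data.frame` with class `variant_panel`.
#' @examples
#' variant_panel("rs850294", "11", 123393838, "T", "C", maf = 0.107)
#' @export
variant_panel <- function(rsid, chrom, pos, effect_allele, other_allele,
                          maf = NA_real_) {
  panel <- data.frame(
    rsid = as.character(rsid),
    chrom = normalize_chrom(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    maf = as.numeric(maf),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$rsid))
    stop("duplicate rsid in panel: ",
         paste(unique(panel$rsid[duplicated(panel$rsid)]), collapse = ", "))
  if (any(panel$effect_allele == panel$other_allele))
    stop("effect allele equals other allele for: ",
         paste(panel$rsid[panel$effect_allele == panel$other_allele],
               collapse = ", "))
  bad <- !is.na(panel$maf) & (panel$maf < 0 | panel$maf > 1)
  if (any(bad))
    stop("maf outside [0, 1] for: ", paste(panel$rsid[bad], collapse = ", "))
  invisible(panel)
}

#' Normalize chromosome labels
#'
#' Strips any `"chr"` prefix and upper-cases sex chromosomes, so `"chrX"`
#' and `"X"` compare equal. Accepted labels are `1`--`22`, `X`, `Y`, `MT`.
#'
#' @param chrom Character or numeric vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  x <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  x[x == "M"] <- "MT"
  ok <- x %in% c(as.character(1:22), "X", "Y", "MT")
  if (!all(ok))
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  x
}

#' Construct a genotype table
#'
#' The central genotype container: an individuals-by-variants matrix of
#' effect-allele dosages in `{0, 1, 2}` with `NA` marking missing calls,
#' paired with the [variant_panel()] describing its columns.
#'
#' @param individual_ids Unique individual identifiers (rows).
#' @param panel A [variant_panel()] describing the columns.
#' @param dosages Integer matrix, `length(individual_ids)` rows by
#'   `nrow(panel)` columns, values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_table` with elements
#'   `individual_ids`, `panel`, `dosages`.
#' @export
genotype_table <- function(individual_ids, panel, dosages) {
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(individual_ids) || ncol(dosages) != nrow(panel))
    stop("dosage matrix is ", nrow(dosages), " x ", ncol(dosages),
         " but there are ", length(individual_ids), " individuals and ",
         nrow(panel), " variants")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(individual_ids, panel$rsid)
  structure(
    list(individual_ids = individual_ids, panel = panel, dosages = dosages),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$individual_ids), " individuals x ",
      nrow(x$panel), " variants\n", sep = "")
  miss <- sum(is.na(x$dosages))
  if (miss) cat("  missing dosages: ", miss, "\n", sep = "")
  cat("  variants: ",
      paste(utils::head(x$panel$rsid, 5), collapse = ", "),
      if (nrow(x$panel) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Subset a genotype table to a set of variants
#'
#' @param genotypes A [genotype_table()].
#' @param rsids Variant identifiers to keep, in the order given.
#' @return A `genotype_table` restricted to `rsids`.
#' @export
subset_variants <- function(genotypes, rsids) {
  missing <- setdiff(rsids, genotypes$panel$rsid)
  if (length(missing))
    stop("variant(s) absent from genotypes: ", paste(missing, collapse = ", "))
  idx <- match(rsids, genotypes$panel$rsid)
  panel <- genotypes$panel[idx, , drop = FALSE]
  rownames(panel) <- NULL
  genotype_table(genotypes$individual_ids, panel,
                 genotypes$dosages[, idx, drop = FALSE])
}
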