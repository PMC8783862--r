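## Readers and writers for the formats the pipeline touches. VCF parsing
## goes through vcfR; writing uses a minimal text emitter so that a
## simulate -> write -> read round trip reproduces the dosage matrix
## byte-exactly. TSV dialect: tab-separated, UTF-8, header required,
## "." or empty for missing.

#' Read genotypes from a VCF file as effect-allele dosages
#'
#' For each requested variant, dosage is the number of haplotypes carrying
#' the named effect allele. The effect allele may be REF or ALT and may be
#' multi-base (an indel allele such as a `TG` insertion). In multi-allelic
#' records only the named allele counts; every other allele, REF or ALT,
#' contributes zero. Genotypes `./.` become missing.
#'
#' @param path Path to a VCF 4.x file with diploid GT fields.
#' @param effect_alleles Named character vector, rsid -> effect allele
#'   string. Only these variants are loaded.
#' @return A [genotype_table()]. Variants requested but absent from the
#'   file are reported in a warning and omitted.
#' @export
read_vcf <- function(path, effect_alleles) {
  if (is.null(names(effect_alleles)) || any(names(effect_alleles) == ""))
    stop("effect_alleles must be a named vector (rsid -> allele)")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  found <- intersect(names(effect_alleles), fix$ID)
  absent <- setdiff(names(effect_alleles), fix$ID)
  if (length(absent))
    warning("variant(s) not found in VCF: ", paste(absent, collapse = ", "))
  if (!length(found)) stop("none of the requested variants are in the VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  idx <- match(found, fix$ID)

  dos <- matrix(NA_integer_, nrow = length(samples), ncol = length(found))
  other <- character(length(found))
  for (k in seq_along(found)) {
    i <- idx[k]
    alleles <- toupper(c(fix$REF[i], strsplit(fix$ALT[i], ",")[[1]]))
    ea <- toupper(effect_alleles[[found[k]]])
    if (!ea %in% alleles)
      warning("effect allele '", ea, "' not among alleles of ", found[k],
              " (", paste(alleles, collapse = "/"), "); dosages are 0")
    other[k] <- if (length(setdiff(alleles, ea)))
      setdiff(alleles, ea)[1] else paste0(ea, "_other")
    dos[, k] <- count_effect_haplotypes(gt[i, ], alleles, ea, found[k])
  }
  panel <- variant_panel(found, fix$CHROM[idx], as.integer(fix$POS[idx]),
                         unname(effect_alleles[found]), other)
  genotype_table(samples, panel, dos)
}

# GT strings like "0/1", "1|1", "./." -> effect-allele count
count_effect_haplotypes <- function(gt_row, alleles, effect_allele, rsid) {
  vapply(gt_row, function(g) {
    if (is.na(g)) return(NA_integer_)
    codes <- strsplit(g, "[/|]")[[1]]
    if (length(codes) != 2)
      stop("non-diploid genotype '", g, "' at ", rsid)
    if (any(codes == ".")) return(NA_integer_)
    codes <- as.integer(codes)
    if (any(codes + 1L > length(alleles)))
      stop("allele index out of range in genotype '", g, "' at ", rsid)
    sum(alleles[codes + 1L] == effect_allele)
  }, integer(1))
}

#' Write a genotype table as a VCF file
#'
#' Emits a minimal VCF 4.2 with one diploid GT field per sample. The
#' non-effect allele is written as REF and the effect allele as ALT, so
#' dosage d maps to genotypes `0/0`, `0/1`, `1/1` and missing to `./.`.
#'
#' @param genotypes A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  p <- genotypes$panel
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polyscreen",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$individual_ids), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(p)), function(j) {
    d <- genotypes$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(p$chrom[j], p$pos[j], p$rsid[j], p$other_allele[j],
            p$effect_allele[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Flip the effect/other allele orientation of selected variants
#'
#' Reorienting a variant maps every dosage d to 2 - d and swaps its allele
#' labels; missing stays missing.
#'
#' @param genotypes A [genotype_table()].
#' @param rsids Variants to flip (default: all).
#' @return A reoriented [genotype_table()].
#' @export
flip_effect_alleles <- function(genotypes, rsids = genotypes$panel$rsid) {
  j <- match(rsids, genotypes$panel$rsid)
  if (anyNA(j))
    stop("variant(s) absent from genotypes: ",
         paste(rsids[is.na(j)], collapse = ", "))
  panel <- genotypes$panel
  ea <- panel$effect_allele[j]
  panel$effect_allele[j] <- panel$other_allele[j]
  panel$other_allele[j] <- ea
  if (!is.null(panel$maf)) panel$maf[j] <- 1 - panel$maf[j]
  dos <- genotypes$dosages
  dos[, j] <- 2L - dos[, j]
  genotype_table(genotypes$individual_ids, panel, dos)
}

#' Write / read a dosage table as TSV
#'
#' The table has one row per individual: an `id` column followed by one
#' column per variant (named by rsid) holding dosages 0/1/2, with `.` for
#' missing.
#'
#' @param genotypes A [genotype_table()].
#' @param path TSV path.
#' @return `write_dosage_tsv`: `path` invisibly. `read_dosage_tsv`: a
#'   [genotype_table()].
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- as.data.frame(genotypes$dosages)
  df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
  df <- cbind(id = genotypes$individual_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param panel Optional [variant_panel()] giving alleles and positions for
#'   the dosage columns; without it a placeholder panel (alleles `A`/`B`,
#'   chromosome 1) is constructed.
#' @export
read_dosage_tsv <- function(path, panel = NULL) {
  df <- utils::read.delim(path, sep = "\t", na.strings = c(".", "NA", ""),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("dosage TSV needs an 'id' column")
  rsids <- setdiff(names(df), "id")
  if (is.null(panel)) {
    panel <- variant_panel(rsids, rep("1", length(rsids)),
                           seq_along(rsids), rep("A", length(rsids)),
                           rep("B", length(rsids)))
  } else {
    missing <- setdiff(rsids, panel$rsid)
    if (length(missing))
      stop("panel lacks variant(s): ", paste(missing, collapse = ", "))
    panel <- panel[match(rsids, panel$rsid), , drop = FALSE]
    rownames(panel) <- NULL
  }
  dos <- as.matrix(df[, rsids, drop = FALSE])
  genotype_table(df$id, panel, dos)
}

#' Write a variant panel as TSV
#'
#' @param panel A [variant_panel()].
#' @param path TSV path.
#' @return `path`, invisibly (`read_panel_tsv` returns the panel).
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c(".", "NA", ""))
  need <- c("rsid", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel TSV missing column(s): ", paste(miss, collapse = ", "))
  panel <- variant_panel(df$rsid, df$chrom, df$pos, df$effect_allele,
                         df$other_allele,
                         if ("maf" %in% names(df)) df$maf else NA_real_)
  extra <- setdiff(names(df), names(panel))
  for (nm in extra) panel[[nm]] <- df[[nm]]
  panel
}

#' Read GWAS summary statistics from TSV
#'
#' Required columns: `rsid`, `trait`, `effect_allele`, `beta`, `p`
#' (renameable through `columns`). Optional `sex` and `se` columns are kept
#' when present. Rows whose beta or p fail to parse, or whose p lies
#' outside (0, 1], are rejected with a warning naming their line numbers.
#'
#' @param path TSV path (scientific notation such as `8.1e-11` is parsed
#'   by the usual numeric conversion).
#' @param columns Named character vector mapping the canonical names to the
#'   file's column names.
#' @return A `data.frame` of summary-statistic records.
#' @export
read_summary_stats <- function(path,
                               columns = c(rsid = "rsid", trait = "trait",
                                           effect_allele = "effect_allele",
                                           beta = "beta", p = "p")) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c(".", "NA", ""))
  miss <- setdiff(unname(columns), names(df))
  if (length(miss))
    stop("summary-statistics file missing column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(rsid = as.character(df[[columns[["rsid"]]]]),
                    trait = as.character(df[[columns[["trait"]]]]),
                    effect_allele = toupper(df[[columns[["effect_allele"]]]]),
                    beta = suppressWarnings(as.numeric(df[[columns[["beta"]]]])),
                    p = suppressWarnings(as.numeric(df[[columns[["p"]]]])),
                    stringsAsFactors = FALSE)
  for (opt in c("sex", "se", "chrom"))
    if (opt %in% names(df)) out[[opt]] <- df[[opt]]
  bad <- is.na(out$beta) | is.na(out$p) | out$p <= 0 | out$p > 1 |
    is.na(out$effect_allele) | out$effect_allele == ""
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (unparseable beta/p or p outside ",
            "(0, 1]) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a phenotype/covariate table from TSV
#'
#' @param path TSV path with a header and an id column.
#' @param id_col Name of the id column.
#' @param categories Named list of allowed labels for categorical columns,
#'   e.g. `list(sex = c("female", "male"))`; an out-of-vocabulary label is
#'   an error listing the allowed ones.
#' @return A `data.frame`; missing values (`.` or empty) are kept as `NA`
#'   and excluded listwise by downstream analyses.
#' @export
read_phenotypes <- function(path, id_col = "id", categories = list()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c(".", "NA", ""))
  if (!id_col %in% names(df))
    stop("phenotype file missing id column '", id_col, "'")
  if (anyDuplicated(df[[id_col]]))
    stop("duplicate ids in phenotype file: ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]),
               collapse = ", "))
  for (nm in names(categories)) {
    if (!nm %in% names(df)) next
    allowed <- categories[[nm]]
    bad <- !is.na(df[[nm]]) & !df[[nm]] %in% allowed
    if (any(bad))
      stop("unknown label(s) in '", nm, "': ",
           paste(unique(df[[nm]][bad]), collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
    df[[nm]] <- factor(df[[nm]], levels = allowed)
  }
  df
}

#' Write result tables as TSV files
#'
#' Each element of `tables` is written to `<out_dir>/<name>.tsv` with a
#' stable column order and no quoting, so identical inputs yield identical
#' bytes. An empty table produces a header-only file.
#'
#' @param tables Named list of `data.frame`s.
#' @param out_dir Output directory (created if needed).
#' @param verbose Log a row count per file.
#' @return Character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, verbose = TRUE) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (verbose)
      message("wrote ", nrow(tables[[nm]]), " row(s) to ", path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
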