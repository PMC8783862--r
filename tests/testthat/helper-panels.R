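# small biallelic SNP panel for unit tests
tiny_panel <- function(m = 3, maf = rep(0.3, m)) {
  variant_panel(sprintf("rsT%03d", seq_len(m)),
                chrom = rep("1", m), pos = seq_len(m) * 100L,
                effect_allele = rep("A", m), other_allele = rep("G", m),
                maf = maf)
}

# genotype table with every individual at a fixed dosage vector
fixed_genotypes <- function(dosage_rows, panel = study_panel()) {
  dos <- do.call(rbind, dosage_rows)
  genotype_table(sprintf("ind%02d", seq_len(nrow(dos))), panel, dos)
}
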