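# Small in-code fixtures shared across test files.

two_locus_annotations <- function() {
    # rs480902: effect allele = protective T; rs1063856: effect allele C is
    # the risk allele, protective is T (exercises the effect != protective
    # recoding path in scoreSamples)
    data.frame(
        locus_id = c("rs480902", "rs1063856"),
        allele_a = c("C", "C"), allele_b = c("T", "T"),
        effect_allele = c("T", "C"),
        protective_flag = c(TRUE, FALSE),
        gene_label = c("EGLN1", "VWF"),
        stringsAsFactors = FALSE)
}

make_ge <- function(dosage, loci = NULL, groups = NULL) {
    if (is.null(loci))
        loci <- data.frame(
            locus_id = rownames(dosage),
            allele_a = "C", allele_b = "T", effect_allele = "T",
            gene_label = NA_character_, stringsAsFactors = FALSE)
    samples <- NULL
    if (!is.null(groups))
        samples <- data.frame(sample_id = colnames(dosage),
                              group_label = groups,
                              stringsAsFactors = FALSE)
    GenotypeExperiment(dosage, loci, samples)
}

write_genotype_fixture <- function(path, header, rows) {
    writeLines(c(paste(header, collapse = "\t"),
                 vapply(rows, paste, character(1), collapse = "\t")),
               path)
    path
}

# minimal VCF v4.2 with GT-only FORMAT
write_vcf_fixture <- function(path, records, samples) {
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, vapply(records, paste, character(1),
                             collapse = "\t")), path)
    path
}
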