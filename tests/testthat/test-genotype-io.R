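test_that("TSV genotype strings are recoded to effect-allele dosages", {
    loci <- two_locus_annotations()
    f <- write_genotype_fixture(
        withr::local_tempfile(fileext = ".tsv"),
        c("sample_id", "rs480902", "rs1063856"),
        list(c("s1", "CC", "CC"),    # eff T -> 0 ; eff C -> 2
             c("s2", "CT", "TC"),    # unordered heterozygotes -> 1 each
             c("s3", "TT", "NN"),
             c("s4", "TC", "TT")))
    ge <- readGenotypeTSV(f, loci)
    d <- dosage(ge)
    expect_identical(d["rs480902", ], c(s1 = 0L, s2 = 1L, s3 = 2L, s4 = 1L))
    expect_identical(d["rs1063856", ], c(s1 = 2L, s2 = 1L, s3 = NA, s4 = 0L))
})

test_that("TSV reader rejects bad cells and duplicate samples by name", {
    loci <- two_locus_annotations()[1, ]
    f <- write_genotype_fixture(
        withr::local_tempfile(fileext = ".tsv"),
        c("sample_id", "rs480902"),
        list(c("s1", "CT"), c("s2", "CX")))
    expect_error(readGenotypeTSV(f, loci), "CX.*s2.*rs480902")
    f2 <- write_genotype_fixture(
        withr::local_tempfile(fileext = ".tsv"),
        c("sample_id", "rs480902"),
        list(c("s1", "CT"), c("s1", "TT")))
    expect_error(readGenotypeTSV(f2, loci), "duplicate sample")
    f3 <- write_genotype_fixture(
        withr::local_tempfile(fileext = ".tsv"),
        c("sample_id", "rsOTHER"), list(c("s1", "CT")))
    expect_error(readGenotypeTSV(f3, loci), "absent")
})

test_that("TSV round-trip preserves dosages including missing calls", {
    set.seed(42)
    loci <- two_locus_annotations()
    ge <- simCohort(c(A = 25, B = 15),
                    matrix(c(0.3, 0.7, 0.6, 0.2), 2,
                           dimnames = list(loci$locus_id, c("A", "B"))),
                    loci, missingRate = 0.1, seed = 9)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypeTSV(ge, f)
    back <- readGenotypeTSV(f, loci)
    expect_identical(dosage(back), dosage(ge))
})

test_that("VCF and TSV readers agree on equivalent fixtures", {
    loci <- two_locus_annotations()
    vf <- write_vcf_fixture(
        withr::local_tempfile(fileext = ".vcf"),
        list(c("1", "100", "rs480902", "C", "T", ".", "PASS", ".", "GT",
               "0/1", "1|1", "./.", "0/0"),
             c("12", "200", "rs1063856", "C", "T", ".", "PASS", ".", "GT",
               "1/1", "0/1", "./1", "0|0")),
        c("s1", "s2", "s3", "s4"))
    gv <- readGenotypeVCF(vf, loci)
    tf <- write_genotype_fixture(
        withr::local_tempfile(fileext = ".tsv"),
        c("sample_id", "rs480902", "rs1063856"),
        list(c("s1", "CT", "TT"), c("s2", "TT", "CT"),
             c("s3", "NN", "NN"), c("s4", "CC", "CC")))
    gt <- readGenotypeTSV(tf, loci)
    expect_identical(dosage(gv), dosage(gt))
    # GT indices count through REF/ALT: "1/1" with ALT=T, effect C -> 0
    expect_identical(dosage(gv)["rs1063856", "s1"], 0L)
    # half-missing GT is a missing call
    expect_true(is.na(dosage(gv)["rs1063856", "s3"]))
})

test_that("VCF reader warns on absent locus and errors on REF/ALT mismatch", {
    loci <- two_locus_annotations()
    vf <- write_vcf_fixture(
        withr::local_tempfile(fileext = ".vcf"),
        list(c("1", "100", "rs480902", "C", "T", ".", "PASS", ".", "GT",
               "0/1", "1/1")),
        c("s1", "s2"))
    expect_warning(ge <- readGenotypeVCF(vf, loci), "rs1063856")
    expect_true(all(is.na(dosage(ge)["rs1063856", ])))
    expect_identical(dosage(ge)["rs480902", ], c(s1 = 1L, s2 = 2L))
    vb <- write_vcf_fixture(
        withr::local_tempfile(fileext = ".vcf"),
        list(c("1", "100", "rs480902", "A", "G", ".", "PASS", ".", "GT",
               "0/1", "1/1")),
        c("s1", "s2"))
    expect_error(readGenotypeVCF(vb, loci[1, ]), "inconsistent")
})

test_that("alleleCounts excludes missing calls and sums to 2n", {
    ge <- make_ge(matrix(c(2L, 2L, 1L, 0L), nrow = 1,
                         dimnames = list("rs1", paste0("s", 1:4))))
    expect_identical(alleleCounts(ge, "rs1"), c(effect = 5L, other = 3L))
    gm <- make_ge(matrix(NA_integer_, 1, 3,
                         dimnames = list("rs1", paste0("s", 1:3))))
    expect_identical(alleleCounts(gm, "rs1"), c(effect = 0L, other = 0L))
    expect_error(alleleCounts(ge, "rsX"), "not in matrix")
    expect_error(alleleCounts(ge, "rs1", character(0)), "empty")
    # a 29-sample group with 3 effect alleles realises the rounded
    # frequency 0.05 at 3/58 (the only count c with round(c/58, 2) == 0.05)
    expect_identical(which(round(0:58 / 58, 2) == 0.05) - 1L, 3L)
    d29 <- matrix(c(1L, 1L, 1L, rep(0L, 26)), nrow = 1,
                  dimnames = list("rs1", paste0("s", 1:29)))
    expect_identical(alleleCounts(make_ge(d29), "rs1"),
                     c(effect = 3L, other = 55L))
})

test_that("GenotypeExperiment validity catches malformed input", {
    loci <- two_locus_annotations()
    d <- matrix(0L, 2, 2, dimnames = list(loci$locus_id, c("a", "b")))
    expect_s4_class(GenotypeExperiment(d, loci), "GenotypeExperiment")
    d_bad <- d; d_bad[1, 1] <- 5L
    expect_error(GenotypeExperiment(d_bad, loci), "0, 1 or 2")
    loci_bad <- loci; loci_bad$effect_allele[1] <- "G"
    expect_error(GenotypeExperiment(d, loci_bad), "effect_allele")
    expect_error(GenotypeExperiment(d, loci[c(1, 1), ]), "duplicate")
})
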