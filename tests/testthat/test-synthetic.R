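test_that("degenerate frequencies give monomorphic cohorts", {
    loci <- data.frame(locus_id = c("rsA", "rsB"), allele_a = "C",
                       allele_b = "T", effect_allele = "T",
                       gene_label = NA_character_)
    freq <- matrix(c(0, 1), 2, 1, dimnames = list(loci$locus_id, "G"))
    ge <- simCohort(c(G = 30), freq, loci, seed = 1)
    expect_true(all(dosage(ge)["rsA", ] == 0L))
    expect_true(all(dosage(ge)["rsB", ] == 2L))
})

test_that("identical seeds give byte-identical genotype files, different
           seeds differ", {
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    f3 <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypeTSV(simStudyCohort(seed = 99, nullLoci = 50), f1)
    writeGenotypeTSV(simStudyCohort(seed = 99, nullLoci = 50), f2)
    writeGenotypeTSV(simStudyCohort(seed = 100, nullLoci = 50), f3)
    expect_identical(readLines(f1), readLines(f2))
    expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("empirical frequencies converge to the generating values under
           HWE proportions", {
    loci <- data.frame(locus_id = "rs1", allele_a = "C", allele_b = "T",
                       effect_allele = "T", gene_label = NA_character_)
    p <- 0.37
    n <- 5000
    ge <- simCohort(c(G = n), matrix(p, 1, 1, dimnames = list("rs1", "G")),
                    loci, seed = 12)
    ac <- alleleCounts(ge, "rs1")
    fhat <- ac["effect"] / sum(ac)
    expect_lt(abs(fhat - p), 4 * sqrt(p * (1 - p) / (2 * n)))
    # genotype-class proportions pass a HWE goodness-of-fit check
    obs <- table(factor(dosage(ge)["rs1", ], levels = 0:2))
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    gof <- suppressWarnings(chisq.test(obs, p = expected))
    expect_gt(gof$p.value, 0.01)
})

test_that("missing calls appear at the configured rate and are excluded
           from counts", {
    loci <- data.frame(locus_id = "rs1", allele_a = "C", allele_b = "T",
                       effect_allele = "T", gene_label = NA_character_)
    ge <- simCohort(c(G = 3000), matrix(0.5, 1, 1,
                                        dimnames = list("rs1", "G")),
                    loci, missingRate = 0.2, seed = 13)
    rate <- mean(is.na(dosage(ge)))
    expect_lt(abs(rate - 0.2), 4 * sqrt(0.2 * 0.8 / 3000))
    ac <- alleleCounts(ge, "rs1")
    expect_identical(sum(ac), as.integer(2 * sum(!is.na(dosage(ge)))))
})

test_that("the default study cohort has the documented shape and planted
           truth", {
    ge <- simStudyCohort(seed = 1)
    expect_identical(dim(ge), c(2800L, 188L))
    tab <- table(sampleInfo(ge)$group_label)
    expect_identical(as.integer(tab[c("V", "P", "K", "IE")]),
                     c(39L, 29L, 28L, 92L))
    md <- S4Vectors::metadata(ge)
    expect_identical(nrow(md$planted), 9L)
    expect_setequal(unique(md$planted$comparison),
                    c("PvsK", "KvsV", "VvsP"))
    # the generating frequency table carries the published subgroup
    # contrasts, e.g. the VWF risk-allele frequencies 0.05 (P) vs 0.37 (K)
    expect_equal(md$frequencies["rs1063856", "P"], 0.05)
    expect_equal(md$frequencies["rs1063856", "K"], 0.37)
    expect_equal(md$frequencies["rs857721", c("P", "K")],
                 c(P = 0.43, K = 0.05))
    # empirical subgroup frequencies match the generating values at
    # scaled-up sizes
    tabl <- studyLociTable()
    freq <- S4Vectors::metadata(ge)$frequencies[tabl$locus_id, , drop = FALSE]
    big <- simCohort(c(V = 5000, P = 5000, K = 5000, IE = 5000), freq,
                     tabl[, c("locus_id", "allele_a", "allele_b",
                              "effect_allele", "gene_label")],
                     seed = 77)
    st <- sampleInfo(big)
    for (g in c("V", "P", "K")) {
        ids <- st$sample_id[st$group_label == g]
        for (l in c("rs1063856", "rs857721", "rs480902")) {
            ac <- alleleCounts(big, l, ids)
            p <- freq[l, g]
            expect_lt(abs(ac["effect"] / sum(ac) - p),
                      4 * sqrt(p * (1 - p) / 10000))
        }
    }
})

test_that("panel populations follow their altitude cline and tolerate
           size 1", {
    loci <- two_locus_annotations()
    cl <- logisticCline(loci$locus_id, f0 = c(0.1, 0.9),
                        f1 = c(0.9, 0.1))
    # protective frequency 0.1 at sea level vs 0.9 at 4,000 m:
    # mean scores come out ordered in every replicate
    pops <- data.frame(population_id = c("low", "high"), size = 100,
                       altitude_m = c(0, 4000))
    ordered <- vapply(1:20, function(r) {
        ge <- simPanel(pops, loci, cl, seed = 500 + r)
        ss <- summarizePopulations(scoreSamples(ge), sampleInfo(ge))
        ss$mean_score[ss$population_id == "high"] >
            ss$mean_score[ss$population_id == "low"]
    }, logical(1))
    expect_true(all(ordered))
    one <- simPanel(data.frame(population_id = "solo", size = 1,
                               altitude_m = 2500), loci, cl, seed = 2)
    ss <- summarizePopulations(scoreSamples(one), sampleInfo(one))
    expect_identical(ss$n_scored, 1L)
    expect_true(ss$mean_score >= 0 && ss$mean_score <= 4)
    expect_error(simPanel(pops, loci, cl[1, ], seed = 1), "missing")
})
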