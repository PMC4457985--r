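#' Simulate a genotype cohort under Hardy-Weinberg equilibrium
#'
#' Draws, for every sample and locus, an effect-allele dosage from
#' Binomial(2, group frequency) — Hardy-Weinberg genotype proportions —
#' with loci independent (no linkage disequilibrium; the screen tests loci
#' marginally and the combined score is additive over loci). Calls are
#' masked missing independently at `missingRate`. Fully reproducible from
#' `seed`; groups use spawn-keyed sub-seeds so a group's draws do not
#' depend on the other groups' sizes.
#'
#' @param sizes named integer vector of group sizes, e.g.
#'   `c(V = 39, P = 29, K = 28)`
#' @param freq numeric matrix of effect-allele frequencies, loci x groups;
#'   rownames are locus ids, colnames the group labels
#' @param loci locus annotation `data.frame` (see [GenotypeExperiment()])
#' @param genotypeFreq optional list (one element per group, in `sizes`
#'   order) of loci x 3 matrices of genotype-class probabilities for
#'   dosages 0/1/2, overriding Hardy-Weinberg sampling
#' @param missingRate per-call missing probability in \[0, 1)
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @return a [GenotypeExperiment-class] with `group_label` sample metadata
#' @examples
#' loci <- data.frame(locus_id = "rs1", allele_a = "C", allele_b = "T",
#'                    effect_allele = "T", gene_label = "G")
#' f <- matrix(c(0.1, 0.9), 1, dimnames = list("rs1", c("A", "B")))
#' simCohort(c(A = 50, B = 50), f, loci, seed = 1)
#' @export
simCohort <- function(sizes, freq, loci, genotypeFreq = NULL,
                      missingRate = 0, seed = NULL) {
    stopifnot(is.matrix(freq), all(sizes >= 1L),
              missingRate >= 0, missingRate < 1,
              all(freq >= 0 & freq <= 1),
              !is.null(names(sizes)),
              all(names(sizes) %in% colnames(freq)))
    freq <- freq[loci$locus_id, , drop = FALSE]
    m <- nrow(loci)
    blocks <- vector("list", length(sizes))
    for (g in seq_along(sizes)) {
        .spawnSeed(seed, g)
        n <- sizes[g]
        d <- if (is.null(genotypeFreq)) {
            matrix(stats::rbinom(m * n, 2L, rep(freq[, names(sizes)[g]],
                                                times = n)),
                   nrow = m, ncol = n)
        } else {
            gf <- genotypeFreq[[g]]
            stopifnot(nrow(gf) == m, ncol(gf) == 3L)
            matrix(vapply(rep(seq_len(m), times = n), function(i)
                sample(0:2, 1L, prob = gf[i, ]), integer(1L)),
                nrow = m, ncol = n)
        }
        if (missingRate > 0)
            d[stats::runif(length(d)) < missingRate] <- NA_integer_
        colnames(d) <- sprintf("%s_%03d", names(sizes)[g], seq_len(n))
        blocks[[g]] <- d
    }
    d <- do.call(cbind, blocks)
    rownames(d) <- loci$locus_id
    samples <- data.frame(
        sample_id = colnames(d),
        group_label = rep(names(sizes), times = sizes),
        stringsAsFactors = FALSE)
    GenotypeExperiment(d, loci, samples)
}

# deterministic per-group/per-population sub-seed below 2^31
.spawnSeed <- function(seed, i) {
    if (!is.null(seed))
        set.seed(as.integer((as.numeric(seed) * 1000003 + i * 7919) %%
                            2147483629))
    invisible(NULL)
}

#' Logistic-in-altitude cline parameters
#'
#' Returns per-locus logistic cline parameters such that the effect-allele
#' frequency is `f0` at altitude `alt0` and `f1` at `alt1`:
#' freq(alt) = plogis(intercept + slope * alt). The logistic form keeps
#' frequencies inside \[0, 1\] over any altitude range. `f1 = f0` gives a
#' constant (null) cline.
#'
#' @param locus_id character vector of locus ids
#' @param f0,f1 frequencies (strictly inside (0, 1)) at `alt0` and `alt1`
#' @param alt0,alt1 anchor altitudes in metres
#' @return `data.frame` with columns `locus_id`, `intercept`, `slope`
#' @export
logisticCline <- function(locus_id, f0, f1, alt0 = 0, alt1 = 4000) {
    stopifnot(all(f0 > 0 & f0 < 1), all(f1 > 0 & f1 < 1), alt1 != alt0)
    a0 <- stats::qlogis(f0)
    a1 <- stats::qlogis(f1)
    slope <- (a1 - a0) / (alt1 - alt0)
    data.frame(locus_id = locus_id, intercept = a0 - slope * alt0,
               slope = slope, stringsAsFactors = FALSE)
}

#' Simulate a population panel along an altitude cline
#'
#' Each population's per-locus effect-allele frequency comes from a
#' logistic function of its altitude (see [logisticCline()]); genotypes
#' are then drawn under Hardy-Weinberg as in [simCohort()]. Emulates a
#' worldwide reference panel in which high-altitude populations carry the
#' protective allele combination at elevated frequency.
#'
#' @param populations `data.frame` with columns `population_id`, `size`,
#'   `altitude_m`
#' @param loci locus annotation `data.frame`
#' @param cline `data.frame` with columns `locus_id`, `intercept`, `slope`
#'   (logit scale per metre), one row per locus
#' @param missingRate per-call missing probability
#' @param seed integer seed or `NULL`
#' @return a [GenotypeExperiment-class]; sample metadata carries
#'   `population_id` and `altitude_m` (and `group_label` = population id)
#' @examples
#' loci <- data.frame(locus_id = c("rs480902", "rs1063856"),
#'                    allele_a = "C", allele_b = "T", effect_allele = "T",
#'                    gene_label = c("EGLN1", "VWF"))
#' pops <- data.frame(population_id = paste0("pop", 1:5), size = 20,
#'                    altitude_m = c(0, 500, 1500, 3000, 4200))
#' cl <- logisticCline(loci$locus_id, f0 = 0.2, f1 = 0.8)
#' simPanel(pops, loci, cl, seed = 7)
#' @export
simPanel <- function(populations, loci, cline, missingRate = 0,
                     seed = NULL) {
    stopifnot(all(c("population_id", "size", "altitude_m") %in%
                  colnames(populations)),
              all(c("locus_id", "intercept", "slope") %in% colnames(cline)),
              all(populations$altitude_m >= 0))
    idx <- match(loci$locus_id, cline$locus_id)
    if (anyNA(idx))
        stop("cline parameters missing for locus: ",
             paste(loci$locus_id[is.na(idx)], collapse = ", "))
    cline <- cline[idx, ]
    freq <- vapply(populations$altitude_m, function(alt)
        stats::plogis(cline$intercept + cline$slope * alt),
        numeric(nrow(loci)))
    if (nrow(loci) == 1L) freq <- matrix(freq, nrow = 1L)
    dimnames(freq) <- list(loci$locus_id, populations$population_id)
    sizes <- stats::setNames(as.integer(populations$size),
                             populations$population_id)
    ge <- simCohort(sizes, freq, loci, missingRate = missingRate,
                    seed = seed)
    st <- sampleInfo(ge)
    st$population_id <- st$group_label
    st$altitude_m <- populations$altitude_m[
        match(st$population_id, populations$population_id)]
    SummarizedExperiment::colData(ge)$population_id <- st$population_id
    SummarizedExperiment::colData(ge)$altitude_m <- st$altitude_m
    ge
}

#' Annotation and generating frequencies of the named cohort loci
#'
#' The nine named SNPs built into [simStudyCohort()]: the eight SNPs in
#' seven genes whose subgroup allele-frequency contrasts the screen is
#' calibrated to recover (with their published per-group effect-allele
#' frequencies; the group not involved in a SNP's printed comparison
#' defaults to the midpoint of the two printed values), plus the EGLN1
#' locus rs480902 of the two-locus protective score. The rs480902
#' per-group frequencies are synthetic defaults (its cohort frequencies
#' were published separately), chosen to contrast P (high protective-T)
#' against K. The IE background-pool frequency of every locus is the
#' size-weighted mean of the three subgroup frequencies, so that pooling
#' the subgroups matches the background.
#'
#' @return `data.frame` with locus annotations, per-group generating
#'   frequencies (`f_V`, `f_P`, `f_K`, `f_IE` — frequencies of the effect
#'   allele) and, for the nine planted subgroup contrasts, the comparison
#'   each belongs to (`planted_comparison`, comma-separated, `NA` for
#'   rs480902).
#' @export
studyLociTable <- function() {
    df <- data.frame(
        locus_id = c("rs1171271", "rs857703", "rs660339", "rs3741860",
                     "rs857691", "rs857721", "rs1063856", "rs857685",
                     "rs480902"),
        gene_label = c("LEPR", "OR6K3", "UCP2", "OLR1", "SPTA1", "SPTA1",
                       "VWF", "OR10Z1", "EGLN1"),
        allele_a = c("C", "A", "A", "A", "C", "A", "C", "A", "C"),
        allele_b = c("T", "G", "G", "G", "T", "T", "T", "C", "T"),
        effect_allele = c("C", "A", "A", "G", "T", "A", "C", "C", "T"),
        protective_flag = c(NA, NA, NA, NA, NA, NA, FALSE, NA, TRUE),
        f_V = c(0.295, 0.43, 0.49, 0.49, 0.23, 0.24, 0.21, 0.23, 0.55),
        f_P = c(0.46, 0.27, 0.32, 0.14, 0.40, 0.43, 0.05, 0.41, 0.82),
        f_K = c(0.13, 0.11, 0.15, 0.53, 0.06, 0.05, 0.37, 0.05, 0.30),
        planted_comparison = c("PvsK", "KvsV", "KvsV", "VvsP,PvsK",
                               "PvsK", "PvsK", "PvsK", "PvsK", NA),
        stringsAsFactors = FALSE)
    df$f_IE <- (39 * df$f_V + 29 * df$f_P + 28 * df$f_K) / 96
    df
}

#' Simulate the default study cohort
#'
#' A deterministic (seeded) synthetic cohort with the structure the
#' analysis assumes: three phenotype subgroups V/P/K of sizes 39/29/28
#' plus a 92-sample heterogeneous IE background pool, genotyped at 2,800
#' loci — the nine named loci of [studyLociTable()] at their per-group
#' generating frequencies, and `nullLoci` null SNPs whose shared frequency
#' is drawn uniformly on (0.05, 0.95) and identical across groups.
#' Genotypes follow Hardy-Weinberg proportions within group; loci are
#' independent.
#'
#' The generating truth is recorded in the object metadata:
#' `metadata(.)$planted` lists the nine planted (locus, comparison) pairs
#' with their generating frequencies, and `metadata(.)$frequencies` the
#' full loci x groups frequency matrix.
#'
#' @param seed integer seed (default 17)
#' @param nullLoci number of null SNPs (default 2791, for 2,800 loci
#'   total)
#' @param missingRate per-call missing probability (default 0)
#' @return a [GenotypeExperiment-class] of 188 samples
#' @examples
#' ge <- simStudyCohort(seed = 1, nullLoci = 10)
#' ge
#' @export
simStudyCohort <- function(seed = 17, nullLoci = 2791, missingRate = 0) {
    tab <- studyLociTable()
    .spawnSeed(seed, 0L)
    nullFreq <- stats::runif(nullLoci, 0.05, 0.95)
    nulls <- data.frame(
        locus_id = sprintf("null%04d", seq_len(nullLoci)),
        gene_label = NA_character_, allele_a = "A", allele_b = "G",
        effect_allele = "A", protective_flag = NA,
        stringsAsFactors = FALSE)
    annCols <- c("locus_id", "gene_label", "allele_a", "allele_b",
                 "effect_allele", "protective_flag")
    loci <- rbind(tab[, annCols], nulls)
    freq <- rbind(as.matrix(tab[, c("f_V", "f_P", "f_K", "f_IE")]),
                  matrix(nullFreq, ncol = 4L, nrow = nullLoci,
                         dimnames = list(NULL, c("f_V", "f_P", "f_K",
                                                 "f_IE"))))
    colnames(freq) <- c("V", "P", "K", "IE")
    rownames(freq) <- loci$locus_id
    ge <- simCohort(c(V = 39L, P = 29L, K = 28L, IE = 92L), freq, loci,
                    missingRate = missingRate, seed = seed)
    planted <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        cmp <- tab$planted_comparison[i]
        if (is.na(cmp)) return(NULL)
        data.frame(locus_id = tab$locus_id[i],
                   comparison = strsplit(cmp, ",")[[1L]],
                   stringsAsFactors = FALSE)
    }))
    S4Vectors::metadata(ge) <- list(planted = planted, frequencies = freq,
                                    seed = seed)
    ge
}
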