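#' Per-SNP exact association screen between sample subgroups
#'
#' For every locus and every requested comparison, tests the 2x2 allele
#' table ([fisherAllelic()]) and optionally the 2x3 genotype table
#' ([fisherGenotypic()]) between the two groups, then applies
#' false-discovery-rate adjustment. The FDR family is, by default, all loci
#' within one comparison — each pairwise contrast is corrected on its own,
#' as when screening a SNP panel between phenotype subgroups;
#' `family = "joint"` pools all comparisons into one family.
#'
#' Comparisons are given as strings `"G1vsG2"`; either side may pool
#' several group labels with `+`, e.g. `"V+P+KvsIE"` compares the pooled
#' constitution groups against an IE background pool. Missing calls are
#' excluded per locus per comparison (complete-case per SNP). A group with
#' zero non-missing calls at a locus yields a record flagged degenerate
#' with p = 1.
#'
#' @param x a [GenotypeExperiment-class] whose sample metadata has
#'   `group_label`
#' @param comparisons character vector of `"AvsB"` comparison strings
#' @param fdr significance threshold on the adjusted values, in (0, 1)
#' @param genotypic also run the 2x3 genotype-class exact test
#'   (default `TRUE`; the allelic arm alone is much faster on large panels)
#' @param family `"per_comparison"` (default) or `"joint"` FDR family
#' @param fdrMethod `"BH"` (default) or `"BY"`, see [bhAdjust()]
#' @return `data.frame`, one row per (locus, comparison): effect-allele
#'   frequencies and allele counts per group, exact p-values, adjusted
#'   q-values, significance and degenerate-margin flags. Frequencies are
#'   full precision; round only at output.
#' @seealso [simStudyCohort()] for a synthetic cohort to exercise the screen
#' @export
screenAssociations <- function(x, comparisons, fdr = 0.05, genotypic = TRUE,
                               family = c("per_comparison", "joint"),
                               fdrMethod = "BH") {
    stopifnot(methods::is(x, "GenotypeExperiment"),
              fdr > 0, fdr < 1, length(comparisons) >= 1L)
    family <- match.arg(family)
    st <- sampleInfo(x)
    if (!"group_label" %in% colnames(st))
        stop("sample metadata lacks group_label")
    li <- lociInfo(x)
    d <- dosage(x)
    res <- lapply(comparisons, function(cmp) {
        pr <- parseComparison(cmp)
        i1 <- st$sample_id[st$group_label %in% pr$group1]
        i2 <- st$sample_id[st$group_label %in% pr$group2]
        missing_grp <- setdiff(c(pr$group1, pr$group2), st$group_label)
        if (length(missing_grp))
            stop("group label(s) not in sample table: ",
                 paste(missing_grp, collapse = ", "))
        .screenOne(d, li, i1, i2, cmp, genotypic)
    })
    out <- do.call(rbind, res)
    qa <- rep(NA_real_, nrow(out))
    if (family == "joint") {
        out$q_allelic <- bhAdjust(out$p_allelic, fdrMethod)
        if (genotypic) out$q_genotypic <- bhAdjust(out$p_genotypic, fdrMethod)
    } else {
        for (cmp in unique(out$comparison)) {
            i <- out$comparison == cmp
            out$q_allelic[i] <- bhAdjust(out$p_allelic[i], fdrMethod)
            if (genotypic)
                out$q_genotypic[i] <- bhAdjust(out$p_genotypic[i], fdrMethod)
        }
    }
    out$significant_allelic <- out$q_allelic <= fdr & !out$degenerate
    if (genotypic)
        out$significant_genotypic <- out$q_genotypic <= fdr & !out$degenerate
    rownames(out) <- NULL
    out
}

#' Parse a comparison string
#'
#' `"PvsK"` -> groups `"P"` and `"K"`; `"V+P+KvsIE"` pools V, P and K on
#' the left.
#'
#' @param cmp a single `"AvsB"` string
#' @return list with `group1`, `group2` character vectors and `name`
#' @export
parseComparison <- function(cmp) {
    parts <- strsplit(cmp, "vs", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]) || !nzchar(parts[2L]))
        stop("comparison must be of the form 'AvsB': ", cmp)
    list(group1 = strsplit(parts[1L], "+", fixed = TRUE)[[1L]],
         group2 = strsplit(parts[2L], "+", fixed = TRUE)[[1L]],
         name = cmp)
}

# one comparison over all loci; vectorised counting, scalar exact tests
.screenOne <- function(d, li, i1, i2, cmp, genotypic) {
    d1 <- d[, i1, drop = FALSE]
    d2 <- d[, i2, drop = FALSE]
    nn1 <- rowSums(!is.na(d1))
    nn2 <- rowSums(!is.na(d2))
    e1 <- rowSums(d1, na.rm = TRUE)
    e2 <- rowSums(d2, na.rm = TRUE)
    o1 <- 2L * nn1 - e1
    o2 <- 2L * nn2 - e2
    m <- nrow(d)
    pa <- numeric(m)
    deg <- logical(m)
    for (i in seq_len(m)) {
        f <- .fisher2x2(e1[i], o1[i], e2[i], o2[i])
        pa[i] <- f$p_value
        deg[i] <- f$degenerate
    }
    out <- data.frame(
        locus_id = rownames(d),
        gene_label = li$gene_label,
        comparison = cmp,
        freq1 = ifelse(nn1 > 0, e1 / (2 * nn1), NA_real_),
        freq2 = ifelse(nn2 > 0, e2 / (2 * nn2), NA_real_),
        n1_alleles = as.integer(2 * nn1),
        n2_alleles = as.integer(2 * nn2),
        p_allelic = pa,
        q_allelic = NA_real_,
        degenerate = deg,
        stringsAsFactors = FALSE)
    if (genotypic) {
        g1 <- cbind(rowSums(d1 == 0L, na.rm = TRUE),
                    rowSums(d1 == 1L, na.rm = TRUE),
                    rowSums(d1 == 2L, na.rm = TRUE))
        g2 <- cbind(rowSums(d2 == 0L, na.rm = TRUE),
                    rowSums(d2 == 1L, na.rm = TRUE),
                    rowSums(d2 == 2L, na.rm = TRUE))
        pg <- numeric(m)
        for (i in seq_len(m))
            pg[i] <- fisherGenotypic(rbind(g1[i, ], g2[i, ]))$p_value
        out$p_genotypic <- pg
        out$q_genotypic <- NA_real_
    }
    out
}
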