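#' Combined protective-allele score per sample
#'
#' The combined genotype score of a sample is the unweighted count of
#' protective alleles over the designated loci: with k loci it ranges from
#' 0 (homozygous for the risk allele everywhere) to 2k (homozygous
#' protective everywhere). The default configuration is the two-locus
#' EGLN1/VWF score with protective allele T at rs480902 (the
#' high-altitude-adaptation-associated allele) and T at rs1063856 (the
#' derived, non-thrombotic allele); the C allele at both loci is the risk
#' allele, so genotype CC/CC scores 0 and TT/TT scores 4.
#'
#' @param x a [GenotypeExperiment-class] containing all configured loci
#' @param protective named character vector `c(locus_id = allele, ...)`
#'   designating the protective allele per locus; each allele must be one
#'   of the locus' annotated pair
#' @param missingPolicy how to treat a sample with a missing call at any
#'   configured locus: `"exclude"` (default, drop the sample from the
#'   result) or `"keep_na"` (keep the row with score `NA`)
#' @return `data.frame` with columns `sample_id`, `score`
#' @examples
#' ge <- simStudyCohort(seed = 1)
#' head(scoreSamples(ge))
#' @export
scoreSamples <- function(x,
                         protective = c(rs480902 = "T", rs1063856 = "T"),
                         missingPolicy = c("exclude", "keep_na")) {
    stopifnot(methods::is(x, "GenotypeExperiment"),
              length(protective) >= 1L, !is.null(names(protective)))
    missingPolicy <- match.arg(missingPolicy)
    absent <- setdiff(names(protective), rownames(x))
    if (length(absent))
        stop("configured locus absent from matrix: ",
             paste(absent, collapse = ", "))
    li <- lociInfo(x)
    rownames(li) <- li$locus_id
    d <- dosage(x)[names(protective), , drop = FALSE]
    prot <- matrix(NA_integer_, nrow = length(protective), ncol = ncol(d))
    for (i in seq_along(protective)) {
        loc <- names(protective)[i]
        pair <- c(li[loc, "allele_a"], li[loc, "allele_b"])
        if (!protective[i] %in% pair)
            stop("protective allele ", protective[i],
                 " not in allele pair of ", loc)
        prot[i, ] <- if (protective[i] == li[loc, "effect_allele"])
            d[i, ] else 2L - d[i, ]
    }
    score <- colSums(prot)  # NA whenever any configured locus is missing
    out <- data.frame(sample_id = colnames(x), score = as.integer(score),
                      stringsAsFactors = FALSE)
    if (missingPolicy == "exclude") out <- out[!is.na(out$score), ]
    rownames(out) <- NULL
    out
}

#' Enumerate the two-locus genotype-to-score table
#'
#' For two biallelic loci there are 3 x 3 = 9 genotype combinations; each
#' is scored as its count of protective alleles, giving scores 0 through 4.
#' The mapping is symmetric under exchanging the two loci.
#'
#' @param protective named character vector of length 2: protective allele
#'   per locus (default the EGLN1/VWF T/T configuration)
#' @param risk named character vector of length 2: the other (risk) allele
#'   per locus (default C/C)
#' @return `data.frame` with one row per combination: the genotype at each
#'   locus (columns named by locus id) and `score`
#' @examples
#' enumerateComboTable()  # 9 rows, scores 0..4
#' @export
enumerateComboTable <- function(protective = c(rs480902 = "T",
                                               rs1063856 = "T"),
                                risk = c(rs480902 = "C", rs1063856 = "C")) {
    stopifnot(length(protective) == 2L, length(risk) == 2L,
              identical(names(protective), names(risk)),
              all(protective != risk))
    geno <- function(p, r) c(paste0(r, r), paste0(r, p), paste0(p, p))
    g1 <- geno(protective[1L], risk[1L])
    g2 <- geno(protective[2L], risk[2L])
    grid <- expand.grid(d1 = 0:2, d2 = 0:2)
    out <- data.frame(grid$d1, grid$d2)
    out[[1L]] <- g1[grid$d1 + 1L]
    out[[2L]] <- g2[grid$d2 + 1L]
    colnames(out) <- names(protective)
    out$score <- grid$d1 + grid$d2
    out
}

#' Score distribution by stratum
#'
#' Tabulates combined scores within strata (subgroup or population):
#' counts, within-stratum frequencies, and the frequency of the maximum
#' score 2k (the fully protective homozygous combination, the quantity
#' mapped against altitude in the cline analysis).
#'
#' @param scores `data.frame` from [scoreSamples()]
#' @param samples sample metadata `data.frame` with `sample_id` and the
#'   stratifying column
#' @param by name of the stratifying column (default `"group_label"`)
#' @param maxScore the maximum attainable score 2k (default: inferred as
#'   `max(scores$score)` is wrong for small strata, so pass explicitly when
#'   the top class may be empty; default 4 for the two-locus score)
#' @return `data.frame` with columns `stratum`, `score`, `count`,
#'   `frequency`; an attribute `"summary"` holds per-stratum n and the
#'   frequency of the maximum score
#' @export
scoreDistribution <- function(scores, samples, by = "group_label",
                              maxScore = 4L) {
    stopifnot(by %in% colnames(samples))
    m <- merge(scores, samples[, c("sample_id", by)], by = "sample_id")
    strata <- unique(samples[[by]])
    lv <- 0:maxScore
    rows <- lapply(strata, function(s) {
        sc <- m$score[m[[by]] == s & !is.na(m$score)]
        cnt <- as.integer(table(factor(sc, levels = lv)))
        data.frame(stratum = s, score = lv, count = cnt,
                   frequency = if (length(sc)) cnt / length(sc) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(strata, function(s) {
        i <- out$stratum == s
        data.frame(stratum = s, n = sum(out$count[i]),
                   freq_score_max = out$frequency[i & out$score == maxScore],
                   stringsAsFactors = FALSE)
    }))
    attr(out, "summary") <- summ
    out
}
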