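#' Read a locus annotation table
#'
#' Tab-separated file with columns `locus_id`, `allele_a`, `allele_b`,
#' `effect_allele`, and optionally `protective_flag` (logical) and
#' `gene_label`.
#'
#' @param path file path
#' @return `data.frame` of locus annotations
#' @export
readLocusTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("locus_id", .REQUIRED_LOCUS_COLS)
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("locus table lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$locus_id))
        stop("duplicate locus_id in locus table")
    bad <- df$effect_allele != df$allele_a & df$effect_allele != df$allele_b
    if (any(bad))
        stop("effect_allele not in allele pair for locus ",
             df$locus_id[which(bad)[1L]])
    if ("protective_flag" %in% colnames(df))
        df$protective_flag <- as.logical(df$protective_flag)
    df
}

#' Read a sample metadata table
#'
#' Tab-separated file with columns `sample_id`, `group_label`,
#' `population_id`, `altitude_m` (blank altitude allowed).
#'
#' @param path file path
#' @return `data.frame` of sample metadata
#' @export
readSampleTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        stop("sample table lacks column sample_id")
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in sample table")
    if ("altitude_m" %in% colnames(df)) {
        df$altitude_m <- suppressWarnings(as.numeric(df$altitude_m))
        if (any(!is.na(df$altitude_m) & df$altitude_m < 0))
            stop("negative altitude_m")
    }
    df
}

#' Read genotypes from a simple TSV table
#'
#' Expects a header row `sample_id` followed by locus ids, then one row per
#' sample whose cells are unordered two-letter genotype strings (`"CT"` and
#' `"TC"` are equivalent) or the missing token. Genotypes are strand-naive:
#' allele letters must match the annotations exactly, no flipping is
#' attempted.
#'
#' @param path file path
#' @param loci locus annotation `data.frame` (see [readLocusTable()]); every
#'   annotated locus must be a column of the file
#' @param samples optional sample metadata `data.frame`
#' @param missing token denoting a missing call (default `"NN"`)
#' @return a [GenotypeExperiment-class] with dosages counting each locus'
#'   effect allele
#' @export
readGenotypeTSV <- function(path, loci, samples = NULL, missing = "NN") {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    if (colnames(raw)[1L] != "sample_id")
        stop("first column must be sample_id")
    if (anyDuplicated(raw$sample_id))
        stop("duplicate sample id in genotype file: ",
             raw$sample_id[duplicated(raw$sample_id)][1L])
    absent <- setdiff(loci$locus_id, colnames(raw))
    if (length(absent))
        stop("annotated loci absent from genotype file: ",
             paste(absent, collapse = ", "))
    n <- nrow(raw)
    d <- matrix(NA_integer_, nrow = nrow(loci), ncol = n,
                dimnames = list(loci$locus_id, raw$sample_id))
    for (i in seq_len(nrow(loci))) {
        d[i, ] <- .genotypeToDosage(
            raw[[loci$locus_id[i]]], loci$allele_a[i], loci$allele_b[i],
            loci$effect_allele[i], missing,
            locus = loci$locus_id[i], sample_ids = raw$sample_id)
    }
    GenotypeExperiment(d, loci, samples)
}

# two-letter genotype strings -> effect-allele dosage, with hard errors
# naming sample/locus/cell on any unknown allele letter
.genotypeToDosage <- function(cells, a, b, effect, missing, locus,
                              sample_ids) {
    out <- rep(NA_integer_, length(cells))
    is_miss <- cells == missing
    gt <- cells[!is_miss]
    if (length(gt)) {
        if (any(nchar(gt) != 2L))
            .badCell(cells, nchar(cells) != 2L & !is_miss, locus, sample_ids)
        a1 <- substr(gt, 1L, 1L)
        a2 <- substr(gt, 2L, 2L)
        known <- c(a, b)
        bad <- !(a1 %in% known) | !(a2 %in% known)
        if (any(bad)) {
            full_bad <- !is_miss
            full_bad[!is_miss] <- bad
            .badCell(cells, full_bad, locus, sample_ids)
        }
        out[!is_miss] <- (a1 == effect) + (a2 == effect)
    }
    out
}

.badCell <- function(cells, bad, locus, sample_ids) {
    i <- which(bad)[1L]
    stop(sprintf("unknown allele in cell '%s' (sample %s, locus %s)",
                 cells[i], sample_ids[i], locus))
}

#' Write a GenotypeExperiment to the genotype TSV dialect
#'
#' Inverse of [readGenotypeTSV()]: heterozygotes are written as
#' `allele_a` then `allele_b`; re-reading yields identical dosages.
#'
#' @param x a [GenotypeExperiment-class]
#' @param path output file path
#' @param missing missing-call token (default `"NN"`)
#' @return `path`, invisibly
#' @export
writeGenotypeTSV <- function(x, path, missing = "NN") {
    li <- lociInfo(x)
    d <- dosage(x)
    cols <- lapply(seq_len(nrow(li)), function(i) {
        g <- c(paste0(li$allele_a[i], li$allele_a[i]),
               paste0(li$allele_a[i], li$allele_b[i]),
               paste0(li$allele_b[i], li$allele_b[i]))
        if (li$effect_allele[i] == li$allele_a[i]) g <- rev(g)
        out <- g[d[i, ] + 1L]
        out[is.na(out)] <- missing
        out
    })
    df <- data.frame(sample_id = colnames(x), stats::setNames(cols, li$locus_id),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read genotypes for annotated loci from a VCF
#'
#' Loci are matched by the VCF ID column; only the GT subfield is consulted.
#' GT allele indices are mapped through REF/ALT to allele letters and then
#' to effect-allele dosage. Half-missing genotypes (e.g. `"./1"`) are coded
#' missing. An annotated locus absent from the VCF yields a warning and a
#' column of missing calls; REF/ALT letters inconsistent with the
#' annotations are a hard error.
#'
#' @inheritParams readGenotypeTSV
#' @return a [GenotypeExperiment-class]
#' @export
readGenotypeVCF <- function(path, loci, samples = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ids <- v@fix[, "ID"]
    gt <- vcfR::extract.gt(v, element = "GT")
    sample_ids <- colnames(gt)
    d <- matrix(NA_integer_, nrow = nrow(loci), ncol = length(sample_ids),
                dimnames = list(loci$locus_id, sample_ids))
    for (i in seq_len(nrow(loci))) {
        j <- match(loci$locus_id[i], ids)
        if (is.na(j)) {
            warning("locus ", loci$locus_id[i],
                    " absent from VCF; coded missing")
            next
        }
        ref <- unname(v@fix[j, "REF"])
        alt <- unname(v@fix[j, "ALT"])
        pair <- sort(c(loci$allele_a[i], loci$allele_b[i]))
        if (grepl(",", alt) || !identical(sort(c(ref, alt)), pair))
            stop(sprintf(
                "REF/ALT (%s/%s) inconsistent with annotated alleles %s/%s at %s",
                ref, alt, loci$allele_a[i], loci$allele_b[i],
                loci$locus_id[i]))
        letters2 <- c(ref, alt)  # GT index 0 -> REF, 1 -> ALT
        d[i, ] <- vapply(gt[j, ], function(g) {
            if (is.na(g)) return(NA_integer_)
            al <- strsplit(g, "[/|]")[[1L]]
            if (length(al) != 2L || any(al == "."))
                return(NA_integer_)
            sum(letters2[as.integer(al) + 1L] == loci$effect_allele[i])
        }, integer(1L), USE.NAMES = FALSE)
    }
    GenotypeExperiment(d, loci, samples)
}
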