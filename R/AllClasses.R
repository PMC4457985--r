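#' GenotypeExperiment: a dosage matrix with locus and sample annotations
#'
#' `GenotypeExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold biallelic SNP
#' genotypes as effect-allele dosages. Rows are loci, columns are samples.
#' The single assay `"dosage"` stores, per (locus, sample), the number of
#' copies of the locus' designated effect allele: 0, 1, 2 or `NA` for a
#' missing call.
#'
#' Row metadata (one row per locus) must carry the columns
#' `allele_a`, `allele_b` (the two single-letter alleles),
#' `effect_allele` (one of the pair, the allele being counted) and
#' `gene_label`; an optional logical `protective_flag` records whether the
#' effect allele is the designated protective allele. Which allele is
#' ancestral or derived, and which is protective, is annotation input: it is
#' asserted by the analyst, never computed here.
#'
#' Column metadata typically carries `group_label` (phenotype subgroup, e.g.
#' V/P/K or an IE background pool), `population_id` and `altitude_m`
#' (metres, `NA` allowed).
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [GenotypeExperiment()] the constructor, [dosage()],
#'   [lociInfo()], [sampleInfo()], [alleleCounts()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

.REQUIRED_LOCUS_COLS <- c("allele_a", "allele_b", "effect_allele")

.validGenotypeExperiment <- function(object) {
    msg <- character(0)
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
            msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
    }
    rd <- SummarizedExperiment::rowData(object)
    miss <- setdiff(.REQUIRED_LOCUS_COLS, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        ok <- rd$effect_allele == rd$allele_a | rd$effect_allele == rd$allele_b
        if (!all(ok))
            msg <- c(msg, paste0("effect_allele must be allele_a or allele_b",
                                 " (offending locus: ",
                                 rownames(object)[which(!ok)[1L]], ")"))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "locus ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
}

setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Construct a GenotypeExperiment
#'
#' @param dosage integer matrix of effect-allele dosages (loci x samples);
#'   values 0/1/2 or `NA`. Row names are locus ids, column names sample ids.
#'   A samples x loci matrix is accepted and transposed when its dimnames
#'   match `loci$locus_id` on columns.
#' @param loci `data.frame` of locus annotations with columns `locus_id`,
#'   `allele_a`, `allele_b`, `effect_allele`, and optionally
#'   `protective_flag`, `gene_label`. Order defines row order.
#' @param samples optional `data.frame` of per-sample metadata with a
#'   `sample_id` column (plus e.g. `group_label`, `population_id`,
#'   `altitude_m`). Order must cover the dosage columns.
#' @return a [GenotypeExperiment-class] object.
#' @examples
#' loci <- data.frame(locus_id = "rs1", allele_a = "C", allele_b = "T",
#'                    effect_allele = "T", gene_label = "GENE1")
#' d <- matrix(c(0L, 1L, 2L), nrow = 1,
#'             dimnames = list("rs1", c("s1", "s2", "s3")))
#' ge <- GenotypeExperiment(d, loci)
#' dosage(ge)
#' @export
GenotypeExperiment <- function(dosage, loci, samples = NULL) {
    stopifnot(is.matrix(dosage), is.data.frame(loci),
              "locus_id" %in% colnames(loci))
    if (anyDuplicated(loci$locus_id))
        stop("duplicate locus_id in annotations")
    if (!is.null(colnames(dosage)) &&
        all(loci$locus_id %in% colnames(dosage)) &&
        !all(loci$locus_id %in% rownames(dosage)))
        dosage <- t(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- loci$locus_id
    missing_loci <- setdiff(loci$locus_id, rownames(dosage))
    if (length(missing_loci))
        stop("loci absent from dosage matrix: ",
             paste(missing_loci, collapse = ", "))
    dosage <- dosage[loci$locus_id, , drop = FALSE]
    storage.mode(dosage) <- "integer"
    rd <- S4Vectors::DataFrame(loci[, setdiff(colnames(loci), "locus_id"),
                                    drop = FALSE])
    rownames(rd) <- loci$locus_id
    if (!"gene_label" %in% colnames(rd)) rd$gene_label <- NA_character_
    if (is.null(samples)) {
        cd <- S4Vectors::DataFrame(row.names = colnames(dosage))
    } else {
        stopifnot(is.data.frame(samples), "sample_id" %in% colnames(samples))
        if (anyDuplicated(samples$sample_id))
            stop("duplicate sample_id in sample metadata")
        idx <- match(colnames(dosage), samples$sample_id)
        if (anyNA(idx))
            stop("samples absent from metadata: ",
                 paste(colnames(dosage)[is.na(idx)], collapse = ", "))
        cd <- S4Vectors::DataFrame(
            samples[idx, setdiff(colnames(samples), "sample_id"),
                    drop = FALSE])
        rownames(cd) <- colnames(dosage)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowData = rd, colData = cd)
    methods::new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment compact display
#' @param object a `GenotypeExperiment`
#' @export
setMethod("show", "GenotypeExperiment", function(object) {
    cat(sprintf("GenotypeExperiment: %d loci x %d samples\n",
                nrow(object), ncol(object)))
    d <- SummarizedExperiment::assay(object, "dosage")
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
    cd <- SummarizedExperiment::colData(object)
    if ("group_label" %in% colnames(cd)) {
        tab <- table(cd$group_label)
        cat("  groups:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
    }
    if ("population_id" %in% colnames(cd))
        cat(sprintf("  populations: %d\n",
                    length(unique(cd$population_id))))
    invisible(NULL)
})
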