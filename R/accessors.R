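#' Accessors for GenotypeExperiment
#'
#' `dosage()` returns the loci x samples integer dosage matrix (`NA` =
#' missing call); `lociInfo()` the locus annotation table including a
#' `locus_id` column; `sampleInfo()` the per-sample metadata including a
#' `sample_id` column.
#'
#' @param x a [GenotypeExperiment-class]
#' @return `dosage()`: integer matrix; `lociInfo()`, `sampleInfo()`:
#'   `data.frame`.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname genotype-accessors
#' @export
setMethod("dosage", "GenotypeExperiment", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname genotype-accessors
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname genotype-accessors
#' @export
setMethod("lociInfo", "GenotypeExperiment", function(x) {
    df <- as.data.frame(SummarizedExperiment::rowData(x))
    cbind(data.frame(locus_id = rownames(x), stringsAsFactors = FALSE),
          df, row.names = NULL)
})

#' @rdname genotype-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname genotype-accessors
#' @export
setMethod("sampleInfo", "GenotypeExperiment", function(x) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE),
          df, row.names = NULL)
})

#' Allele counts at one locus in a sample subset
#'
#' Counts effect-allele and other-allele copies at `locus` over the given
#' samples, excluding missing calls. The two counts sum to twice the number
#' of samples with a non-missing call.
#'
#' @param x a [GenotypeExperiment-class]
#' @param locus a locus id present in `x`
#' @param samples character vector of sample ids (default: all samples)
#' @return named integer vector `c(effect = , other = )`
#' @examples
#' ge <- GenotypeExperiment(
#'   matrix(c(2L, 2L, 1L, 0L), nrow = 1,
#'          dimnames = list("rs1", paste0("s", 1:4))),
#'   data.frame(locus_id = "rs1", allele_a = "C", allele_b = "T",
#'              effect_allele = "T"))
#' alleleCounts(ge, "rs1")  # c(effect = 5, other = 3)
#' @export
alleleCounts <- function(x, locus, samples = colnames(x)) {
    stopifnot(methods::is(x, "GenotypeExperiment"))
    if (!locus %in% rownames(x))
        stop("locus not in matrix: ", locus)
    if (!length(samples))
        stop("empty sample subset")
    bad <- setdiff(samples, colnames(x))
    if (length(bad))
        stop("unknown sample id(s): ", paste(bad, collapse = ", "))
    d <- dosage(x)[locus, samples]
    d <- d[!is.na(d)]
    eff <- sum(d)
    c(effect = as.integer(eff), other = as.integer(2L * length(d) - eff))
}
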