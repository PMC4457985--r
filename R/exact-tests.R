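#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on the margins, the count in cell (1,1) is hypergeometric.
#' The two-sided p-value follows the point-probability (minimum-likelihood)
#' rule used by mainstream statistical software: the sum of probabilities of
#' all tables with the same margins whose probability does not exceed that
#' of the observed table, with a relative tolerance of 1e-7 on the
#' comparison to absorb floating-point ties. The p-value is clamped to
#' (0, 1].
#'
#' A table with any zero margin carries no information about association;
#' it returns p = 1 flagged `degenerate`.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = alleles)
#' @return list with `p_value` and logical `degenerate`
#' @examples
#' fisherAllelic(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))$p_value  # 1/3
#' @export
fisherAllelic <- function(tab) {
    stopifnot(is.matrix(tab), all(dim(tab) == 2L))
    if (any(tab < 0)) stop("negative count in 2x2 table")
    .fisher2x2(tab[1L, 1L], tab[1L, 2L], tab[2L, 1L], tab[2L, 2L])
}

# scalar kernel: cells a b / c d; margins m = a+b (row1), n = c+d (row2),
# k = a+c (col1). dhyper gives the conditional distribution of a.
.fisher2x2 <- function(a, b, c, d, eps = 1e-7) {
    m <- a + b
    n <- c + d
    k <- a + c
    if (m == 0L || n == 0L || k == 0L || b + d == 0L)
        return(list(p_value = 1, degenerate = TRUE))
    x <- max(0L, k - n):min(k, m)
    pp <- stats::dhyper(x, m, n, k)
    pobs <- stats::dhyper(a, m, n, k)
    p <- sum(pp[pp <= pobs * (1 + eps)])
    list(p_value = min(1, max(p, .Machine$double.xmin)), degenerate = FALSE)
}

#' Two-sided exact test on a 2x3 genotype table
#'
#' Exact conditional test on the 2 x 3 table of genotype-class counts
#' (columns ordered by dosage 0, 1, 2), two-sided by the same
#' point-probability rule as [fisherAllelic()]; the enumeration over all
#' tables with fixed margins is feasible at cohort scale. A column that is
#' all zero is dropped (the test then reduces to the 2x2 case); a zero row
#' margin is degenerate and returns p = 1.
#'
#' @param tab 2 x k matrix of non-negative integer counts
#' @return list with `p_value` and logical `degenerate`
#' @export
fisherGenotypic <- function(tab) {
    stopifnot(is.matrix(tab), nrow(tab) == 2L)
    if (any(tab < 0)) stop("negative count in genotype table")
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L || any(rowSums(tab) == 0))
        return(list(p_value = 1, degenerate = TRUE))
    p <- stats::fisher.test(tab)$p.value
    list(p_value = min(1, max(p, .Machine$double.xmin)), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment: after sorting the m p-values
#' ascending, q(i) = min over j >= i of m * p(j) / j, mapped back to the
#' input order. `method = "BY"` applies the Benjamini-Yekutieli variant for
#' dependent tests.
#'
#' @param p numeric vector of p-values in (0, 1]
#' @param method `"BH"` (default) or `"BY"`
#' @return numeric vector of adjusted values, same order as input
#' @examples
#' bhAdjust(c(0.001, 0.01, 0.02, 0.04, 0.2))
#' @export
bhAdjust <- function(p, method = c("BH", "BY")) {
    method <- match.arg(method)
    if (!length(p)) return(numeric(0))
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = method)
}
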