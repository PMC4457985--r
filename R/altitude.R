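#' Per-population summaries of combined scores
#'
#' One row per population with at least one scored sample: sample count,
#' mean score, the frequency of the maximum score 2k (the fully protective
#' homozygous combination) and the population altitude.
#'
#' @param scores `data.frame` from [scoreSamples()]
#' @param samples sample metadata `data.frame` with `sample_id`,
#'   `population_id` and `altitude_m`
#' @param maxScore maximum attainable score 2k (default 4, the two-locus
#'   score)
#' @return `data.frame` with columns `population_id`, `n_scored`,
#'   `mean_score`, `freq_score_max`, `altitude_m`
#' @export
summarizePopulations <- function(scores, samples, maxScore = 4L) {
    stopifnot(all(c("population_id", "altitude_m") %in% colnames(samples)))
    m <- merge(scores, samples[, c("sample_id", "population_id",
                                   "altitude_m")], by = "sample_id")
    m <- m[!is.na(m$score), ]
    pops <- unique(samples$population_id)
    empty <- setdiff(pops, m$population_id)
    if (length(empty))
        warning("population(s) with zero scored samples omitted: ",
                paste(empty, collapse = ", "))
    out <- do.call(rbind, lapply(intersect(pops, m$population_id),
                                 function(p) {
        sc <- m$score[m$population_id == p]
        data.frame(population_id = p, n_scored = length(sc),
                   mean_score = mean(sc),
                   freq_score_max = mean(sc == maxScore),
                   altitude_m = m$altitude_m[m$population_id == p][1L],
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks). The two-sided p-value is computed by exact enumeration of all
#' n! permutations when n <= 8, and by the t-approximation with n - 2
#' degrees of freedom otherwise. rho is invariant under any strictly
#' increasing transform of either vector and symmetric in its arguments.
#'
#' @param x,y numeric vectors of equal length n >= 3
#' @return list with `rho`, `n`, `p_value`, `method`
#'   (`"exact_permutation"` or `"t_approximation"`) and logical
#'   `degenerate` (`TRUE`, with `rho = NA` and p = 1, when either vector
#'   has zero variance)
#' @examples
#' spearmanCorrelation(1:3, c(10, 20, 30))$rho  # 1
#' @export
spearmanCorrelation <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("need at least 3 paired observations")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        return(list(rho = NA_real_, n = n, p_value = 1,
                    method = "degenerate", degenerate = TRUE))
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= 8L) {
        rxs <- (rx - mean(rx)) / stats::sd(rx)
        rys <- (ry - mean(ry)) / stats::sd(ry)
        perms <- .allPerms(n)
        rhos <- as.vector(matrix(rys[perms], ncol = n) %*% rxs) / (n - 1)
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
        method <- "exact_permutation"
    } else {
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), df = n - 2)
        method <- "t_approximation"
    }
    list(rho = rho, n = n, p_value = min(1, max(p, .Machine$double.xmin)),
         method = method, degenerate = FALSE)
}

# all permutations of 1..n as an (n!) x n matrix
.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

#' Rank-correlation test of a score cline against altitude
#'
#' Tests whether the per-population mean combined score increases with
#' altitude: Spearman rank correlation between mean score and altitude
#' across the population panel. The same correlation is also reported for
#' the frequency of the maximum score (the fully protective homozygous
#' combination) against altitude.
#'
#' @param summaries `data.frame` from [summarizePopulations()] (>= 3
#'   populations with altitude)
#' @return list with elements `mean_score` and `freq_score_max`, each a
#'   [spearmanCorrelation()] result
#' @export
clineTest <- function(summaries) {
    s <- summaries[!is.na(summaries$altitude_m), ]
    if (nrow(s) < 3L)
        stop("need at least 3 populations with altitude")
    list(mean_score = spearmanCorrelation(s$mean_score, s$altitude_m),
         freq_score_max = spearmanCorrelation(s$freq_score_max,
                                              s$altitude_m))
}
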