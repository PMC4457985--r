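#' ScoreAssociation: result of a score-on-outcome regression
#'
#' Holds a fitted logistic (binary) or baseline-category multinomial model
#' of a categorical outcome on the combined genotype score (numeric
#' predictor), with the omnibus likelihood-ratio test against the
#' intercept-only model and, for the multinomial model, per-level contrasts
#' against the reference.
#'
#' @slot model `"binary"` or `"multinomial"`
#' @slot outcomeLevels outcome levels, reference first
#' @slot coefficients matrix, one row per non-reference level, columns
#'   `intercept` and `slope` (log-odds per protective allele)
#' @slot lrtStat likelihood-ratio statistic (>= 0)
#' @slot df degrees of freedom of the test
#' @slot pValue two-sided LRT p-value in (0, 1]
#' @slot converged logical; `FALSE` under (quasi-)separation, where the
#'   coefficient estimates diverge and only the LRT at the boundary is
#'   meaningful
#' @slot contrasts `data.frame` of per-level binary contrasts vs. the
#'   reference (multinomial only), or a 0-row data.frame
#' @export
setClass("ScoreAssociation",
    representation(model = "character", outcomeLevels = "character",
                   coefficients = "matrix", lrtStat = "numeric",
                   df = "integer", pValue = "numeric",
                   converged = "logical", contrasts = "data.frame"))

#' @describeIn ScoreAssociation display
#' @param object a `ScoreAssociation`
#' @export
setMethod("show", "ScoreAssociation", function(object) {
    cat(sprintf("%s logistic score association (reference: %s)\n",
                object@model, object@outcomeLevels[1L]))
    print(round(object@coefficients, 4))
    cat(sprintf("LRT chi-sq = %.4g, df = %d, p = %.4g%s\n",
                object@lrtStat, object@df, object@pValue,
                if (object@converged) "" else "  [not converged]"))
    if (nrow(object@contrasts)) {
        cat("contrasts vs reference:\n")
        print(object@contrasts, digits = 4)
    }
    invisible(NULL)
})

#' @rdname pValue
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Extract the omnibus LRT p-value
#'
#' @param x a [ScoreAssociation-class]
#' @return numeric p-value
#' @export
setMethod("pValue", "ScoreAssociation", function(x) x@pValue)

#' Binary logistic regression of outcome on combined score
#'
#' Maximum-likelihood logistic regression with the score as a numeric
#' predictor, e.g. high-altitude residence vs. sea-level residence, or
#' high-altitude natives vs. one phenotype subgroup. The p-value is from
#' the likelihood-ratio test against the intercept-only model (chi-square,
#' 1 df), preferred over the Wald test for subgroup sizes around 30.
#'
#' @param score numeric vector of combined scores
#' @param outcome vector (2 levels) parallel to `score`; the first factor
#'   level is taken as the reference
#' @return a [ScoreAssociation-class]
#' @examples
#' set.seed(1)
#' s <- rbinom(200, 4, 0.5)
#' y <- rbinom(200, 1, plogis(-1.6 + 0.8 * s))
#' fitScoreBinary(s, y)
#' @export
fitScoreBinary <- function(score, outcome) {
    ok <- !is.na(score) & !is.na(outcome)
    score <- score[ok]
    outcome <- droplevels(as.factor(outcome[ok]))
    if (nlevels(outcome) != 2L)
        stop("outcome must have exactly 2 observed levels")
    if (length(score) < 3L)
        stop("need at least 3 samples")
    y <- as.integer(outcome) - 1L
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(y ~ score, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", w$message) ||
                grepl("did not converge", w$message))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    lrt <- max(0, fit$null.deviance - fit$deviance)
    df <- 1L
    cf <- stats::coef(fit)
    if (anyNA(cf)) {  # constant score: no slope estimable
        lrt <- 0
        cf["score"] <- NA_real_
    }
    if (sep)
        warning("outcome (quasi-)separated by score; ",
                "coefficients unreliable, LRT reported at the boundary")
    p <- min(1, max(stats::pchisq(lrt, df, lower.tail = FALSE),
                    .Machine$double.xmin))
    methods::new("ScoreAssociation", model = "binary",
                 outcomeLevels = levels(outcome),
                 coefficients = matrix(cf, nrow = 1,
                     dimnames = list(levels(outcome)[2L],
                                     c("intercept", "slope"))),
                 lrtStat = lrt, df = df, pValue = p,
                 converged = !sep && fit$converged,
                 contrasts = data.frame())
}

#' Multinomial logistic regression of a 3-level outcome on combined score
#'
#' Baseline-category logit model with the score as a numeric predictor,
#' associating the combined genotype score with phenotype subgroups
#' (e.g. K/V/P). The omnibus p-value is a likelihood-ratio test against
#' the intercept-only model (df = levels - 1); per-level contrasts against
#' the reference (each fitted as a binary logistic on the corresponding
#' sample subset) are reported alongside.
#'
#' Starting values come from [nnet::multinom()]; the fit is then polished
#' by Newton-Raphson with step-halving on the full likelihood, so that the
#' attained deviance (hence the LRT) is invariant to the choice of
#' reference level to high precision.
#'
#' @param score numeric vector of combined scores
#' @param outcome vector parallel to `score`; all declared factor levels
#'   must be observed
#' @param reference outcome level used as baseline (default: first level)
#' @return a [ScoreAssociation-class]
#' @examples
#' set.seed(1)
#' s <- rbinom(96, 4, 0.5)
#' g <- sample(c("K", "V", "P"), 96, replace = TRUE)
#' fitScoreMultinomial(s, g, reference = "K")
#' @export
fitScoreMultinomial <- function(score, outcome, reference = NULL) {
    ok <- !is.na(score) & !is.na(outcome)
    score <- score[ok]
    outcome <- as.factor(outcome[ok])
    if (any(table(outcome) == 0L))
        stop("empty outcome level: ",
             paste(names(which(table(outcome) == 0L)), collapse = ", "))
    if (is.null(reference)) reference <- levels(outcome)[1L]
    if (!reference %in% levels(outcome))
        stop("reference level not among outcome levels")
    outcome <- stats::relevel(droplevels(outcome), ref = reference)
    J <- nlevels(outcome)
    if (J < 2L) stop("outcome must have at least 2 levels")
    n <- length(score)
    yidx <- as.integer(outcome)
    nj <- tabulate(yidx, J)
    nullDev <- -2 * sum(nj * log(nj / n))
    df <- J - 1L
    if (stats::var(score) == 0) {
        cf <- matrix(c(log(nj[-1L] / nj[1L]), rep(NA_real_, J - 1L)),
                     ncol = 2, dimnames = list(levels(outcome)[-1L],
                                               c("intercept", "slope")))
        ctr <- .nullContrasts(levels(outcome))
        return(methods::new("ScoreAssociation", model = "multinomial",
                            outcomeLevels = levels(outcome),
                            coefficients = cf, lrtStat = 0, df = df,
                            pValue = 1, converged = TRUE, contrasts = ctr))
    }
    start <- tryCatch({
        fit0 <- nnet::multinom(outcome ~ score, trace = FALSE,
                               reltol = 1e-12, maxit = 500)
        b <- stats::coef(fit0)
        if (is.null(dim(b))) b <- matrix(b, nrow = 1)
        unname(b)
    }, error = function(e) matrix(0, nrow = J - 1L, ncol = 2L))
    pol <- .multinomNewton(start, score, yidx, J)
    lrt <- max(0, nullDev - pol$deviance)
    p <- min(1, max(stats::pchisq(lrt, df, lower.tail = FALSE),
                    .Machine$double.xmin))
    cf <- pol$beta
    dimnames(cf) <- list(levels(outcome)[-1L], c("intercept", "slope"))
    ctr <- do.call(rbind, lapply(levels(outcome)[-1L], function(lv) {
        i <- outcome %in% c(reference, lv)
        b <- fitScoreBinary(score[i], factor(outcome[i],
                                             levels = c(reference, lv)))
        data.frame(level = lv, reference = reference,
                   slope = b@coefficients[1L, "slope"],
                   lrt_stat = b@lrtStat, p_value = b@pValue,
                   converged = b@converged, stringsAsFactors = FALSE)
    }))
    if (!pol$converged)
        warning("multinomial fit did not converge (possible separation); ",
                "LRT reported at the boundary")
    methods::new("ScoreAssociation", model = "multinomial",
                 outcomeLevels = levels(outcome), coefficients = cf,
                 lrtStat = lrt, df = df, pValue = p,
                 converged = pol$converged, contrasts = ctr)
}

.nullContrasts <- function(lev) {
    data.frame(level = lev[-1L], reference = lev[1L], slope = NA_real_,
               lrt_stat = 0, p_value = 1, converged = TRUE,
               stringsAsFactors = FALSE)
}

# baseline-category logit log-likelihood; beta is (J-1) x 2, reference
# level index 1 has linear predictor 0
.multinomLoglik <- function(beta, x, yidx) {
    eta <- cbind(0, outer(rep(1, length(x)), beta[, 1L]) + x %o% beta[, 2L])
    lse <- log(rowSums(exp(eta - apply(eta, 1L, max)))) + apply(eta, 1L, max)
    sum(eta[cbind(seq_along(x), yidx)] - lse)
}

# Newton-Raphson with step-halving; returns polished coefficients,
# deviance and convergence flag
.multinomNewton <- function(beta, x, yidx, J, maxit = 100L, tol = 1e-10) {
    X <- cbind(1, x)
    n <- length(x)
    ll <- .multinomLoglik(beta, x, yidx)
    converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- cbind(0, X %*% t(beta))
        eta <- eta - apply(eta, 1L, max)
        P <- exp(eta) / rowSums(exp(eta))       # n x J
        Y <- matrix(0, n, J)
        Y[cbind(seq_len(n), yidx)] <- 1
        R <- (Y - P)[, -1L, drop = FALSE]       # n x (J-1)
        grad <- as.vector(t(X) %*% R)           # (b0_2, b1_2, b0_3, b1_3, ...)
        if (max(abs(grad)) < tol) { converged <- TRUE; break }
        K <- J - 1L
        H <- matrix(0, 2L * K, 2L * K)
        for (j in seq_len(K)) for (k in seq_len(K)) {
            w <- if (j == k) P[, j + 1L] * (1 - P[, j + 1L])
                 else        -P[, j + 1L] * P[, k + 1L]
            H[(2L * j - 1L):(2L * j), (2L * k - 1L):(2L * k)] <-
                t(X) %*% (X * w)
        }
        step <- tryCatch(solve(H, grad), error = function(e) NULL)
        if (is.null(step)) break
        stepm <- matrix(step, ncol = 2L, byrow = TRUE)
        lam <- 1
        repeat {
            cand <- beta + lam * stepm
            llc <- .multinomLoglik(cand, x, yidx)
            if (is.finite(llc) && llc >= ll - 1e-12) break
            lam <- lam / 2
            if (lam < 1e-8) { cand <- beta; llc <- ll; break }
        }
        beta <- cand
        if (abs(llc - ll) < tol && max(abs(grad)) < 1e-6) {
            ll <- llc; converged <- TRUE; break
        }
        ll <- llc
    }
    if (max(abs(beta)) > 30) converged <- FALSE  # separation heuristic
    list(beta = beta, deviance = -2 * ll, converged = converged)
}
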