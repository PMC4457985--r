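# Independent brute-force oracles used to validate the package's tests.
# They share no code with the implementation paths they check.

# two-sided 2x2 Fisher p by explicit enumeration of all tables with the
# observed margins, point probabilities from binomial coefficients
oracle_fisher_2x2 <- function(tab, eps = 1e-7) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
    N <- r1 + r2
    as <- max(0, c1 - r2):min(r1, c1)
    pr <- choose(r1, as) * choose(r2, c1 - as) / choose(N, c1)
    pobs <- pr[match(a, as)]
    min(1, sum(pr[pr <= pobs * (1 + eps)]))
}

# two-sided 2xK exact p by enumeration of all tables with fixed margins
# (multivariate hypergeometric point probabilities)
oracle_fisher_2xk <- function(tab, eps = 1e-7) {
    rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
    if (any(rs == 0) || sum(cs > 0) < 2) return(1)
    K <- ncol(tab)
    logp <- function(top) sum(lchoose(cs, top)) - lchoose(N, rs[1])
    pobs <- exp(logp(tab[1, ]))
    tops <- expand.grid(lapply(cs, function(m) 0:m))
    tops <- tops[rowSums(tops) == rs[1], , drop = FALSE]
    pr <- exp(apply(tops, 1, logp))
    min(1, sum(pr[pr <= pobs * (1 + eps)]))
}

# BH step-up adjusted values: q(i) = min over j >= i of m p(j)/j after
# ascending sort, mapped back to input order
oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    qs <- vapply(seq_len(m), function(i)
        min(1, min(m * ps[i:m] / (i:m))), numeric(1))
    q <- numeric(m)
    q[o] <- qs
    q
}

# exact two-sided permutation p for Spearman rho by full n! enumeration,
# rho computed as Pearson correlation of mid-ranks via cor()
oracle_spearman_p <- function(x, y) {
    n <- length(x)
    rho_obs <- cor(rank(x), rank(y))
    perms <- all_perms_oracle(n)
    rhos <- apply(perms, 1, function(pm) cor(rank(x), rank(y[pm])))
    mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_perms_oracle <- function(n) {
    if (n == 1) return(matrix(1, 1, 1))
    out <- NULL
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        sub <- all_perms_oracle(n - 1)
        out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
    }
    unname(out)
}
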