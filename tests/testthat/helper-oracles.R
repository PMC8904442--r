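## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: naive products, lattice searches and
## closed-form counting.

## Naive binomial pmf by direct product (no lchoose): P(ad | dp, theta)
naive_binom_pmf <- function(ad, dp, theta) {
    comb <- 1
    if (ad > 0)
        comb <- prod((dp - ad + seq_len(ad)) / seq_len(ad))
    comb * theta^ad * (1 - theta)^(dp - ad)
}

## Brute-force maximum of the one-component binomial log-likelihood over a
## theta grid.
grid_max_one_component <- function(ad, dp, step = 1e-4) {
    thetas <- seq(0, 1, by = step)
    best <- -Inf
    for (th in thetas) {
        ll <- sum(mitomix::binomLogpmf(ad, dp, th))
        if (ll > best) best <- ll
    }
    best
}

## Brute-force maximum of the two-component binomial mixture log-likelihood
## over a (pi, theta0, theta1) lattice. Counts are compressed to unique
## (ad, dp) patterns so the triple loop stays fast.
grid_max_mixture <- function(ad, dp, step = 0.01) {
    pat <- table(paste(ad, dp))
    key <- do.call(rbind, strsplit(names(pat), " "))
    pa <- as.numeric(key[, 1]); pd <- as.numeric(key[, 2])
    w <- as.numeric(pat)
    thetas <- seq(0, 1, by = step)
    pis <- seq(0, 1, by = step)
    ## patterns x thetas matrices of component probabilities
    B <- outer(seq_along(pa), seq_along(thetas),
               function(i, j) exp(mitomix::binomLogpmf(pa[i], pd[i],
                                                       thetas[j])))
    best <- -Inf
    for (p in pis) {
        ## D[t0, t1] = sum_pat w * log((1-p) B[,t0] + p B[,t1])
        A1 <- p * B          # patterns x t1
        A0 <- (1 - p) * B    # patterns x t0
        for (i0 in seq_along(thetas)) {
            mix <- A0[, i0] + A1   # patterns x t1
            ll <- colSums(w * log(mix))
            m <- max(ll)
            if (m > best) best <- m
        }
    }
    best
}

## Exhaustive-threshold PR/ROC for small instances.
brute_pr_roc <- function(scores, truth) {
    truth <- as.logical(truth)
    thr <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- fpr <- numeric(length(thr))
    for (i in seq_along(thr)) {
        sel <- scores >= thr[i]
        prec[i] <- sum(sel & truth) / sum(sel)
        rec[i] <- sum(sel & truth) / sum(truth)
        fpr[i] <- sum(sel & !truth) / sum(!truth)
    }
    auprc <- sum(diff(c(0, rec)) * prec)
    auroc <- sum(diff(c(0, fpr)) * (rec + c(0, head(rec, -1))) / 2)
    list(precision = prec, recall = rec, fpr = fpr,
         auprc = auprc, auroc = auroc)
}

## Small simulation configs used by several test files: scaled-down problem
## sizes keep the suite quick while preserving every mechanism.
tiny_sim_config <- function(seed = 1L, ...) {
    mitomix::simConfig(variants_per_clone = 3L, noise_sites = 150L,
                       genome_length = 2000L, on_target_depth = 200,
                       rng_seed = seed, ...)
}
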