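test_that("PR/ROC sweep matches brute-force threshold enumeration", {
    ## 4-item toy: AUROC 0.75 by hand
    ev <- prRoc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(ev@auroc, 0.75)
    brute <- brute_pr_roc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(ev@auprc, brute$auprc)
    ## random instances, including ties and -Inf sentinels
    set.seed(81)
    for (i in 1:10) {
        n <- 60
        truth <- runif(n) < 0.3
        scores <- round(rnorm(n, truth * 2), 1)
        scores[sample(n, 3)] <- -Inf
        if (!any(truth) || all(truth)) next
        ev <- prRoc(scores, truth)
        brute <- brute_pr_roc(scores, truth)
        expect_equal(ev@auprc, brute$auprc, tolerance = 1e-12)
        expect_equal(ev@auroc, brute$auroc, tolerance = 1e-12)
    }
})

test_that("AUROC equals the normalised Mann-Whitney U statistic", {
    set.seed(82)
    truth <- runif(100) < 0.4
    scores <- rnorm(100, truth * 0.8)
    ev <- prRoc(scores, truth)
    w <- wilcox.test(scores[truth], scores[!truth], exact = FALSE)
    expect_equal(ev@auroc,
                 unname(w$statistic) / (sum(truth) * sum(!truth)),
                 tolerance = 1e-10)
    ## cross-check against pROC
    skip_if_not_installed("pROC")
    expect_equal(ev@auroc,
                 as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
})

test_that("perfect and uninformative rankings hit the boundary values", {
    truth <- c(rep(TRUE, 5), rep(FALSE, 20))
    ev <- prRoc(c(rnorm(5, 100), rnorm(20)), truth)
    expect_equal(ev@auprc, 1.0)
    expect_equal(ev@auroc, 1.0)
    ## constant scores: a single atomic threshold block, AUROC 1/2
    ev2 <- prRoc(rep(3, 25), truth)
    expect_equal(ev2@auroc, 0.5)
    expect_error(prRoc(1:5, rep(TRUE, 5)), "positive and one negative")
})

test_that("AUPRC never decreases when a positive's score is raised", {
    set.seed(83)
    truth <- runif(40) < 0.25
    scores <- rnorm(40)
    base <- prRoc(scores, truth)@auprc
    i <- which(truth)[1]
    for (bump in c(0.5, 2, 10)) {
        s2 <- scores
        s2[i] <- s2[i] + bump
        expect_gte(prRoc(s2, truth)@auprc, base - 1e-12)
    }
})

test_that("operating points cover boundary thresholds", {
    scores <- c(5, 4, 1, 0.5)
    truth <- c(TRUE, FALSE, TRUE, FALSE)
    expect_equal(operatingPoint(scores, truth, 4.5),
                 c(precision = 1, recall = 0.5))
    ## below the minimum: recall 1, precision = prevalence
    expect_equal(operatingPoint(scores, truth, -1),
                 c(precision = 0.5, recall = 1))
    ## above the maximum: empty selection flagged as NaN
    op <- operatingPoint(scores, truth, 10)
    expect_true(is.nan(op["precision"]))
    expect_equal(unname(op["recall"]), 0)
})

test_that("clone concordance is permutation-invariant and floor-aware", {
    set.seed(84)
    lab <- sample(1:3, 60, replace = TRUE)
    ## one-hot assignment identical to labels, columns permuted
    perm <- c(3, 1, 2)
    prob <- matrix(0.01, 60, 3)
    prob[cbind(1:60, perm[lab])] <- 0.98
    prob <- prob / rowSums(prob)
    cc <- cloneConcordance(prob, lab)
    expect_equal(cc$concordance, 1.0)
    expect_equal(cc$n_assigned, 60L)
    ## uniform soft assignment: nobody passes the 0.8 floor
    cc2 <- cloneConcordance(matrix(1 / 3, 60, 3), lab)
    expect_equal(cc2$n_assigned, 0L)
    expect_true(is.nan(cc2$concordance))
    ## uniform random hard assignment hovers near 1/3
    hard <- matrix(0.001, 600, 3)
    hard[cbind(1:600, sample(1:3, 600, replace = TRUE))] <- 0.998
    hard <- hard / rowSums(hard)
    cc3 <- cloneConcordance(hard, sample(1:3, 600, replace = TRUE))
    expect_gt(cc3$concordance, 1 / 3 - 0.08)
    expect_lt(cc3$concordance, 1 / 3 + 0.08)
})

test_that("concordance uses optimal rectangular matching", {
    ## 2 predicted clones vs 3 labels: best injection is still found
    prob <- matrix(0.01, 30, 2)
    lab <- rep(1:3, each = 10)
    prob[1:10, 1] <- 0.99
    prob[11:30, 2] <- 0.99
    prob <- prob / rowSums(prob)
    cc <- cloneConcordance(prob, lab)
    ## clone1 -> label1 (10) and clone2 -> label2 or 3 (10): 20/30
    expect_equal(cc$concordance, 20 / 30)
})
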