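test_that("lineage trees produce the stated inheritance patterns", {
    carried <- function(cfg) {
        withr::with_seed(1, {
            tr <- plantTreeVariants(cfg)
        })
        colSums(tr$membership)
    }
    expect_equal(carried(simConfig(variants_per_clone = 2, tree = "branched")),
                 c(2, 2, 2))
    expect_equal(carried(simConfig(variants_per_clone = 2, tree = "linear")),
                 c(2, 4, 6))
    ## mixed: c1 private M; M shared by c2+c3; private M each for c2, c3
    expect_equal(carried(simConfig(variants_per_clone = 2, tree = "mixed")),
                 c(2, 4, 4))
    withr::with_seed(2, {
        tr <- plantTreeVariants(simConfig(variants_per_clone = 2,
                                          tree = "branched"))
    })
    expect_equal(nrow(tr$variants), 6L)
    expect_equal(rowSums(tr$membership), rep(1, 6))
})

test_that("planted positions avoid the blacklist and stay distinct", {
    bl_pos <- c(302:315, 513:525, 3105:3109)
    for (tree in c("branched", "linear", "mixed")) {
        withr::with_seed(3, {
            tr <- plantTreeVariants(simConfig(variants_per_clone = 25,
                                              tree = tree))
        })
        expect_false(any(tr$variants$position %in% bl_pos))
        expect_equal(anyDuplicated(tr$variants$position), 0L)
        expect_true(all(tr$variants$ref != tr$variants$alt))
    }
})

test_that("clone sizes follow largest-remainder apportionment", {
    sizes <- function(r, n = 90) {
        cfg <- simConfig(n_cells = n, clone_ratio = r)
        withr::with_seed(1, plantTreeVariants(cfg))$clone_sizes
    }
    expect_equal(sizes(c(1, 1, 1)), c(30L, 30L, 30L))
    expect_equal(sizes(c(2, 4, 4)), c(18L, 36L, 36L))
    expect_equal(sizes(c(2, 2, 6)), c(18L, 18L, 54L))
    expect_equal(sizes(c(1, 1, 8)), c(9L, 9L, 72L))
    ## non-divisible case: sums are exact, remainder to largest fraction
    expect_equal(sum(sizes(c(1, 1, 1), n = 91)), 91L)
})

test_that("identical configs give bit-identical simulations", {
    a <- simulateClones(tiny_sim_config(seed = 42L))
    b <- simulateClones(tiny_sim_config(seed = 42L))
    expect_identical(adCounts(simCounts(a)), adCounts(simCounts(b)))
    expect_identical(dpCounts(simCounts(a)), dpCounts(simCounts(b)))
    expect_identical(as.data.frame(simTruth(a)), as.data.frame(simTruth(b)))
    c <- simulateClones(tiny_sim_config(seed = 43L))
    expect_false(identical(adCounts(simCounts(a)), adCounts(simCounts(c))))
})

test_that("planted allele frequencies and noise levels hit their targets", {
    sim <- simulateClones(simConfig(rng_seed = 11L))
    tr <- simTruth(sim)
    mc <- simCounts(sim)
    eaf <- as.matrix(tr$expectedAF)
    ## clonal mean AF among carrier cells near the log-normal median 0.1
    clonal <- which(tr$isClonal)
    carrier_af <- unlist(lapply(clonal, function(v) {
        cells <- eaf[v, cloneLabels(sim)] > 0
        ad <- adCounts(mc)[v, cells]
        dp <- dpCounts(mc)[v, cells]
        ad[dp > 0] / dp[dp > 0]
    }))
    expect_gte(length(carrier_af), 150L)
    expect_gte(mean(carrier_af), 0.08)
    expect_lte(mean(carrier_af), 0.12)
    ## pooled noise VAF near 0.44%
    nz <- tr$class == "noise"
    noise_vaf <- sum(adCounts(mc)[nz, ]) / sum(dpCounts(mc)[nz, ])
    expect_gte(noise_vaf, 0.002)
    expect_lte(noise_vaf, 0.008)
    ## every candidate has coverage somewhere
    expect_true(all(rowSums(dpCounts(mc)) > 0))
})

test_that("the default candidate space is large and truth-aligned", {
    sim <- simulateClones(simConfig(rng_seed = 12L))
    tr <- simTruth(sim)
    expect_gt(sum(!tr$isClonal), 16000)
    ## truth alignment: isClonal exactly matches the planted variant ids
    planted <- unlist(sim@cloneVariants)
    expect_setequal(tr$id[tr$isClonal], unique(planted))
    expect_identical(tr$id, variantIds(simCounts(sim)))
})

test_that("a noiseless configuration emits only the planted variants", {
    cfg <- simConfig(variants_per_clone = 4, noise_sites = 0L,
                     per_base_error = 0, rng_seed = 13L)
    sim <- simulateClones(cfg)
    tr <- simTruth(sim)
    expect_true(all(tr$isClonal))
    expect_equal(nrow(tr), 12L)
})

test_that("high-AF simulations are perfectly separable by mean AF", {
    ## oracle thresholding of per-variant mean AF must reach AUROC 1: clone
    ## labels must not leak into noise sites
    cfg <- simConfig(clonal_af_mu = 0.5, rng_seed = 14L)
    sim <- simulateClones(cfg)
    mc <- simCounts(sim)
    dp <- dpCounts(mc)
    af <- rowSums(adCounts(mc)) / pmax(rowSums(dp), 1)
    ev <- prRoc(af, simTruth(sim)$isClonal)
    expect_equal(ev@auroc, 1.0)
})
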