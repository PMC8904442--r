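test_that("MitoCounts enforces the AD <= DP invariant with coordinates", {
    v <- data.frame(position = c(100L, 200L, 300L), ref = "A", alt = "G")
    expect_error(
        MitoCounts(matrix(c(0, 5, 0, 2, 8, 0), 3), matrix(3, 3, 2), v),
        "AD > DP at variant")
    expect_error(
        MitoCounts(matrix(-1, 1, 1), matrix(3, 1, 1), v[1, ]),
        "negative")
    expect_error(
        MitoCounts(matrix(0, 1, 1), matrix(0, 1, 1),
                   data.frame(position = 20000L, ref = "A", alt = "G")),
        "positions")
})

test_that("cellSNP round trip preserves counts, variant order and cells", {
    ad <- matrix(c(0, 5, 3, 2, 8, 0), nrow = 3)
    dp <- matrix(c(4, 9, 3, 2, 10, 7), nrow = 3)
    v <- data.frame(position = c(7207L, 100L, 16000L),
                    ref = c("G", "A", "C"), alt = c("A", "T", "T"))
    mc <- MitoCounts(ad, dp, v, cells = c("BC1", "BC2"))
    d <- withr::local_tempdir()
    writeCellSNP(mc, d)
    back <- readCellSNP(d)
    expect_equal(unname(adCounts(back)), unname(adCounts(mc)))
    expect_equal(unname(dpCounts(back)), unname(dpCounts(mc)))
    expect_equal(variantIds(back), c("7207G>A", "100A>T", "16000C>T"))
    expect_equal(cellBarcodes(back), c("BC1", "BC2"))
})

test_that("simulator output read back equals the in-memory matrices", {
    sim <- simulateClones(tiny_sim_config(seed = 7L))
    d <- withr::local_tempdir()
    writeSimulation(sim, d)
    back <- readCellSNP(d)
    expect_equal(unname(adCounts(back)), unname(adCounts(simCounts(sim))))
    expect_equal(unname(dpCounts(back)), unname(dpCounts(simCounts(sim))))
    expect_equal(variantIds(back), variantIds(simCounts(sim)))
})

test_that("reader errors name the offending file on shape mismatches", {
    sim <- simulateClones(tiny_sim_config(seed = 8L))
    d <- withr::local_tempdir()
    writeSimulation(sim, d)
    ## truncate the barcode file
    writeLines("onlycell", file.path(d, "cellSNP.samples.tsv"))
    expect_error(readCellSNP(d), "cellSNP.samples.tsv")
    ## missing matrix
    file.remove(file.path(d, "cellSNP.tag.AD.mtx"))
    expect_error(readCellSNP(d), "cellSNP.tag.AD.mtx")
})

test_that("blacklist removes exactly the error-prone positions", {
    pos <- c(301L, 302L, 315L, 316L, 513L, 525L, 3105L, 3109L, 3110L)
    n <- length(pos)
    mc <- MitoCounts(matrix(1, n, 2), matrix(5, n, 2),
                     data.frame(position = pos, ref = "A", alt = "G"))
    out <- applyBlacklist(mc)
    expect_equal(variantInfo(out)$position, c(301L, 316L, 3110L))
    ## idempotent and order-preserving
    again <- applyBlacklist(out)
    expect_identical(variantIds(again), variantIds(out))
    ## empty region list is the identity
    expect_identical(variantIds(applyBlacklist(mc, IRanges::IRanges())),
                     variantIds(mc))
    ## empty result is legal
    all_bl <- applyBlacklist(mc[c(2, 7), ])
    expect_equal(nrow(all_bl), 0L)
})

test_that("writeSelected keeps relative order and supports degenerate sets", {
    sim <- simulateClones(tiny_sim_config(seed = 9L))
    mc <- simCounts(sim)[1:5, ]
    d <- withr::local_tempdir()
    writeSelected(mc, c(1L, 3L), file.path(d, "some"))
    back <- readCellSNP(file.path(d, "some"))
    expect_equal(variantIds(back), variantIds(mc)[c(1, 3)])
    ## select all
    writeSelected(mc, seq_len(5L), file.path(d, "all"))
    expect_equal(unname(adCounts(readCellSNP(file.path(d, "all")))),
                 unname(adCounts(mc)))
    ## select none -> valid empty matrices and tsv
    writeSelected(mc, integer(), file.path(d, "none"))
    none <- readCellSNP(file.path(d, "none"))
    expect_equal(dim(none), c(0L, ncol(mc)))
    expect_true(file.exists(file.path(d, "none", "deltaBIC.tsv")))
})
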