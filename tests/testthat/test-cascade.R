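test_that("filter boundary semantics: closed band, strict distance and difference", {
    genes <- sprintf("g%d", 1:6)
    conds <- c("sucrose", "acetate")
    w1 <- matrix(1, 6, 2, dimnames = list(genes, conds))
    w2 <- w1
    # baseline fitness at, just under and just over the band edges
    w1[, "sucrose"] <- w2[, "sucrose"] <- c(0.9, 0.89, 1.1, 1.11, 1.0, 1.0)
    # acetate replicate distances at and just under the cutoff (0 - 0.2
    # subtracts exactly in binary, so the boundary is genuinely hit)
    w1[5, "acetate"] <- 0.0; w2[5, "acetate"] <- 0.2    # distance 0.2
    w1[6, "acetate"] <- 0.0; w2[6, "acetate"] <- 0.19   # distance 0.19
    ft <- makeFitnessFixture(w1, w2)
    cfg <- filterConfig(baselineCondition = "sucrose")

    expect_identical(neutralOnBaseline(ft, genes, cfg),
                     c("g1", "g3", "g5", "g6"))
    expect_identical(concordanceFilter(ft, genes, cfg), genes[-5])

    # difference strictly greater than the threshold
    wd1 <- matrix(1, 2, 2, dimnames = list(c("d1", "d2"), conds))
    wd2 <- wd1
    wd1["d1", "acetate"] <- wd2["d1", "acetate"] <- 0.75
    wd1["d2", "acetate"] <- wd2["d2", "acetate"] <- 0.85
    ftd <- makeFitnessFixture(wd1, wd2)
    dg <- differentialGenes(ftd, c("d1", "d2"), cfg, threshold = 0.2)
    expect_identical(dg$acetate, "d1")
    expect_identical(dg$union, "d1")
})

test_that("completeness filter drops flagged genes in any listed condition", {
    genes <- sprintf("g%d", 1:5)
    conds <- c("sucrose", "acetate")
    w <- matrix(1, 5, 2, dimnames = list(genes, conds))
    zero <- matrix(FALSE, 5, 2)
    zero[2, 2] <- TRUE
    lowT1 <- matrix(FALSE, 5, 2)
    lowT1[4, ] <- TRUE
    ft <- makeFitnessFixture(w, w, lowT1, zero)
    expect_identical(completenessFilter(ft), c("g1", "g3", "g5"))
    expect_error(completenessFilter(ft, conditions = "glycerol"),
                 "missing from table")
})

test_that("substrate specificity requires a difference on exactly one substrate", {
    diff <- list(acetate = c("a", "shared"), succinate = c("s", "shared"),
                 glycerol = character())
    spec <- substrateSpecific(diff)
    expect_identical(spec$acetate, "a")
    expect_identical(spec$succinate, "s")
    expect_identical(spec$glycerol, character())
})

test_that("a hand-enumerated eight-gene cascade produces the expected stages", {
    genes <- LETTERS[1:8]
    conds <- c("sucrose", "acetate", "succinate", "glycerol")
    w1 <- matrix(1, 8, 4, dimnames = list(genes, conds))
    w2 <- w1
    zero <- matrix(FALSE, 8, 4, dimnames = list(genes, conds))
    zero["A", "acetate"] <- TRUE
    lowT1 <- matrix(FALSE, 8, 4, dimnames = list(genes, conds))
    lowT1["B", ] <- TRUE
    w1["C", "sucrose"] <- w2["C", "sucrose"] <- 0.8       # fails band
    w1["D", "acetate"] <- 0.9; w2["D", "acetate"] <- 1.2  # distance 0.3
    w1["E", "acetate"] <- w2["E", "acetate"] <- 0.55      # specific, |d|=.45
    w1["F", "acetate"] <- w2["F", "acetate"] <- 0.75      # |d|=.25, on two
    w1["F", "succinate"] <- w2["F", "succinate"] <- 0.75
    w1["H", "glycerol"] <- w2["H", "glycerol"] <- 0.65    # specific, |d|=.35
    ft <- makeFitnessFixture(w1, w2, lowT1, zero)
    rep <- runCascade(ft, filterConfig())

    sc <- stageCounts(rep)
    expect_identical(unname(sc[c("input", "complete", "compared")]),
                     c(8L, 6L, 4L))
    expect_identical(unname(parallelCounts(rep)),
                     c(5L, 5L))  # C fails the band; D fails concordance
    expect_identical(unname(sc[c("differential_0.2", "differential_0.3",
                                 "differential_0.4")]), c(3L, 2L, 1L))
    expect_identical(sort(differentialSets(rep)[["0.2"]]$acetate),
                     c("E", "F"))
    expect_identical(specificSets(rep)[["0.2"]]$acetate, "E")
    expect_identical(specificSets(rep)[["0.2"]]$glycerol, "H")
    expect_identical(specificSets(rep)[["0.2"]]$succinate, character())
    expect_identical(differentialSets(rep)[["0.4"]]$acetate, "E")
})

test_that("every cascade stage equals an independent brute-force re-scan", {
    set.seed(77)
    cfg <- filterConfig()
    for (i in 1:60) {
        ft <- randomFitnessFixture(sample(5:50, 1))
        got <- runCascade(ft, cfg)
        want <- oracleCascade(ft, cfg)
        expect_setequal(completenessFilter(ft), want$complete)
        sc <- stageCounts(got)
        expect_identical(unname(sc["complete"]), length(want$complete))
        expect_identical(unname(sc["compared"]), length(want$compared))
        expect_identical(unname(parallelCounts(got)),
                         c(length(want$neutral), length(want$concordant)))
        for (key in names(differentialSets(got))) {
            for (s in names(want$differential[[key]])) {
                expect_setequal(differentialSets(got)[[key]][[s]],
                                want$differential[[key]][[s]])
                expect_setequal(specificSets(got)[[key]][[s]],
                                want$specific[[key]][[s]])
            }
        }
    }
})

test_that("cascade stages are nested and thresholds monotone", {
    set.seed(101)
    for (i in 1:20) {
        ft <- randomFitnessFixture(sample(10:50, 1))
        rep <- runCascade(ft)
        sc <- stageCounts(rep)
        expect_true(all(diff(sc) <= 0))
        ds <- differentialSets(rep)
        ss <- specificSets(rep)
        keys <- names(ds)
        for (k in seq_along(keys)) {
            for (s in names(ds[[k]])) {
                expect_true(all(ss[[k]][[s]] %in% ds[[k]][[s]]))
                if (k > 1L)  # larger threshold nested in smaller
                    expect_true(all(ds[[k]][[s]] %in% ds[[k - 1L]][[s]]))
            }
        }
    }
})

test_that("an all-neutral noise-free experiment yields no differential genes", {
    lib <- makeLibrary(80, fracDeleterious = 0, seed = 31)
    ft <- fitnessTable(simulateExperiment(lib, depth = 0, seed = 3))
    rep <- runCascade(ft)
    for (key in names(differentialSets(rep)))
        expect_identical(unlist(differentialSets(rep)[[key]],
                                use.names = FALSE), character())
})

test_that("cascade configuration is validated", {
    expect_error(filterConfig(neutralBand = c(1.1, 0.9)), "neutralBand")
    expect_error(filterConfig(differenceThresholds = c(0.3, 0.2)),
                 "strictly increasing")
    ft <- randomFitnessFixture(10)
    expect_error(runCascade(ft, filterConfig(baselineCondition = "mannose")),
                 "baseline condition")
})
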