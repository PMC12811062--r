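test_that("library generation assigns deleterious genes deterministically", {
    # all-neutral case
    lib0 <- makeLibrary(10, fracDeleterious = 0, seed = 1)
    expect_identical(trueFitness(lib0), rep(1, 10))

    # fraction rounded to an exact count, reproducible from the seed
    lib <- makeLibrary(5000, fracDeleterious = 0.1,
                       deleteriousFitnessRange = c(0, 0.6),
                       abundanceDispersion = 1.0,
                       backgroundExpansion = 121.1, seed = 7)
    expect_identical(sum(trueFitness(lib) < 1), 500L)
    expect_true(all(trueFitness(lib) >= 0 & trueFitness(lib) <= 1))
    lib2 <- makeLibrary(5000, fracDeleterious = 0.1,
                        deleteriousFitnessRange = c(0, 0.6),
                        abundanceDispersion = 1.0,
                        backgroundExpansion = 121.1, seed = 7)
    expect_identical(trueFitness(lib), trueFitness(lib2))
    expect_identical(t1Proportions(lib), t1Proportions(lib2))

    # degenerate range forces the exact split
    lib3 <- makeLibrary(2, fracDeleterious = 0.5,
                        deleteriousFitnessRange = c(0.5, 0.5), seed = 3)
    expect_identical(sort(trueFitness(lib3)), c(0.5, 1))

    expect_error(makeLibrary(10, fracDeleterious = 1), "fracDeleterious")
    expect_error(makeLibrary(10, backgroundExpansion = 1),
                 "backgroundExpansion")
    expect_error(makeLibrary(1), "nGenes")
})

test_that("expected t2 proportions follow the closed-form growth model", {
    E <- 121.1
    # neutrality fixed point: proportions unchanged, realized expansion = E
    lib0 <- makeLibrary(50, fracDeleterious = 0, backgroundExpansion = E,
                        seed = 2)
    exp0 <- expectedT2Proportions(lib0)
    expect_equal(exp0$proportions, t1Proportions(lib0), tolerance = 1e-12)
    expect_equal(exp0$realizedExpansion, E, tolerance = 1e-12)

    # one dead lineage among neutrals: two-class closed form
    p <- 0.01
    lib1 <- trueLibrary(c("dead", sprintf("n%02d", 1:99)),
                        c(0, rep(1, 99)),
                        c(p, rep((1 - p) / 99, 99)),
                        backgroundExpansion = E)
    exp1 <- expectedT2Proportions(lib1)
    expect_equal(unname(exp1$proportions[1L]), p / (p + (1 - p) * E),
                 tolerance = 1e-12)
    # direct-summation oracle for the realized expansion
    masses <- t1Proportions(lib1) * E^trueFitness(lib1)
    expect_equal(exp1$realizedExpansion, sum(masses), tolerance = 1e-15)

    # normalisation holds for arbitrary libraries
    for (s in 1:5) {
        lib <- makeLibrary(100, fracDeleterious = 0.3, seed = s)
        expect_equal(sum(expectedT2Proportions(lib)$proportions), 1,
                     tolerance = 1e-12)
    }
})

test_that("multinomial sampling conserves depth and respects the seed", {
    expect_identical(sampleCounts(1.0, 100, seed = 5), 100L)

    cts <- sampleCounts(rep(0.25, 4), 4e6, seed = 3)
    expect_identical(sum(cts), 4000000L)
    sd1 <- sqrt(4e6 * 0.25 * 0.75)
    expect_true(all(abs(cts - 1e6) < 5 * sd1))

    for (s in 1:5) {
        p <- geneProportions(runif(30))
        cts <- sampleCounts(p, 12345, seed = s)
        expect_identical(sum(cts), 12345L)
        expect_identical(cts, sampleCounts(p, 12345, seed = s))
    }
    expect_false(identical(sampleCounts(rep(0.25, 4), 1000, seed = 1),
                           sampleCounts(rep(0.25, 4), 1000, seed = 2)))
    expect_error(sampleCounts(c(0.5, 0.6), 100), "sum to 1")
})

test_that("simulated experiments have the declared layout and metadata", {
    lib <- makeLibrary(40, fracDeleterious = 0.1, seed = 4)
    se <- simulateExperiment(lib, conditions = c("acetate", "succinate",
                                                 "glycerol", "sucrose"),
                             replicates = 2, depth = 1e5, seed = 9)
    expect_s4_class(se, "TnSeqExperiment")
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    expect_identical(sum(cd$timepoint == "t1"), 1L)
    expect_identical(sum(cd$timepoint == "t2"), 8L)
    cts <- SummarizedExperiment::assay(se, "counts")
    expect_true(all(colSums(cts) == 1e5))
    # recorded d equals the synthetic OD ratio
    expect_equal(cd$d, cd$od_t2 / cd$od_t1, tolerance = 1e-9)
    # reproducibility
    se2 <- simulateExperiment(lib, conditions = c("acetate", "succinate",
                                                  "glycerol", "sucrose"),
                              replicates = 2, depth = 1e5, seed = 9)
    expect_identical(SummarizedExperiment::assay(se2, "counts"), cts)

    expect_error(simulateExperiment(lib, conditions = c("acetate",
                                                        "acetate")),
                 "distinct")
})

test_that("noise-free simulation is exactly invertible by the estimator", {
    # all-neutral library: every gene at W = 1, zero replicate distance
    lib0 <- makeLibrary(60, fracDeleterious = 0, seed = 11)
    ft0 <- fitnessTable(simulateExperiment(lib0, depth = 0, seed = 1))
    w0 <- meanW(ft0)
    expect_equal(unname(as.vector(w0)), rep(1, length(w0)),
                 tolerance = 1e-12)
    expect_true(all(replicateDistance(ft0) < 1e-12))

    # single planted non-neutral gene is recovered exactly
    lib <- makeLibrary(100, fracDeleterious = 0, seed = 12)
    lib <- trueLibrary(geneIds(lib), replace(trueFitness(lib), 10, 0.5),
                       t1Proportions(lib))
    ft <- fitnessTable(simulateExperiment(lib, conditions = "acetate",
                                          depth = 0, seed = 2))
    expect_lt(abs(meanW(ft)[10, "acetate"] - 0.5), 1e-9)
})

test_that("ground truth round-trips through its TSV export", {
    lib <- makeLibrary(25, seed = 6)
    path <- tempfile(fileext = ".tsv")
    writeGroundTruth(lib, path)
    df <- read.delim(path)
    expect_identical(df$gene_id, geneIds(lib))
    expect_equal(df$true_fitness, trueFitness(lib), tolerance = 1e-12)
    expect_equal(df$t1_proportion, unname(t1Proportions(lib)),
                 tolerance = 1e-12)
})
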