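test_that("relative weight change arithmetic", {
    ph <- data.frame(subjectId = c("a", "b", "c"),
                     weightT0 = c(100, 90, 87.6),
                     weightT18 = c(84, 90, 83.6))
    wc <- relativeWeightChange(ph)
    expect_equal(wc$relativeChangePct[1], -16)
    expect_equal(wc$relativeChangePct[2], 0)
    expect_equal(round(wc$relativeChangePct[3], 2), -4.57)
    ph$weightT18[2] <- NA
    expect_error(relativeWeightChange(ph), "b")
})

test_that("combined correlation: exact linear, bounds, errors", {
    cc <- combinedCorrelation(1:10, (1:10) * 2 + 1)
    expect_equal(cc$pearsonR, 1)
    expect_equal(cc$spearmanRho, 1)
    expect_equal(cc$combinedR, 1)
    set.seed(3)
    for (i in 1:20) {
        x <- rnorm(12); y <- rnorm(12)
        cc <- combinedCorrelation(x, y)
        expect_gte(cc$combinedP, min(cc$pearsonP, cc$spearmanP))
        expect_lte(cc$combinedP, max(cc$pearsonP, cc$spearmanP))
    }
    expect_error(combinedCorrelation(rep(1, 10), rnorm(10)), "constant")
    expect_error(combinedCorrelation(1:3, 1:3), ">= 4")
})

test_that("geometric-mean p combination identities", {
    expect_equal(combinePValues(c(0.04, 0.09)), 0.06)
    expect_equal(combinePValues(c(0.2, 0.2)), 0.2)
    expect_equal(combinePValues(c(1e-310, 1e-300)), 1e-305)
    expect_error(combinePValues(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("spearman p switches between exact and t-approximation", {
    set.seed(8)
    x <- rnorm(8); y <- rnorm(8)
    cc <- combinedCorrelation(x, y)
    expect_equal(cc$spearmanP,
                 cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
    x2 <- rnorm(30); y2 <- rnorm(30)
    cc2 <- combinedCorrelation(x2, y2)
    n <- 30; rho <- cor(rank(x2), rank(y2))
    expect_equal(cc2$spearmanP,
                 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
})

test_that("ewasScan finds a planted CpG and is order/sign stable", {
    cfg <- simConfig(nSubjects = 40, nProbes = 300, nMarkerProbes = 0,
                     nPlantedEwasCpgs = 1, plantedR = 0.6, nTail = 0,
                     seed = 15)
    sim <- simulateMethylation(cfg)
    scan <- ewasScan(sim$experiment)
    planted <- sim$truth$plantedEwasCpgs$probeId[1]
    expect_lte(match(planted, scan$probeId), 5)
    # tier columns are definitional memberships
    expect_equal(scan$`p_lt_0.01`, scan$combinedP < 0.01)
    expect_equal(scan$`p_lt_0.001`, scan$combinedP < 1e-3)
    # flipping the outcome's sign flips combinedR, preserves combinedP
    wc <- relativeWeightChange(as.data.frame(
        SummarizedExperiment::colData(sim$experiment)))
    wcNeg <- transform(wc, relativeChangePct = -relativeChangePct)
    scanNeg <- ewasScan(sim$experiment, weightChange = wcNeg)
    m <- match(scan$probeId, scanNeg$probeId)
    expect_equal(scan$combinedR, -scanNeg$combinedR[m])
    expect_equal(scan$combinedP, scanNeg$combinedP[m])
    # invariant to sample reordering
    shuffled <- sim$experiment[, sample(ncol(sim$experiment))]
    scanShuf <- ewasScan(shuffled)
    expect_equal(scanShuf$combinedP[match(scan$probeId, scanShuf$probeId)],
                 scan$combinedP)
})

test_that("phenotype correlations detect a planted linear trait", {
    cfg <- simConfig(nSubjects = 30, nProbes = 100, nMarkerProbes = 0,
                     nTail = 0, seed = 23)
    sim <- simulateMethylation(cfg)
    me <- sim$experiment
    ph <- as.data.frame(SummarizedExperiment::colData(me))
    # trait is a linear readout of probe 1's methylation at each timepoint
    ph$fakeTrait <- 10 + 50 * betaValues(me)[1, rownames(ph)]
    SummarizedExperiment::colData(me)$fakeTrait <- ph$fakeTrait
    res <- phenotypeCorrelations(me, "fakeTrait",
                                 probeSet = rownames(me)[1:5])
    hit <- res[res$probeId == rownames(me)[1] & res$analysis == "level_T0", ]
    expect_lt(hit$combinedP, 1e-6)
    expect_equal(hit$pearsonR, 1, tolerance = 1e-9)
    # empty probe set -> empty table
    expect_equal(nrow(phenotypeCorrelations(me, "fakeTrait",
                                            character(0))), 0)
})

test_that("paired change tests: identity, degenerate shift, power", {
    ph <- makePheno(rep(0, 10))
    res <- pairedChangeTests(ph, "weight")
    expect_equal(res$t, 0)
    expect_equal(res$p, 1)
    # constant -1 kg shift: zero-variance differences -> flagged, p = 0
    ph2 <- makePheno(rep(0, 10))
    ph2$weight[ph2$timepoint == "T18"] <-
        ph2$weight[ph2$timepoint == "T18"] - 1
    res2 <- pairedChangeTests(ph2, "weight")
    expect_true(res2$degenerate)
    expect_equal(res2$p, 0)
    expect_equal(res2$meanDelta, -1)
    # cohort-scale weight loss is overwhelmingly significant
    for (seed in 1:5) {
        cfg <- simConfig(nSubjects = 120, weightChangeMeanPct = -4.04,
                         nTail = 0, seed = seed)
        res3 <- pairedChangeTests(simulateCohort(cfg), "weight")
        expect_lt(res3$p, 1e-6)
        expect_lt(res3$meanDelta, 0)
    }
})

test_that("gene annotation: upstream extension, strand, clipping", {
    genes <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr2"),
        IRanges::IRanges(start = c(1500, 5000, 100),
                         end = c(3000, 6000, 200)),
        strand = c("+", "-", "+"))
    names(genes) <- c("G1", "G2", "G3")
    feats <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr1", "chr2"),
        IRanges::IRanges(start = c(1000, 6100, 7510, 150), width = 1))
    ann <- annotateFeaturesToGenes(feats, genes)
    expect_equal(ann[[1]], "G1")  # inside the upstream extension (clipped at 1)
    expect_equal(ann[[2]], "G2")  # within 1500 nt downstream end on - strand
    expect_equal(ann[[3]], character(0))  # 10 nt past the extension
    expect_equal(ann[[4]], "G3")
    # a feature overlapping two genes reports both in input order
    genes2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(100, 150), end = c(300, 400)),
        strand = c("+", "+"))
    names(genes2) <- c("A", "B")
    f2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 210))
    expect_equal(annotateFeaturesToGenes(f2, genes2)[[1]], c("A", "B"))
    # unknown strand defaults to '+' with a warning
    GenomicRanges::strand(genes2) <- c("*", "+")
    expect_warning(annotateFeaturesToGenes(f2, genes2), "strand")
})

test_that("gene annotation agrees with the all-pairs oracle", {
    set.seed(40)
    for (i in 1:20) {
        ng <- sample(3:15, 1); nf <- sample(3:15, 1)
        gs <- sample(1:5000, ng); ge <- gs + sample(100:2000, ng, TRUE)
        str <- sample(c("+", "-"), ng, TRUE)
        genes <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(gs, ge), strand = str)
        names(genes) <- paste0("G", seq_len(ng))
        fs <- sample(1:7000, nf)
        feats <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(fs, fs + sample(0:500, nf, TRUE)))
        ann <- annotateFeaturesToGenes(feats, genes)
        oracle <- geneOverlapOracle(rep("chr1", nf), GenomicRanges::start(feats),
                                    GenomicRanges::end(feats),
                                    rep("chr1", ng), gs, ge, str,
                                    names(genes))
        for (k in seq_len(nf))
            expect_setequal(ann[[k]], oracle[[k]])
    }
})
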