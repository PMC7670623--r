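test_that("responder selection takes the deciles deterministically", {
    chg <- seq(-19, 19, by = 2)  # 20 distinct changes
    ph <- makePheno(chg)
    des <- selectResponders(ph, nPerGroup = 10)
    expect_setequal(des$groupA, sprintf("P%02d", 1:10))
    expect_setequal(des$groupB, sprintf("P%02d", 11:20))
    expect_length(intersect(des$groupA, des$groupB), 0)
    # boundary tie broken by ascending subject id
    chg2 <- c(rep(-10, 4), rep(10, 4))
    ph2 <- makePheno(chg2)
    des2 <- selectResponders(ph2, nPerGroup = 3)
    expect_equal(sort(des2$groupA), c("P01", "P02", "P03"))
    expect_equal(sort(des2$groupB), c("P05", "P06", "P07"))
    # sex filter and shortage error
    phF <- makePheno(chg, sex = c("male", "female"))
    expect_error(selectResponders(phF, nPerGroup = 10), "selection error")
    # age imbalance flag
    ph3 <- makePheno(chg, age = c(rep(30, 10), rep(60, 10)))
    expect_true(selectResponders(ph3, nPerGroup = 10)$ageImbalance)
})

test_that("selection matches the generator's planted responder truth", {
    sim <- simulateMethylation(simConfig(nSubjects = 60, maleFraction = 1,
                                         nTail = 10, nProbes = 50,
                                         nMarkerProbes = 0, seed = 13))
    lab <- sim$truth$responderLabels
    des <- selectResponders(sim$cohort, nPerGroup = 10)
    expect_setequal(des$groupA, names(lab)[lab == "responder"])
    expect_setequal(des$groupB, names(lab)[lab == "non_responder"])
})

test_that("probe clustering follows the gap rule", {
    man <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 500, 1400, 2600), width = 1))
    names(man) <- paste0("cg", 1:4)
    cl <- clusterProbes(man)
    expect_equal(nrow(cl), 1)
    expect_equal(cl$probeIds[[1]], c("cg1", "cg2", "cg3"))
    expect_equal(c(cl$start, cl$end), c(1, 1400))
    # gaps of exactly 1000 nt stay in one cluster (boundary inclusive)
    man2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(1, 1001, 2001, 3001), width = 1))
    names(man2) <- paste0("cg", 1:4)
    expect_equal(nrow(clusterProbes(man2)), 1)
    expect_equal(clusterProbes(man2)$nProbes, 4)
    # chromosomes never co-cluster
    man3 <- GenomicRanges::GRanges(rep(c("chr1", "chr2"), each = 3),
        IRanges::IRanges(start = rep(c(1, 100, 200), 2), width = 1))
    names(man3) <- paste0("cg", 1:6)
    cl3 <- clusterProbes(man3)
    expect_equal(nrow(cl3), 2)
    expect_setequal(cl3$chrom, c("chr1", "chr2"))
})

test_that("combined-timepoint mode doubles each group's sample set", {
    ph <- makePheno(seq(-16, 3, length.out = 8))
    both <- methresp:::designSamples(ph, c("P01", "P02"), c("T0", "T18"))
    t0 <- methresp:::designSamples(ph, c("P01", "P02"), "T0")
    expect_length(both, 2 * length(t0))
    expect_setequal(both, c("P01_T0", "P01_T18", "P02_T0", "P02_T18"))
})

test_that("callDMRs recovers a planted region and respects geometry", {
    cfg <- simConfig(nSubjects = 16, maleFraction = 1, nTail = 8,
                     nProbes = 400, nMarkerProbes = 0, nPlantedDmrs = 2,
                     plantedDeltaM = 0.12, dmrWidthProbes = 5,
                     clusterSizeRange = c(5L, 5L), noiseSd = 0.05, seed = 4)
    sim <- simulateMethylation(cfg)
    des <- selectResponders(sim$cohort, nPerGroup = 8)
    dmrs <- callDMRs(sim$experiment, des, nPerm = 200, seed = 1)
    expect_s4_class(dmrs, "GRanges")
    # regions never span chromosomes and bounds are member-probe positions
    man <- probeManifest(sim$experiment)
    for (i in seq_along(dmrs)) {
        ids <- dmrs$probeIds[[i]]
        expect_length(unique(as.character(seqnames(man[ids]))), 1)
        expect_equal(start(dmrs)[i], min(start(man[ids])))
        expect_equal(end(dmrs)[i], max(start(man[ids])))
    }
    expect_true(all(dmrs$adjP >= dmrs$ks2dP))
    # planted regions surface at the permutation floor with accurate deltaM
    truth <- sim$truth$plantedDmrs
    tGr <- GenomicRanges::GRanges(truth$chrom,
        IRanges::IRanges(truth$start, truth$end))
    hits <- GenomicRanges::findOverlaps(tGr, dmrs)
    expect_setequal(S4Vectors::queryHits(hits), seq_len(nrow(truth)))
    for (k in seq_len(nrow(truth))) {
        cand <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
        best <- cand[which.min(dmrs$ks2dP[cand])]
        expect_lt(abs(dmrs$deltaM[best] - truth$deltaM[k]), 0.03)
        expect_equal(dmrs$ks2dP[best], 1 / 201)
    }
})

test_that("single-CpG tests behave across outcome types", {
    set.seed(6)
    n <- 20
    beta <- matrix(rnorm(50 * n, 0.4, 0.02), 50, n,
                   dimnames = list(sprintf("cg%05d", 1:50),
                                   paste0("s", 1:n)))
    grp <- rep(c("a", "b"), each = n / 2)
    beta[1, grp == "b"] <- beta[1, grp == "b"] + 0.10
    beta[2, ] <- 0.42  # constant probe
    res <- dmpSingleCpG(beta, grp)
    expect_lt(res$p[1], 1e-4)
    expect_gt(res$estimate[1], 0.05)
    expect_equal(res$p[2], 1)
    expect_true(res$flagged[2])
    expect_true(all(res$q >= res$p))
    # continuous outcome matches cor.test's t transform
    y <- rnorm(n)
    resC <- dmpSingleCpG(beta, y)
    ct <- cor.test(beta[5, ], y)
    expect_equal(resC$p[5], ct$p.value, tolerance = 1e-12)
    # paired mode detects a within-subject shift
    subj <- rep(sprintf("P%02d", 1:(n / 2)), 2)
    tp <- rep(c("T0", "T18"), each = n / 2)
    betaP <- beta
    betaP[3, tp == "T18"] <- betaP[3, tp == "T0"] + 0.1 +
        rnorm(n / 2, 0, 0.01)
    resP <- dmpSingleCpG(betaP, tp, paired = TRUE, subject = subj)
    expect_lt(resP$p[3], 1e-6)
    expect_lt(abs(resP$estimate[3] - 0.1), 0.02)
})

test_that("BH adjustment matches the hand example and the oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    set.seed(9)
    for (i in 1:50) {
        p <- runif(sample(1:40, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bhOracle(p))
        expect_true(all(adj >= p))
        # non-decreasing in sorted-p order
        expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
})
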