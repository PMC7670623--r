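test_that("manifest geometry: clusters obey the DMR rule, positions sorted", {
    cfg <- simConfig(nProbes = 500, nChromosomes = 3, nTail = 0, seed = 9)
    man <- simulateManifest(cfg)
    expect_length(man, 500)
    expect_false(anyDuplicated(names(man)) > 0)
    # strictly increasing positions within chromosome
    for (ch in unique(as.character(seqnames(man)))) {
        pos <- start(man[seqnames(man) == ch])
        expect_true(all(diff(pos) > 0))
    }
    # every cluster re-checked by scan: >= 3 probes, consecutive gaps <= 1000
    cl <- man$clusterId
    for (id in unique(cl[!is.na(cl)])) {
        sel <- man[!is.na(cl) & cl == id]
        expect_gte(length(sel), 3)
        expect_length(unique(as.character(seqnames(sel))), 1)
        expect_true(all(diff(start(sel)) <= 1000))
    }
    # a sizeable fraction of probes lives in clusters
    expect_gt(mean(!is.na(cl)), 0.5)
})

test_that("empty and invalid manifest configs", {
    expect_length(simulateManifest(simConfig(nProbes = 0, nTail = 0)), 0)
    expect_error(simConfig(nProbes = -5), "non-negative")
    expect_error(simConfig(maleFraction = 1.2), "maleFraction")
    expect_error(simConfig(plantedDeltaM = 1), "plantedDeltaM")
    expect_error(simConfig(dmrWidthProbes = 2), "dmrWidthProbes")
})

test_that("simulation is deterministic under a fixed seed", {
    cfg <- simConfig(nSubjects = 10, nProbes = 200, nMarkerProbes = 50,
                     nPlantedDmrs = 2, plantedDeltaM = 0.1,
                     nPlantedEwasCpgs = 2, nTail = 3, seed = 77)
    s1 <- simulateMethylation(cfg)
    s2 <- simulateMethylation(cfg)
    expect_identical(s1$manifest, s2$manifest)
    expect_identical(s1$cohort, s2$cohort)
    expect_identical(betaValues(s1$experiment), betaValues(s2$experiment))
    expect_identical(detectionP(s1$experiment), detectionP(s2$experiment))
    expect_identical(s1$truth, s2$truth)
})

test_that("cohort: weight arithmetic, tails, degenerate sd", {
    cfg <- simConfig(nSubjects = 40, nTail = 5, maleFraction = 1, seed = 3)
    ph <- simulateCohort(cfg)
    expect_equal(nrow(ph), 80)
    expect_setequal(unique(ph$timepoint), c("T0", "T18"))
    # planted tails sit at the configured means
    lab <- ph$responderLabel[!duplicated(ph$subjectId)]
    chg <- with(ph[!duplicated(ph$subjectId), ],
                100 * (weightT18 - weightT0) / weightT0)
    expect_equal(sum(lab == "responder"), 5)
    expect_equal(sum(lab == "non_responder"), 5)
    expect_lt(mean(chg[lab == "responder"]), -12)
    expect_gt(mean(chg[lab == "non_responder"]), 0)
    # responders are exactly the most extreme subjects
    expect_true(max(chg[lab == "responder"]) <=
                min(chg[lab != "responder"]))
    # sd = 0 without tails collapses onto the configured mean
    cfg0 <- simConfig(nSubjects = 6, weightChangeMeanPct = -5,
                      weightChangeSdPct = 0, nTail = 0, seed = 1)
    ph0 <- simulateCohort(cfg0)
    chg0 <- with(ph0[!duplicated(ph0$subjectId), ],
                 100 * (weightT18 - weightT0) / weightT0)
    expect_true(all(abs(chg0 + 5) < 0.02))  # rounding of weights only
    expect_error(simulateCohort(simConfig(nSubjects = 1)), ">= 2")
})

test_that("cohort Monte-Carlo: sample mean matches the configured change", {
    cfg <- simConfig(nSubjects = 1000, weightChangeMeanPct = -3.65,
                     weightChangeSdPct = 5.2, nTail = 0, seed = 42)
    ph <- simulateCohort(cfg)
    chg <- with(ph[!duplicated(ph$subjectId), ],
                100 * (weightT18 - weightT0) / weightT0)
    expect_lt(abs(mean(chg) - (-3.65)), 0.5)
})

test_that("zero-noise, effect-free betas are identical across samples", {
    cfg <- simConfig(nSubjects = 5, nProbes = 60, nMarkerProbes = 0,
                     noiseSd = 0, nTail = 0, seed = 8)
    sim <- simulateMethylation(cfg)
    b <- betaValues(sim$experiment)
    expect_true(all(apply(b, 1, function(x) max(x) - min(x)) == 0))
    expect_true(all(b > 0 & b < 1))
})

test_that("planted DMR difference is realized at the configured scale", {
    diffs <- vapply(1:20, function(seed) {
        cfg <- simConfig(nSubjects = 20, maleFraction = 1, nTail = 10,
                         nProbes = 300, nMarkerProbes = 0,
                         nPlantedDmrs = 1, plantedDeltaM = 0.10,
                         dmrWidthProbes = 5, noiseSd = 0.02, seed = seed)
        sim <- simulateMethylation(cfg)
        lab <- sim$truth$responderLabels
        ph <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
        sa <- rownames(ph)[ph$subjectId %in% names(lab)[lab == "responder"]]
        sb <- rownames(ph)[ph$subjectId %in%
                           names(lab)[lab == "non_responder"]]
        ids <- sim$truth$plantedDmrs$probeIds[[1]]
        b <- betaValues(sim$experiment)
        mean(rowMeans(b[ids, sa]) - rowMeans(b[ids, sb]))
    }, numeric(1))
    expect_lt(abs(mean(diffs) - 0.10), 0.03)
})

test_that("planted EWAS correlation is realized at the configured scale", {
    rs <- vapply(1:8, function(seed) {
        cfg <- simConfig(nSubjects = 120, nProbes = 200, nMarkerProbes = 0,
                         nPlantedEwasCpgs = 1, plantedR = 0.6, seed = seed)
        sim <- simulateMethylation(cfg)
        ph <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
        t0 <- rownames(ph)[ph$timepoint == "T0"]
        wc <- relativeWeightChange(ph)
        y <- wc$relativeChangePct[match(ph[t0, "subjectId"], wc$subjectId)]
        pr <- sim$truth$plantedEwasCpgs$probeId[1]
        cor(betaValues(sim$experiment)[pr, t0], y)
    }, numeric(1))
    expect_true(all(rs > 0.4 & rs < 0.75))
})

test_that("synthetic truth is internally consistent", {
    cfg <- simConfig(nSubjects = 12, nProbes = 400, nMarkerProbes = 100,
                     nPlantedDmrs = 3, nPlantedEwasCpgs = 3, nTail = 3,
                     maleFraction = 1, seed = 21)
    sim <- simulateMethylation(cfg)
    man <- sim$manifest
    for (ids in sim$truth$plantedDmrs$probeIds) {
        expect_true(all(ids %in% names(man)))
        sel <- man[ids]
        expect_gte(length(sel), 3)
        expect_true(all(diff(start(sel)) <= 1000))
    }
    expect_true(all(sim$truth$plantedEwasCpgs$probeId %in% names(man)))
    expect_true(all(abs(rowSums(sim$truth$trueCellProportions) - 1) < 1e-9))
    # mismatched inputs are rejected
    expect_error(simulateBeta(man[0], sim$cohort, cfg), "non-empty")
})
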