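twoTypeReference <- function() {
    prof <- cbind(T1 = c(0.9, 0.1, 0.8, 0.2), T2 = c(0.1, 0.9, 0.2, 0.8))
    rownames(prof) <- sprintf("cg%05d", 1:4)
    CellReference(prof)
}

test_that("noiseless mixtures are recovered exactly", {
    ref <- twoTypeReference()
    w <- c(0.6, 0.4)
    beta <- cbind(mix = referenceProfile(ref) %*% w,
                  pure = referenceProfile(ref)[, 1])
    colnames(beta) <- c("mix", "pure")
    est <- estimateCellProportions(beta, ref)
    expect_lt(max(abs(est["mix", ] - w)), 1e-6)
    expect_equal(unname(est["pure", ]), c(1, 0), tolerance = 1e-9)
    expect_true(all(abs(rowSums(est) - 1) < 1e-6))
})

test_that("too few shared markers is an error", {
    ref <- twoTypeReference()
    beta <- matrix(0.5, 1, 2,
                   dimnames = list("cg00001", c("a", "b")))
    expect_error(estimateCellProportions(beta, ref), "under-determined")
})

test_that("noisy six-type mixtures are recovered with small error", {
    cfg <- simConfig(nSubjects = 15, nProbes = 700, nMarkerProbes = 600,
                     noiseSd = 0.02, nTail = 0, seed = 31)
    sim <- simulateMethylation(cfg)
    est <- estimateCellProportions(sim$experiment, sim$reference)
    truth <- sim$truth$trueCellProportions[rownames(est), colnames(est)]
    expect_lt(mean(abs(est - truth)), 0.05)
    # deterministic
    expect_identical(est, estimateCellProportions(sim$experiment,
                                                  sim$reference))
})

test_that("composition comparison handles identity, shift and tiny n", {
    set.seed(7)
    n <- 20
    ph <- makePheno(rep(-5, n))
    props0 <- matrix(runif(2 * n, 0.2, 0.8), 2 * n, 1)
    props <- cbind(A = props0, B = 1 - props0)
    colnames(props) <- c("A", "B")
    rownames(props) <- rownames(ph)
    # T18 identical to T0 -> all p = 1
    idProps <- props
    idProps[ph$timepoint == "T18", ] <- idProps[ph$timepoint == "T0", ]
    res <- compareComposition(idProps, ph)
    expect_true(all(res$p == 1))
    # constant +0.1 shift in one type, 20 pairs -> strong signal
    shifted <- idProps
    shifted[ph$timepoint == "T18", "A"] <-
        shifted[ph$timepoint == "T0", "A"] + 0.1
    shifted[ph$timepoint == "T18", "B"] <-
        shifted[ph$timepoint == "T18", "B"] - 0.1
    res2 <- compareComposition(shifted, ph)
    expect_lt(res2$p[res2$cellType == "A"], 0.01)
    expect_equal(res2$medianDifference[res2$cellType == "A"], 0.1)
    # two pairs: exact signed-rank test cannot go below 0.25
    ph2 <- makePheno(c(-5, -5))
    pr2 <- matrix(c(0.3, 0.5, 0.4, 0.6, 0.7, 0.5, 0.6, 0.4), 4, 2,
                  dimnames = list(rownames(ph2), c("A", "B")))
    res3 <- compareComposition(pr2, ph2)
    expect_true(all(res3$p >= 0.25))
    # unpaired subject is reported by name
    expect_error(compareComposition(pr2[-1, , drop = FALSE], ph2), "P01")
})

test_that("composition adjustment removes composition variance only", {
    set.seed(12)
    n <- 30
    props <- cbind(A = runif(n, 0.2, 0.8))
    props <- cbind(props, B = 1 - props[, 1])
    rownames(props) <- paste0("s", seq_len(n))
    # betas exactly linear in proportions -> adjusted to the grand mean
    beta <- rbind(cg1 = 0.2 + 0.5 * props[, 1],
                  cg2 = 0.9 - 0.6 * props[, 1])
    colnames(beta) <- rownames(props)
    adj <- adjustForComposition(beta, props)
    expect_lt(max(abs(adj - rowMeans(beta))), 1e-9)
    # identical proportions across samples: output equals input
    flat <- matrix(0.5, n, 2, dimnames = list(rownames(props), c("A", "B")))
    beta2 <- matrix(runif(2 * n), 2, n, dimnames = dimnames(beta))
    expect_warning(adj2 <- adjustForComposition(beta2, flat),
                   "rank-deficient")
    expect_equal(adj2, beta2)
    # per-probe means preserved
    beta3 <- matrix(runif(5 * n, 0.2, 0.8), 5, n,
                    dimnames = list(paste0("cg", 1:5), rownames(props)))
    adj3 <- adjustForComposition(beta3, props)
    expect_lt(max(abs(rowMeans(adj3) - rowMeans(beta3))), 1e-9)
})

test_that("adjustment recovers a planted group effect under confounding", {
    set.seed(99)
    nPer <- 20
    types <- c("A", "B", "C")
    nMark <- 150
    prof <- matrix(runif(nMark * 3, 0.1, 0.9), nMark, 3,
                   dimnames = list(sprintf("cg%05d", 1:nMark), types))
    # planted probes load on cell type A so the confounder biases them
    planted <- 1:5
    prof[planted, ] <- cbind(runif(5, 0.75, 0.85), runif(5, 0.25, 0.35),
                             runif(5, 0.25, 0.35))
    ref <- CellReference(prof)
    # responders mildly enriched for type A (the confounder)
    mkProps <- function(n, alpha) {
        g <- matrix(rgamma(n * 3, shape = rep(alpha, each = n)), n, 3)
        g / rowSums(g)
    }
    pA <- mkProps(nPer, c(5, 4.5, 4.5)); pB <- mkProps(nPer, c(4, 5, 5))
    props <- rbind(pA, pB)
    dimnames(props) <- list(paste0("s", 1:(2 * nPer)), types)
    group <- rep(c(0, 1), each = nPer)
    beta <- t(props %*% t(prof))
    beta[planted, group == 0] <- beta[planted, group == 0] + 0.08
    beta <- pmin(pmax(beta + rnorm(length(beta), 0, 0.01), 0.001), 0.999)
    dimnames(beta) <- list(rownames(prof), rownames(props))
    rawDelta <- mean(rowMeans(beta[planted, group == 0]) -
                     rowMeans(beta[planted, group == 1]))
    est <- estimateCellProportions(beta, ref)
    adj <- adjustForComposition(beta, est)
    adjDelta <- mean(rowMeans(adj[planted, group == 0]) -
                     rowMeans(adj[planted, group == 1]))
    # confounding inflates the raw contrast; adjustment restores the plant
    expect_lt(abs(adjDelta - 0.08), abs(rawDelta - 0.08))
    expect_lt(abs(adjDelta - 0.08), 0.02)
})
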