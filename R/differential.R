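#' Select extreme responders and non-responders
#'
#' Ranks subjects of the requested sex by relative weight change
#' \eqn{(w_{T18} - w_{T0}) / w_{T0} \times 100}: the \code{nPerGroup} most
#' negative are the responders, the \code{nPerGroup} most positive the
#' non-responders. Ties at a group boundary are broken by ascending subject
#' id, making the selection deterministic. Age matching is a post-hoc balance
#' check: the design carries the group mean ages and a flag raised when their
#' absolute difference exceeds \code{ageTolerance} years.
#'
#' @param pheno per-sample phenotype data (rownames = sample ids) with
#'   columns \code{subjectId}, \code{sex}, \code{age}, \code{weightT0},
#'   \code{weightT18}, e.g. \code{colData} of the experiment.
#' @param nPerGroup subjects per group (default 10).
#' @param sexFilter sex label to keep (default \code{"male"}); \code{NULL}
#'   keeps everyone.
#' @param ageTolerance tolerated absolute difference of group mean ages in
#'   years (default 5).
#' @return a list of class \code{"GroupDesign"}: \code{groupA}/\code{groupB}
#'   (responder / non-responder subject ids), labels, group mean ages and
#'   relative changes, and \code{ageImbalance} flag.
#' @export
selectResponders <- function(pheno, nPerGroup = 10L, sexFilter = "male",
                             ageTolerance = 5) {
    pheno <- as.data.frame(pheno)
    sub <- pheno[!duplicated(pheno$subjectId), ]
    if (!is.null(sexFilter)) sub <- sub[sub$sex %in% sexFilter, ]
    if (nrow(sub) < 2L * nPerGroup)
        stop("selection error: only ", nrow(sub),
             " subjects after sex filter, need ", 2L * nPerGroup)
    change <- 100 * (sub$weightT18 - sub$weightT0) / sub$weightT0
    ordAsc <- order(change, sub$subjectId)
    ordDesc <- order(-change, sub$subjectId)
    responders <- sub$subjectId[ordAsc[seq_len(nPerGroup)]]
    nonResponders <- sub$subjectId[ordDesc[seq_len(nPerGroup)]]
    if (length(intersect(responders, nonResponders)))
        stop("selection error: responder groups overlap; too few subjects")
    meanAge <- c(mean(sub$age[sub$subjectId %in% responders]),
                 mean(sub$age[sub$subjectId %in% nonResponders]))
    design <- list(groupA = responders, groupB = nonResponders,
                   labelA = "responder", labelB = "non_responder",
                   meanAgeA = meanAge[1], meanAgeB = meanAge[2],
                   ageImbalance = abs(diff(meanAge)) > ageTolerance,
                   meanChangeA = mean(change[ordAsc[seq_len(nPerGroup)]]),
                   meanChangeB = mean(change[ordDesc[seq_len(nPerGroup)]]))
    class(design) <- "GroupDesign"
    design
}

#' @export
print.GroupDesign <- function(x, ...) {
    cat("GroupDesign:", length(x$groupA), x$labelA, "vs", length(x$groupB),
        x$labelB, "\n")
    cat(sprintf("  mean relative change: %.2f%% vs %.2f%%\n",
                x$meanChangeA, x$meanChangeB))
    cat(sprintf("  mean age: %.1f vs %.1f%s\n", x$meanAgeA, x$meanAgeB,
                if (isTRUE(x$ageImbalance)) "  [age imbalance!]" else ""))
    invisible(x)
}

#' Cluster probes by genomic proximity
#'
#' Maximal runs of same-chromosome probes whose consecutive gaps are at most
#' \code{maxGap} nt (boundary inclusive); runs with fewer than
#' \code{minProbes} probes are discarded.
#'
#' @param manifest a named probe \code{GRanges} (sorted internally).
#' @param maxGap maximum distance between neighbouring cluster members in nt
#'   (default 1000).
#' @param minProbes minimum probes per cluster (default 3).
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{nProbes} and a list column \code{probeIds}
#'   (position-ordered).
#' @export
clusterProbes <- function(manifest, maxGap = 1000, minProbes = 3L) {
    if (length(manifest) == 0)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), nProbes = integer(0),
                          probeIds = I(list())))
    ord <- order(as.character(seqnames(manifest)), start(manifest))
    gr <- manifest[ord]
    chrom <- as.character(seqnames(gr))
    pos <- start(gr)
    newRun <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                      diff(pos) > maxGap)
    runId <- cumsum(newRun)
    keep <- table(runId) >= minProbes
    runs <- as.integer(names(keep)[keep])
    res <- lapply(runs, function(r) {
        i <- which(runId == r)
        data.frame(chrom = chrom[i[1]], start = pos[i[1]],
                   end = pos[i[length(i)]], nProbes = length(i),
                   probeIds = I(list(names(gr)[i])))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

# sample ids for one side of a design at the requested timepoints
designSamples <- function(pheno, subjects, timepoints) {
    rn <- rownames(pheno)
    rn[pheno$subjectId %in% subjects & pheno$timepoint %in% timepoints]
}

#' Call differentially methylated regions between two groups
#'
#' The full DMR workflow: probes are clustered by proximity
#' (\code{\link{clusterProbes}}), each cluster's group-difference signal is
#' binary-segmented into candidate regions (\code{\link{segmentCluster}}),
#' every candidate is tested with the two-dimensional Kolmogorov-Smirnov
#' permutation test on its (position, beta) point clouds
#' (\code{\link{ks2dPValue}}), deltaM is the difference of the group means of
#' per-probe mean betas, and Benjamini-Hochberg adjustment is applied across
#' all candidates. With \code{timepoints = c("T0", "T18")} both samples of
#' each subject enter the group's point cloud as replicates (doubling its
#' size, with no dependence correction — interpret with care).
#'
#' @param object a \linkS4class{MethylationExperiment} whose \code{colData}
#'   provides \code{subjectId} and \code{timepoint}.
#' @param design a \code{GroupDesign} from \code{\link{selectResponders}} (or
#'   a list with \code{groupA}/\code{groupB} subject ids).
#' @param timepoints timepoints entering the point clouds (default
#'   \code{c("T0", "T18")}, the combined-replicates mode).
#' @param maxGap,minProbes cluster geometry (defaults 1000 nt / 3 probes).
#' @param nPerm permutations per candidate (default 1000).
#' @param earlyStop passed to \code{\link{ks2dPValue}}: abort permutations for
#'   clearly-null candidates after this many exceedances (default 32; 0
#'   disables). Small p-values are unaffected.
#' @param seed RNG seed for the permutation tests.
#' @param scalePositions min-max scale positions within each region (default
#'   TRUE).
#' @return a \code{GRanges} of candidate regions sorted by adjusted p, with
#'   metadata columns \code{nProbes}, \code{deltaM} (group A - group B),
#'   \code{D}, \code{ks2dP} (conservative permutation p used for BH),
#'   \code{ks2dMidP} (tie-corrected mid-p for calibration diagnostics),
#'   \code{adjP}, \code{snpProbes}, \code{crossReactive}, \code{genes}
#'   (\code{CharacterList}) and \code{probeIds}.
#' @export
callDMRs <- function(object, design, timepoints = c("T0", "T18"),
                     maxGap = 1000, minProbes = 3L, nPerm = 1000,
                     earlyStop = 32L, seed = 1L, scalePositions = TRUE) {
    pheno <- as.data.frame(colData(object))
    sampA <- designSamples(pheno, design$groupA, timepoints)
    sampB <- designSamples(pheno, design$groupB, timepoints)
    if (!length(sampA) || !length(sampB))
        stop("design groups have no samples at the requested timepoints")
    set.seed(seed)
    b <- betaValues(object)
    manifest <- probeManifest(object)
    clusters <- clusterProbes(manifest, maxGap = maxGap,
                              minProbes = minProbes)
    mc <- S4Vectors::mcols(manifest)
    allPos <- start(manifest)
    snpFlag <- mc$snp
    crFlag <- mc$crossReactive
    geneList <- as.list(mc$genes)
    # resolve all probe ids to row indices in one pass
    nPer <- vapply(clusters$probeIds, length, integer(1))
    flatIdx <- match(unlist(clusters$probeIds), rownames(b))
    idxByCluster <- split(flatIdx, rep(seq_len(nrow(clusters)), nPer))
    colA <- match(sampA, colnames(b))
    colB <- match(sampB, colnames(b))
    grpVec <- c(rep(0L, length(colA)), rep(1L, length(colB)))
    recs <- list()
    for (ci in seq_len(nrow(clusters))) {
        pIdx <- idxByCluster[[ci]]
        bA <- b[pIdx, colA, drop = FALSE]
        bB <- b[pIdx, colB, drop = FALSE]
        d <- rowMeans(bA) - rowMeans(bB)
        segs <- segmentCluster(d, minProbes = minProbes)
        pos <- allPos[pIdx]
        for (si in seq_len(nrow(segs))) {
            idx <- segs$start[si]:segs$end[si]
            i <- pIdx[idx]
            kt <- ks2dPValue(cbind(bA[idx, , drop = FALSE],
                                   bB[idx, , drop = FALSE]),
                             pos[idx], grpVec,
                             method = "permutation", nPerm = nPerm,
                             scalePositions = scalePositions,
                             earlyStop = earlyStop)
            recs[[length(recs) + 1L]] <- list(
                chrom = clusters$chrom[ci],
                start = min(pos[idx]), end = max(pos[idx]),
                nProbes = length(idx), deltaM = segs$deltaM[si],
                ks2dP = kt$p, ks2dMidP = kt$midP, D = kt$D,
                snpProbes = sum(snpFlag[i]),
                crossReactive = sum(crFlag[i]),
                genes = sort(unique(unlist(geneList[i]))),
                probeIds = rownames(b)[i])
        }
    }
    if (!length(recs)) {
        gr <- GRanges()
        S4Vectors::mcols(gr) <- DataFrame(nProbes = integer(0),
            deltaM = numeric(0), ks2dP = numeric(0), adjP = numeric(0))
        return(gr)
    }
    gr <- GRanges(seqnames = vapply(recs, `[[`, character(1), "chrom"),
                  ranges = IRanges(
                      start = vapply(recs, `[[`, numeric(1), "start"),
                      end = vapply(recs, `[[`, numeric(1), "end")))
    S4Vectors::mcols(gr) <- DataFrame(
        nProbes = vapply(recs, `[[`, integer(1), "nProbes"),
        deltaM = vapply(recs, `[[`, numeric(1), "deltaM"),
        D = vapply(recs, `[[`, numeric(1), "D"),
        ks2dMidP = vapply(recs, `[[`, numeric(1), "ks2dMidP"),
        ks2dP = vapply(recs, `[[`, numeric(1), "ks2dP"),
        adjP = bhAdjust(vapply(recs, `[[`, numeric(1), "ks2dP")),
        snpProbes = vapply(recs, function(r) as.integer(r$snpProbes),
                           integer(1)),
        crossReactive = vapply(recs, function(r) as.integer(r$crossReactive),
                               integer(1)),
        genes = CharacterList(lapply(recs, `[[`, "genes")),
        probeIds = CharacterList(lapply(recs, `[[`, "probeIds")))
    gr[order(gr$adjP, gr$ks2dP)]
}

# vectorized one-sample t on rows; returns list(mean, t, p, flagged)
rowTTestOne <- function(d) {
    n <- ncol(d)
    m <- rowMeans(d)
    v <- (rowSums(d^2) - n * m^2) / (n - 1)
    v[v < 0] <- 0
    flagged <- v == 0
    t <- ifelse(flagged, 0, m / sqrt(v / n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
    p[flagged] <- 1
    list(estimate = m, statistic = t, p = p, flagged = flagged)
}

#' Single-CpG differential methylation tests
#'
#' Per-probe least-squares association of beta with the outcome: a two-level
#' outcome becomes a pooled-variance two-sample t-test (equivalent to OLS on
#' a group indicator), a numeric outcome a simple linear regression with the
#' t-test on its slope, and \code{paired = TRUE} a paired t-test on
#' within-subject (second minus first level) differences. Zero-variance
#' probes get p = 1 and are flagged. q-values are Benjamini-Hochberg across
#' probes.
#'
#' @param object a \linkS4class{MethylationExperiment} or beta matrix.
#' @param outcome per-sample outcome: factor/character with two levels, or
#'   numeric.
#' @param paired paired mode; requires \code{subject}.
#' @param subject per-sample subject ids for pairing.
#' @return \code{data.frame}: \code{probeId}, \code{estimate},
#'   \code{statistic}, \code{p}, \code{q}, \code{flagged}.
#' @export
dmpSingleCpG <- function(object, outcome, paired = FALSE, subject = NULL) {
    b <- if (is(object, "MethylationExperiment")) betaValues(object)
         else as.matrix(object)
    if (length(outcome) != ncol(b))
        stop("outcome length must equal the number of samples")
    if (paired) {
        if (is.null(subject)) stop("paired mode requires subject ids")
        g <- as.factor(outcome)
        if (nlevels(g) != 2) stop("paired mode requires a two-level outcome")
        s1 <- which(g == levels(g)[1]); s2 <- which(g == levels(g)[2])
        s2 <- s2[match(subject[s1], subject[s2])]
        if (anyNA(s2)) stop("unpaired subjects in paired mode")
        res <- rowTTestOne(b[, s2, drop = FALSE] - b[, s1, drop = FALSE])
    } else if (is.numeric(outcome)) {
        n <- ncol(b)
        y <- outcome - mean(outcome)
        sy <- sqrt(sum(y^2))
        m <- rowMeans(b)
        sx <- sqrt(rowSums(b^2) - n * m^2)
        flagged <- sx == 0 | sy == 0
        r <- ifelse(flagged, 0, as.numeric(b %*% y) / (sx * sy))
        r <- pmin(1, pmax(-1, r))
        t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
        p <- 2 * stats::pt(-abs(t), df = n - 2)
        p[flagged] <- 1
        res <- list(estimate = ifelse(flagged, 0, r * sy / pmax(sx, 1e-300)),
                    statistic = t, p = p, flagged = flagged)
    } else {
        g <- as.factor(outcome)
        if (nlevels(g) != 2) stop("outcome must have exactly two levels")
        i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
        n1 <- sum(i1); n2 <- sum(i2)
        m1 <- rowMeans(b[, i1, drop = FALSE])
        m2 <- rowMeans(b[, i2, drop = FALSE])
        ss1 <- rowSums(b[, i1, drop = FALSE]^2) - n1 * m1^2
        ss2 <- rowSums(b[, i2, drop = FALSE]^2) - n2 * m2^2
        sp2 <- (pmax(ss1, 0) + pmax(ss2, 0)) / (n1 + n2 - 2)
        flagged <- sp2 <= 0
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        t <- ifelse(flagged, 0, (m2 - m1) / se)
        p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
        p[flagged] <- 1
        res <- list(estimate = m2 - m1, statistic = t, p = p,
                    flagged = flagged)
    }
    data.frame(probeId = rownames(b), estimate = res$estimate,
               statistic = res$statistic, p = res$p, q = bhAdjust(res$p),
               flagged = res$flagged, row.names = NULL)
}
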