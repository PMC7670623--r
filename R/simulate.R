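#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' Defaults emulate the study conditions of an 18-month lifestyle-intervention
#' methylation cohort: 120 subjects (90\% male) measured at baseline (T0) and
#' 18 months (T18), mean relative weight change -4.04\% (SD 5.76\%, i.e.
#' -3.65 +/- 5.2 kg on a 90.3 kg baseline), extreme tails of 10 male
#' responders (~ -16\%) and 10 male non-responders (~ +2.4\%), gap-clustered
#' array probes, and a six-population leukocyte mixture with
#' neutrophil-dominated Dirichlet composition.
#'
#' @param nSubjects number of subjects (each contributes a T0 and a T18
#'   sample).
#' @param maleFraction proportion of male subjects in \eqn{[0,1]}.
#' @param nProbes number of array probes.
#' @param nChromosomes chromosomes the probes are spread over.
#' @param intraClusterSpacing mean spacing (nt) between neighbouring probes
#'   inside a CpG cluster; kept \eqn{\le} 1000 so planted clusters satisfy the
#'   DMR geometry rule (\eqn{\ge} 3 CpGs, gaps \eqn{\le} 1000 nt).
#' @param interClusterSpacing mean gap (nt) between consecutive clusters;
#'   always > 1000 so clusters never merge.
#' @param singletonFraction fraction of probes emitted as isolated singletons
#'   rather than cluster members.
#' @param clusterSizeRange integer range of cluster sizes (min \eqn{\ge} 3).
#' @param nPlantedDmrs number of clusters that receive a planted
#'   responder/non-responder methylation difference.
#' @param plantedDeltaM signed beta-scale group difference planted in DMRs
#'   (responder minus non-responder); signs alternate across planted regions.
#'   Default matches the strongest reported region-level effect (0.126).
#' @param dmrWidthProbes probes per planted DMR (\eqn{\ge} 3).
#' @param nPlantedEwasCpgs number of isolated CpGs whose baseline methylation
#'   is correlated with relative weight change.
#' @param plantedR target Pearson correlation of planted CpGs with relative
#'   weight change; signs alternate. Default matches the strongest reported
#'   single-CpG effect (0.42).
#' @param weightChangeMeanPct,weightChangeSdPct normal distribution of
#'   relative weight change (\%) for non-tail subjects; the default SD of
#'   4.6 makes the full cohort including the planted tails reproduce the
#'   reported overall spread (about 5.2 kg on a 90.3 kg baseline).
#' @param responderMeanPct,nonResponderMeanPct,tailSdPct means/SD (\%) of the
#'   planted responder and non-responder tails.
#' @param nTail subjects per tail (male only); 0 disables tails.
#' @param cellTypes character labels of the mixed cell populations.
#' @param dirichletAlpha positive Dirichlet concentration per cell type.
#' @param nMarkerProbes probes carrying cell-type-specific signal (0 disables
#'   the mixture structure).
#' @param noiseSd SD of Gaussian measurement noise added on the logit scale
#'   (0.12 on the logit scale is roughly 0.03 on the beta scale at
#'   mid-methylation).
#' @param detectionFailFraction fraction of probes designated as failing;
#' @param detectionFailRate per-sample failure probability on those probes
#'   (detection p drawn above 0.01).
#' @param seed integer RNG seed; identical configurations reproduce all
#'   outputs exactly.
#'
#' @return a validated list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(nSubjects = 10, nProbes = 200, nTail = 0, seed = 7)
#' @export
simConfig <- function(nSubjects = 120L,
                      maleFraction = 0.9,
                      nProbes = 10000L,
                      nChromosomes = 6L,
                      intraClusterSpacing = 100,
                      interClusterSpacing = 5000,
                      singletonFraction = 0.3,
                      clusterSizeRange = c(3L, 8L),
                      nPlantedDmrs = 0L,
                      plantedDeltaM = 0.126,
                      dmrWidthProbes = 5L,
                      nPlantedEwasCpgs = 0L,
                      plantedR = 0.42,
                      weightChangeMeanPct = -4.04,
                      weightChangeSdPct = 4.6,
                      responderMeanPct = -16,
                      nonResponderMeanPct = 2.4,
                      tailSdPct = 1.5,
                      nTail = 10L,
                      cellTypes = c("CD4T", "CD8T", "NK", "Bcell",
                                    "Mono", "Neu"),
                      dirichletAlpha = c(5, 2.5, 1.5, 1.5, 2.5, 17),
                      nMarkerProbes = 600L,
                      noiseSd = 0.12,
                      detectionFailFraction = 0.01,
                      detectionFailRate = 0.05,
                      seed = 1L) {
    cfg <- list(nSubjects = as.integer(nSubjects),
                maleFraction = maleFraction,
                nProbes = as.integer(nProbes),
                nChromosomes = as.integer(nChromosomes),
                intraClusterSpacing = intraClusterSpacing,
                interClusterSpacing = interClusterSpacing,
                singletonFraction = singletonFraction,
                clusterSizeRange = as.integer(clusterSizeRange),
                nPlantedDmrs = as.integer(nPlantedDmrs),
                plantedDeltaM = plantedDeltaM,
                dmrWidthProbes = as.integer(dmrWidthProbes),
                nPlantedEwasCpgs = as.integer(nPlantedEwasCpgs),
                plantedR = plantedR,
                weightChangeMeanPct = weightChangeMeanPct,
                weightChangeSdPct = weightChangeSdPct,
                responderMeanPct = responderMeanPct,
                nonResponderMeanPct = nonResponderMeanPct,
                tailSdPct = tailSdPct,
                nTail = as.integer(nTail),
                cellTypes = as.character(cellTypes),
                dirichletAlpha = dirichletAlpha,
                nMarkerProbes = as.integer(nMarkerProbes),
                noiseSd = noiseSd,
                detectionFailFraction = detectionFailFraction,
                detectionFailRate = detectionFailRate,
                seed = as.integer(seed))
    counts <- c("nSubjects", "nProbes", "nChromosomes", "nPlantedDmrs",
                "nPlantedEwasCpgs", "nTail", "nMarkerProbes")
    for (f in counts)
        if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
            stop("invalid config: ", f, " must be a non-negative count")
    if (cfg$maleFraction < 0 || cfg$maleFraction > 1)
        stop("invalid config: maleFraction must lie in [0, 1]")
    if (abs(cfg$plantedDeltaM) >= 1)
        stop("invalid config: plantedDeltaM must lie in (-1, 1)")
    if (abs(cfg$plantedR) >= 1)
        stop("invalid config: |plantedR| must be < 1")
    if (cfg$dmrWidthProbes < 3L)
        stop("invalid config: dmrWidthProbes must be >= 3")
    if (cfg$clusterSizeRange[1] < 3L)
        stop("invalid config: minimum cluster size must be >= 3")
    if (length(cfg$dirichletAlpha) != length(cfg$cellTypes) ||
        any(cfg$dirichletAlpha <= 0))
        stop("invalid config: dirichletAlpha must be positive, one per cell type")
    if (cfg$noiseSd < 0 || cfg$weightChangeSdPct < 0)
        stop("invalid config: SDs must be non-negative")
    if (cfg$detectionFailFraction < 0 || cfg$detectionFailFraction > 1 ||
        cfg$detectionFailRate < 0 || cfg$detectionFailRate > 1)
        stop("invalid config: detection failure parameters must lie in [0, 1]")
    class(cfg) <- "SimConfig"
    cfg
}

#' Simulate a probe manifest
#'
#' Lays gap-clustered CpG probes along chromosomes: runs of
#' \code{clusterSizeRange} probes with intra-cluster spacings \eqn{\le} 1000 nt
#' (mean \code{intraClusterSpacing}), separated by inter-cluster gaps > 1000 nt,
#' interspersed with isolated singleton probes. A fraction of probes carries
#' cross-reactive or SNP flags and cluster-level gene annotations.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return a \code{GRanges} named by probe id, sorted by (chromosome,
#'   position), with metadata columns \code{crossReactive}, \code{snp},
#'   \code{genes} (\code{CharacterList}) and \code{clusterId} (NA for
#'   singletons).
#' @examples
#' man <- simulateManifest(simConfig(nProbes = 100, seed = 3))
#' @export
simulateManifest <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    n <- config$nProbes
    if (n == 0L)
        return(GRanges(seqnames = character(0),
                       ranges = IRanges(start = integer(0), width = integer(0))))
    set.seed(config$seed)
    sizes <- integer(0)
    total <- 0L
    while (total < n) {
        s <- if (stats::runif(1) < config$singletonFraction) 1L
             else sample(seq(config$clusterSizeRange[1],
                             config$clusterSizeRange[2]), 1L)
        s <- min(s, n - total)
        sizes <- c(sizes, s)
        total <- total + s
    }
    nClust <- length(sizes)
    chromOf <- sort(rep_len(seq_len(config$nChromosomes), nClust))
    chrom <- integer(0); pos <- integer(0); clusterId <- integer(0)
    geneOf <- character(0)
    cid <- 0L
    for (ch in seq_len(config$nChromosomes)) {
        idx <- which(chromOf == ch)
        cur <- 10000L
        for (k in idx) {
            cid <- cid + 1L
            gaps <- if (sizes[k] > 1L)
                pmin(1000, pmax(2, round(stats::rexp(sizes[k] - 1L,
                    1 / config$intraClusterSpacing))))
            else numeric(0)
            p <- cur + cumsum(c(0, gaps))
            chrom <- c(chrom, rep(ch, sizes[k]))
            pos <- c(pos, p)
            clusterId <- c(clusterId,
                           rep(if (sizes[k] >= 3L) cid else NA_integer_,
                               sizes[k]))
            gene <- if (stats::runif(1) < 0.7)
                sprintf("GENE%d_%d", ch, cid) else ""
            geneOf <- c(geneOf, rep(gene, sizes[k]))
            cur <- p[length(p)] +
                max(1001, round(stats::rexp(1, 1 / config$interClusterSpacing)))
        }
    }
    ids <- sprintf("cg%08d", seq_len(n))
    gr <- GRanges(seqnames = paste0("chr", chrom),
                  ranges = IRanges(start = pos, width = 1L))
    names(gr) <- ids
    S4Vectors::mcols(gr)$crossReactive <- stats::runif(n) < 0.02
    S4Vectors::mcols(gr)$snp <- stats::runif(n) < 0.03
    S4Vectors::mcols(gr)$genes <- CharacterList(
        lapply(geneOf, function(g) if (nzchar(g)) g else character(0)))
    S4Vectors::mcols(gr)$clusterId <- clusterId
    gr
}

#' Simulate a cohort phenotype table
#'
#' Draws per-subject sex, age, BMI, baseline weight and intervention arm, and
#' a relative weight-change trajectory. When \code{nTail > 0}, that many male
#' subjects are planted as extreme responders (mean \code{responderMeanPct})
#' and as non-responders (mean \code{nonResponderMeanPct}); all remaining
#' subjects draw from \code{N(weightChangeMeanPct, weightChangeSdPct^2)}.
#'
#' @param config a \code{\link{simConfig}} object with \code{nSubjects >= 2}.
#' @return a \code{data.frame} with one row per sample (two per subject,
#'   rownames \code{<subject>_T0} / \code{<subject>_T18}) and columns
#'   \code{subjectId}, \code{timepoint}, \code{sex}, \code{age}, \code{bmi},
#'   \code{arm}, \code{weightT0}, \code{weightT6}, \code{weightT18},
#'   \code{responderLabel} (\code{"responder"}, \code{"non_responder"} or
#'   \code{"neither"}), plus long-format \code{weight} and \code{bmiAt}
#'   (the values at that row's timepoint).
#' @examples
#' pheno <- simulateCohort(simConfig(nSubjects = 20, nTail = 5, seed = 2))
#' table(pheno$responderLabel) / 2
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    n <- config$nSubjects
    if (n < 2L) stop("nSubjects must be >= 2")
    set.seed(config$seed + 1L)
    subj <- sprintf("S%03d", seq_len(n))
    nMale <- round(config$maleFraction * n)
    sex <- sample(c(rep("male", nMale), rep("female", n - nMale)))
    age <- round(pmin(70, pmax(25, stats::rnorm(n, 49, 9.3))))
    bmi <- round(pmin(45, pmax(22, stats::rnorm(n, 30.2, 3.3))), 1)
    weightT0 <- round(pmin(130, pmax(60, stats::rnorm(n, 90.3, 11.5))), 2)
    arm <- sample(rep_len(c("LF", "LF+PA", "MED/LC", "MED/LC+PA"), n))
    pct <- stats::rnorm(n, config$weightChangeMeanPct, config$weightChangeSdPct)
    label <- rep("neither", n)
    if (config$nTail > 0L) {
        males <- which(sex == "male")
        if (length(males) < 2L * config$nTail)
            stop("not enough male subjects for the configured tails")
        picks <- sampleVec(males, 2L * config$nTail)
        resp <- picks[seq_len(config$nTail)]
        nonresp <- picks[config$nTail + seq_len(config$nTail)]
        pct[resp] <- stats::rnorm(config$nTail, config$responderMeanPct,
                                  config$tailSdPct)
        pct[nonresp] <- stats::rnorm(config$nTail, config$nonResponderMeanPct,
                                     config$tailSdPct)
        label[resp] <- "responder"
        label[nonresp] <- "non_responder"
    }
    weightT18 <- round(weightT0 * (1 + pct / 100), 2)
    # both tails lose weight during the first 6 months before diverging
    pct6 <- 0.5 * pct - 3 + stats::rnorm(n, 0, 1)
    weightT6 <- round(weightT0 * (1 + pct6 / 100), 2)
    if (config$nTail > 0L) {
        # responder status is defined by the realized ranking (as in the
        # study design: the observed extremes are the responder groups),
        # using the same rounded weights and tie rule the selection uses
        change <- 100 * (weightT18 - weightT0) / weightT0
        males <- which(sex == "male")
        ordAsc <- males[order(change[males], subj[males])]
        ordDesc <- males[order(-change[males], subj[males])]
        label <- rep("neither", n)
        label[ordAsc[seq_len(config$nTail)]] <- "responder"
        label[ordDesc[seq_len(config$nTail)]] <- "non_responder"
    }
    one <- data.frame(subjectId = subj, sex = sex, age = age, bmi = bmi,
                      arm = arm, weightT0 = weightT0, weightT6 = weightT6,
                      weightT18 = weightT18, responderLabel = label,
                      stringsAsFactors = FALSE)
    pheno <- rbind(cbind(one, timepoint = "T0"),
                   cbind(one, timepoint = "T18"))
    pheno <- pheno[order(pheno$subjectId, pheno$timepoint), ]
    rownames(pheno) <- paste(pheno$subjectId, pheno$timepoint, sep = "_")
    # long-format trait values (the measurement at that row's timepoint),
    # used by the paired T0-vs-T18 change tests
    atT18 <- pheno$timepoint == "T18"
    pheno$weight <- ifelse(atT18, pheno$weightT18, pheno$weightT0)
    pheno$bmiAt <- round(ifelse(atT18,
                                pheno$bmi * pheno$weightT18 / pheno$weightT0,
                                pheno$bmi), 2)
    pheno
}

# samples x cellTypes Dirichlet draw
rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                nrow = n, byrow = TRUE)
    g / rowSums(g)
}

#' Simulate a cell-type methylation reference
#'
#' Generates well-separated marker profiles: every marker probe is randomly
#' hypo- (~0.15) or hyper-methylated (~0.85) in each cell type, giving a
#' pairwise mean absolute profile difference of about 0.35, which makes the
#' mixture identifiable by construction.
#'
#' @param manifest probe manifest (\code{GRanges}) the markers are drawn from.
#' @param config a \code{\link{simConfig}} object.
#' @return a \code{\link{CellReference}} over \code{nMarkerProbes} probes.
#' @export
simulateCellReference <- function(manifest, config) {
    stopifnot(inherits(config, "SimConfig"))
    nm <- min(config$nMarkerProbes, length(manifest))
    if (nm == 0L) return(NULL)
    set.seed(config$seed + 2L)
    markers <- sort(sample(length(manifest), nm))
    k <- length(config$cellTypes)
    high <- matrix(stats::runif(nm * k) < 0.5, nm, k)
    prof <- 0.15 + 0.7 * high + matrix(stats::rnorm(nm * k, 0, 0.02), nm, k)
    prof <- clip01(prof)
    dimnames(prof) <- list(names(manifest)[markers], config$cellTypes)
    CellReference(prof)
}

#' Simulate beta and detection p-value matrices with planted truth
#'
#' Builds per-sample methylation as a cell-type mixture of reference profiles
#' (marker probes) or a shared base level (other probes), plants
#' responder/non-responder DMR differences and weight-change-correlated
#' baseline CpGs, then adds Gaussian noise on the logit scale and transforms
#' back so all values stay in (0, 1). Weight-correlated CpGs are planted by
#' adding \eqn{c \cdot z} (standardized relative weight change) on the logit
#' scale with \eqn{c = \sigma \rho / \sqrt{1 - \rho^2}}, which hits the target
#' correlation \eqn{\rho} in closed form given the noise SD \eqn{\sigma}.
#'
#' @param manifest probe manifest from \code{\link{simulateManifest}}.
#' @param cohort phenotype table from \code{\link{simulateCohort}}.
#' @param config a \code{\link{simConfig}} object.
#' @param reference optional \code{\link{CellReference}}; generated from
#'   \code{config} when \code{NULL} and \code{nMarkerProbes > 0}.
#' @return a list with elements \code{experiment} (a
#'   \linkS4class{MethylationExperiment} with \code{beta} and
#'   \code{detectionP} assays), \code{truth} (planted DMRs, planted EWAS
#'   CpGs, true cell proportions, responder labels) and \code{reference}.
#' @examples
#' cfg <- simConfig(nSubjects = 8, nProbes = 120, nMarkerProbes = 40,
#'                  nTail = 2, seed = 5)
#' sim <- simulateBeta(simulateManifest(cfg), simulateCohort(cfg), cfg)
#' range(betaValues(sim$experiment))
#' @export
simulateBeta <- function(manifest, cohort, config, reference = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    if (length(manifest) == 0L || nrow(cohort) == 0L)
        stop("manifest and cohort must be non-empty")
    if (is.null(reference) && config$nMarkerProbes > 0L)
        reference <- simulateCellReference(manifest, config)
    set.seed(config$seed + 3L)
    n <- length(manifest)
    samples <- rownames(cohort)
    ns <- length(samples)
    ids <- names(manifest)

    # base methylation level: bimodal like real array data
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
    mu <- numeric(n)
    mu[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 10)
    mu[comp == 2] <- stats::rbeta(sum(comp == 2), 10, 2)
    mu[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)

    # mean matrix per probe x sample
    props <- rdirichlet(ns, config$dirichletAlpha)
    dimnames(props) <- list(samples, config$cellTypes)
    M <- matrix(mu, n, ns, dimnames = list(ids, samples))
    markerIdx <- integer(0)
    if (!is.null(reference)) {
        markerIdx <- match(rownames(referenceProfile(reference)), ids)
        M[markerIdx, ] <- referenceProfile(reference) %*% t(props)
    }

    subjOf <- cohort$subjectId
    respLabel <- cohort$responderLabel[!duplicated(subjOf)]
    names(respLabel) <- subjOf[!duplicated(subjOf)]
    respSamples <- samples[cohort$responderLabel == "responder"]

    # planted DMRs: shift responder samples (both timepoints) by deltaM
    plantedDmrs <- NULL
    usedProbes <- integer(0)
    if (config$nPlantedDmrs > 0L) {
        cl <- S4Vectors::mcols(manifest)$clusterId
        tab <- table(cl[!is.na(cl) & !(seq_len(n) %in% markerIdx)])
        eligible <- as.integer(names(tab)[tab >= config$dmrWidthProbes])
        if (length(eligible) < config$nPlantedDmrs)
            stop("not enough clusters of width ", config$dmrWidthProbes,
                 " to plant ", config$nPlantedDmrs, " DMRs")
        chosen <- sort(sampleVec(eligible, config$nPlantedDmrs))
        recs <- vector("list", length(chosen))
        for (k in seq_along(chosen)) {
            probes <- which(!is.na(cl) & cl == chosen[k])
            probes <- probes[seq_len(config$dmrWidthProbes)]
            usedProbes <- c(usedProbes, probes)
            dm <- config$plantedDeltaM * (-1)^(k + 1)
            # keep base level mid-range so the shift stays inside (0,1)
            base <- stats::runif(length(probes), 0.35, 0.55)
            M[probes, ] <- base
            M[probes, respSamples] <- clip01(base + dm)
            recs[[k]] <- data.frame(
                chrom = as.character(seqnames(manifest))[probes[1]],
                start = min(start(manifest)[probes]),
                end = max(start(manifest)[probes]),
                nProbes = length(probes), deltaM = dm,
                probeIds = I(list(ids[probes])))
        }
        plantedDmrs <- do.call(rbind, recs)
    }

    # planted EWAS CpGs: baseline methylation correlated with weight change
    plantedEwas <- NULL
    if (config$nPlantedEwasCpgs > 0L) {
        free <- setdiff(seq_len(n), c(markerIdx, usedProbes))
        if (length(free) < config$nPlantedEwasCpgs)
            stop("not enough free probes to plant EWAS CpGs")
        probes <- sort(sampleVec(free, config$nPlantedEwasCpgs))
        pct <- 100 * (cohort$weightT18 - cohort$weightT0) / cohort$weightT0
        z <- as.numeric(scale(pct[match(unique(subjOf), subjOf)]))
        names(z) <- unique(subjOf)
        sigma <- max(config$noiseSd, 1e-6)
        rs <- config$plantedR * (-1)^(seq_along(probes) + 1)
        base <- stats::runif(length(probes), 0.3, 0.7)
        for (k in seq_along(probes)) {
            cc <- sigma * rs[k] / sqrt(1 - rs[k]^2)
            M[probes[k], ] <- invlogit(logit(squeezeBeta(base[k])) +
                                       cc * z[subjOf])
        }
        plantedEwas <- data.frame(probeId = ids[probes], trueR = rs,
                                  sign = ifelse(rs >= 0, "positive",
                                                "negative"))
    }

    # measurement noise on the logit scale keeps betas inside (0,1)
    if (config$noiseSd > 0) {
        eps <- matrix(stats::rnorm(n * ns, 0, config$noiseSd), n, ns)
        beta <- invlogit(logit(squeezeBeta(M)) + eps)
    } else beta <- squeezeBeta(M)
    dimnames(beta) <- list(ids, samples)

    detp <- matrix(stats::runif(n * ns, 0, 0.005), n, ns,
                   dimnames = list(ids, samples))
    nBad <- round(config$detectionFailFraction * n)
    badProbes <- if (nBad > 0) sort(sample(setdiff(seq_len(n), usedProbes),
                                           min(nBad, n))) else integer(0)
    if (length(badProbes)) {
        fail <- matrix(stats::runif(length(badProbes) * ns) <
                       config$detectionFailRate, length(badProbes), ns)
        detp[badProbes, ][fail] <- stats::runif(sum(fail), 0.02, 0.6)
    }

    truth <- list(plantedDmrs = plantedDmrs,
                  plantedEwasCpgs = plantedEwas,
                  trueCellProportions = props,
                  responderLabels = respLabel,
                  badProbes = ids[badProbes])
    stopifnot(max(abs(rowSums(props) - 1)) < 1e-9)
    exper <- MethylationExperiment(beta, manifest, colData = cohort,
                                   detectionP = detp)
    list(experiment = exper, truth = truth, reference = reference)
}

#' One-call cohort simulation
#'
#' Convenience wrapper running \code{\link{simulateManifest}},
#' \code{\link{simulateCohort}} and \code{\link{simulateBeta}} from one
#' configuration.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with \code{experiment}, \code{truth}, \code{reference},
#'   \code{manifest}, \code{cohort}.
#' @examples
#' sim <- simulateMethylation(
#'     simConfig(nSubjects = 6, nProbes = 80, nTail = 0, seed = 1))
#' dim(betaValues(sim$experiment))
#' @export
simulateMethylation <- function(config) {
    manifest <- simulateManifest(config)
    cohort <- simulateCohort(config)
    out <- simulateBeta(manifest, cohort, config)
    out$manifest <- manifest
    out$cohort <- cohort
    out
}
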