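#' Relative weight change per subject
#'
#' \eqn{(w_{T18} - w_{T0}) / w_{T0} \times 100}; negative values are weight
#' loss.
#'
#' @param pheno per-sample (or per-subject) phenotype data with
#'   \code{subjectId}, \code{weightT0}, \code{weightT18}.
#' @return \code{data.frame} with \code{subjectId} and
#'   \code{relativeChangePct}.
#' @examples
#' relativeWeightChange(data.frame(subjectId = "S1", weightT0 = 100,
#'                                 weightT18 = 84))  # -16
#' @export
relativeWeightChange <- function(pheno) {
    pheno <- as.data.frame(pheno)
    sub <- pheno[!duplicated(pheno$subjectId), ]
    bad <- sub$subjectId[is.na(sub$weightT0) | is.na(sub$weightT18)]
    if (length(bad))
        stop("missing T0/T18 weight for subject(s): ",
             paste(bad, collapse = ", "))
    if (any(sub$weightT0 <= 0))
        stop("weightT0 must be positive")
    data.frame(subjectId = sub$subjectId,
               relativeChangePct =
                   100 * (sub$weightT18 - sub$weightT0) / sub$weightT0,
               row.names = NULL)
}

# Spearman correlation with average ranks; exact p (via cor.test) for
# n <= 9 without ties, t-approximation otherwise
spearmanPT <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    hasTies <- anyDuplicated(x) || anyDuplicated(y)
    if (n <= 9 && !hasTies) {
        p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    } else {
        t <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
        p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    list(rho = rho, p = min(p, 1))
}

#' Combined Pearson/Spearman correlation
#'
#' Computes both correlation coefficients with two-sided p-values, a combined
#' p as the geometric mean \eqn{\sqrt{p_{pearson} \cdot p_{spearman}}}
#' (evaluated in log space to avoid underflow), and a combined correlation as
#' the arithmetic mean of r and rho; discordant signs are flagged, not
#' dropped. Pearson p uses the t transform with n-2 df; Spearman p is exact
#' for n \eqn{\le} 9 without ties and t-approximated otherwise.
#'
#' @param x,y finite, non-constant numeric vectors of equal length
#'   \eqn{\ge 4}.
#' @return list: \code{pearsonR}, \code{pearsonP}, \code{spearmanRho},
#'   \code{spearmanP}, \code{combinedP}, \code{combinedR},
#'   \code{signConcordant}.
#' @examples
#' cc <- combinedCorrelation(1:10, (1:10) * 2 + 1)
#' cc$combinedR  # 1
#' @export
combinedCorrelation <- function(x, y) {
    if (length(x) != length(y) || length(x) < 4)
        stop("x and y must have equal length >= 4")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("x and y must be finite")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: constant vector")
    n <- length(x)
    r <- stats::cor(x, y)
    t <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    pp <- min(2 * stats::pt(-abs(t), df = n - 2), 1)
    sp <- spearmanPT(x, y)
    combP <- combinePValues(c(pp, sp$p))
    list(pearsonR = r, pearsonP = pp, spearmanRho = sp$rho,
         spearmanP = sp$p, combinedP = combP,
         combinedR = mean(c(r, sp$rho)),
         signConcordant = sign(r) == sign(sp$rho))
}

#' Combine p-values by geometric mean
#'
#' \eqn{(\prod_i p_i)^{1/n}}, evaluated in log space so values below
#' 1e-300 do not underflow. The result always lies between the smallest and
#' largest input.
#'
#' @param p numeric vector of p-values in \eqn{[0,1]}.
#' @return the geometric mean.
#' @examples
#' combinePValues(c(0.04, 0.09))  # 0.06
#' @export
combinePValues <- function(p) {
    stopIfNot01(p, "p-values")
    if (any(p == 0)) return(0)
    exp(mean(log(p)))
}

#' Epigenome-wide association of baseline methylation with weight change
#'
#' For every probe, correlates baseline (one sample per subject) methylation
#' with relative weight change using Pearson and Spearman jointly (see
#' \code{\link{combinedCorrelation}}). Probes are reported sorted by combined
#' p with threshold-tier memberships, SNP/cross-reactive flags and gene
#' annotation propagated from the manifest. Constant probes are flagged and
#' assigned p = 1.
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param weightChange optional \code{data.frame} from
#'   \code{\link{relativeWeightChange}}; computed from \code{colData} when
#'   \code{NULL}.
#' @param timepoint which timepoint's samples are "baseline" (default
#'   \code{"T0"}).
#' @param thresholds combined-p tiers reported as indicator columns
#'   (default 1e-3, 1e-4, 0.01).
#' @return \code{data.frame} sorted by \code{combinedP}: probe id, location,
#'   both correlations with p-values, \code{combinedP}, \code{combinedR},
#'   sign concordance, flags, genes, and one logical \code{p_lt_*} column per
#'   threshold.
#' @export
ewasScan <- function(object, weightChange = NULL, timepoint = "T0",
                     thresholds = c(1e-3, 1e-4, 0.01)) {
    pheno <- as.data.frame(colData(object))
    samples <- rownames(pheno)[pheno$timepoint == timepoint]
    if (anyDuplicated(pheno$subjectId[rownames(pheno) %in% samples]))
        stop("design error: more than one baseline sample per subject")
    if (is.null(weightChange)) weightChange <- relativeWeightChange(pheno)
    subjOf <- pheno[samples, "subjectId"]
    wc <- weightChange$relativeChangePct[match(subjOf,
                                               weightChange$subjectId)]
    if (anyNA(wc))
        stop("design error: weight change missing for some baseline samples")
    b <- betaValues(object)[, samples, drop = FALSE]
    n <- ncol(b)
    if (n < 4) stop("need at least 4 baseline samples")

    pearson <- rowCorT(b, wc)
    ranks <- t(apply(b, 1, rank))
    spearman <- rowCorT(ranks, rank(wc))
    flagged <- pearson$flagged | spearman$flagged
    pp <- ifelse(flagged, 1, pearson$p)
    sp <- ifelse(flagged, 1, spearman$p)
    combP <- ifelse(pp == 0 | sp == 0, 0, exp(0.5 * (log(pp) + log(sp))))
    manifest <- probeManifest(object)
    mc <- S4Vectors::mcols(manifest)
    out <- data.frame(
        probeId = rownames(b),
        chrom = as.character(seqnames(manifest)),
        pos = start(manifest),
        pearsonR = pearson$r, pearsonP = pp,
        spearmanRho = spearman$r, spearmanP = sp,
        combinedP = combP,
        combinedR = (pearson$r + spearman$r) / 2,
        signConcordant = sign(pearson$r) == sign(spearman$r),
        flagged = flagged,
        snp = mc$snp, crossReactive = mc$crossReactive,
        genes = vapply(mc$genes, paste, character(1), collapse = ","),
        row.names = NULL)
    for (th in thresholds)
        out[[paste0("p_lt_", format(th))]] <- out$combinedP < th
    out[order(out$combinedP, out$probeId), ]
}

# vectorized Pearson correlation of matrix rows against one vector,
# with the t-transform p-value (n-2 df)
rowCorT <- function(b, y) {
    n <- length(y)
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2))
    m <- rowMeans(b)
    sx <- sqrt(pmax(rowSums(b^2) - n * m^2, 0))
    flagged <- sx < 1e-12 | sy < 1e-12
    r <- ifelse(flagged, 0,
                as.numeric(b %*% yc) / (pmax(sx, 1e-300) * max(sy, 1e-300)))
    r <- pmin(1, pmax(-1, r))
    t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- pmin(2 * stats::pt(-abs(t), df = n - 2), 1)
    p[flagged] <- 1
    list(r = r, p = p, flagged = flagged)
}

#' Correlate candidate-probe methylation with clinical phenotypes
#'
#' Combined Pearson/Spearman association of each candidate probe against
#' each continuous trait: trait levels at each timepoint against the
#' methylation of that timepoint's samples, and trait change (T18 - T0)
#' against baseline methylation. Benjamini-Hochberg adjustment is applied
#' across the whole table. Trait/timepoint combinations with fewer than 4
#' non-missing values are skipped with a warning.
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param traits character vector of \code{colData} columns holding
#'   per-sample continuous trait values (long format: the value at that
#'   row's timepoint).
#' @param probeSet probe ids to test (must exist in the experiment).
#' @param timepoints the two timepoints, baseline first.
#' @return \code{data.frame}: probe, trait, analysis
#'   (\code{level_T0} / \code{level_T18} / \code{change}), both correlations,
#'   \code{combinedP}, \code{combinedR}, \code{q}.
#' @export
phenotypeCorrelations <- function(object, traits, probeSet,
                                  timepoints = c("T0", "T18")) {
    if (!length(probeSet))
        return(data.frame(probeId = character(0), trait = character(0),
                          analysis = character(0), combinedP = numeric(0),
                          combinedR = numeric(0), q = numeric(0)))
    if (!all(probeSet %in% rownames(object)))
        stop("probeSet contains unknown probes")
    pheno <- as.data.frame(colData(object))
    b <- betaValues(object)
    s0 <- rownames(pheno)[pheno$timepoint == timepoints[1]]
    s1 <- rownames(pheno)[pheno$timepoint == timepoints[2]]
    s1 <- s1[match(pheno[s0, "subjectId"], pheno[s1, "subjectId"])]
    rows <- list()
    for (tr in traits) {
        v0 <- pheno[s0, tr]; v1 <- pheno[s1, tr]
        tasks <- list(level_T0 = list(x = s0, y = v0),
                      level_T18 = list(x = s1, y = v1),
                      change = list(x = s0, y = v1 - v0))
        for (an in names(tasks)) {
            y <- tasks[[an]]$y
            ok <- !is.na(y) & !is.na(tasks[[an]]$x)
            if (sum(ok) < 4) {
                warning("skipping ", tr, " (", an, "): fewer than 4 values")
                next
            }
            for (pr in probeSet) {
                x <- b[pr, tasks[[an]]$x[ok]]
                if (stats::sd(x) == 0 || stats::sd(y[ok]) == 0) next
                cc <- combinedCorrelation(x, y[ok])
                rows[[length(rows) + 1L]] <- data.frame(
                    probeId = pr, trait = tr, analysis = an,
                    pearsonR = cc$pearsonR, spearmanRho = cc$spearmanRho,
                    combinedP = cc$combinedP, combinedR = cc$combinedR)
            }
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(out)
    out$q <- bhAdjust(out$combinedP)
    rownames(out) <- NULL
    out
}

#' Paired T0 vs T18 change tests for clinical traits
#'
#' Per trait: mean and SD at each timepoint, the mean within-subject change,
#' and the paired t-test on T18 - T0 differences. Subjects missing either
#' timepoint are excluded (their count reported). A degenerate non-zero
#' constant shift (zero variance of differences) is reported as p = 0 with a
#' flag; an all-zero change gives t = 0, p = 1.
#'
#' @param pheno per-sample phenotype data with \code{subjectId},
#'   \code{timepoint} and the trait columns in long format.
#' @param traits character vector of trait column names.
#' @param timepoints the two timepoints, baseline first.
#' @return \code{data.frame} with one row per trait.
#' @export
pairedChangeTests <- function(pheno, traits, timepoints = c("T0", "T18")) {
    pheno <- as.data.frame(pheno)
    subj <- unique(pheno$subjectId)
    key <- paste(pheno$subjectId, pheno$timepoint)
    i0 <- match(paste(subj, timepoints[1]), key)
    i1 <- match(paste(subj, timepoints[2]), key)
    res <- lapply(traits, function(tr) {
        v0 <- pheno[i0, tr]; v1 <- pheno[i1, tr]
        ok <- !is.na(v0) & !is.na(v1)
        nExcluded <- sum(!ok)
        v0 <- v0[ok]; v1 <- v1[ok]
        d <- v1 - v0
        flagged <- FALSE
        if (stats::sd(d) == 0) {
            if (all(d == 0)) { t <- 0; p <- 1 }
            else { t <- sign(mean(d)) * Inf; p <- 0; flagged <- TRUE }
        } else {
            tt <- stats::t.test(v1, v0, paired = TRUE)
            t <- unname(tt$statistic); p <- tt$p.value
        }
        data.frame(trait = tr, nPairs = length(d), nExcluded = nExcluded,
                   meanT0 = mean(v0), sdT0 = stats::sd(v0),
                   meanT18 = mean(v1), sdT18 = stats::sd(v1),
                   meanDelta = mean(d), sdDelta = stats::sd(d),
                   t = t, p = p, degenerate = flagged)
    })
    do.call(rbind, res)
}

#' Annotate features with overlapping genes
#'
#' Each gene interval is extended upstream by \code{upstream} nt on its own
#' strand (start clipped at position 1); a feature is annotated with every
#' extended gene it overlaps (1-based inclusive overlap). Unknown strand is
#' treated as '+' with a warning.
#'
#' @param features \code{GRanges} of CpG positions or regions.
#' @param genes \code{GRanges} of gene bodies with strand; gene names taken
#'   from \code{names(genes)} or a \code{name}/\code{gene} metadata column.
#' @param upstream extension in nt (default 1500).
#' @return a \code{CharacterList}, one element per feature, genes in input
#'   order.
#' @export
annotateFeaturesToGenes <- function(features, genes, upstream = 1500) {
    if (any(start(genes) > end(genes)))
        stop("invalid gene intervals (start > end)")
    gnames <- names(genes)
    if (is.null(gnames)) gnames <- S4Vectors::mcols(genes)$name
    if (is.null(gnames)) gnames <- S4Vectors::mcols(genes)$gene
    if (is.null(gnames)) stop("genes must carry names")
    if (any(strand(genes) == "*")) {
        warning("unknown strand treated as '+'")
        strand(genes)[strand(genes) == "*"] <- "+"
    }
    ext <- genes
    plus <- as.logical(strand(ext) == "+")
    start(ext)[plus] <- pmax(1, start(ext)[plus] - upstream)
    end(ext)[!plus] <- end(ext)[!plus] + upstream
    hits <- findOverlaps(features, ext, ignore.strand = TRUE)
    res <- rep(list(character(0)), length(features))
    for (i in seq_along(features)) {
        j <- subjectHits(hits)[queryHits(hits) == i]
        res[[i]] <- gnames[sort(j)]
    }
    CharacterList(res)
}
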