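#' Exclude probes failing the detection p-value criterion
#'
#' A probe is excluded when its detection p-value exceeds \code{pDetect} in
#' strictly more than \code{maxFailFraction} of the samples (the boundary case
#' of exactly \code{maxFailFraction} is retained). Probe order is preserved.
#' The operation is idempotent: re-filtering a filtered experiment removes
#' nothing further.
#'
#' @param object a \linkS4class{MethylationExperiment} carrying a
#'   \code{detectionP} assay.
#' @param pDetect detection p-value threshold above which a measurement counts
#'   as failed (default 0.01).
#' @param maxFailFraction maximum tolerated fraction of failed samples per
#'   probe (default 0.01, i.e. "more than 1\% of samples" excludes).
#' @return the filtered \linkS4class{MethylationExperiment}; the QC report is
#'   available via \code{\link{qcReport}}.
#' @examples
#' cfg <- simConfig(nSubjects = 10, nProbes = 300, nTail = 0, seed = 2,
#'                  detectionFailFraction = 0.05, detectionFailRate = 0.3)
#' sim <- simulateMethylation(cfg)
#' filt <- filterDetectionP(sim$experiment)
#' qcReport(filt)$nProbesExcluded
#' @export
filterDetectionP <- function(object, pDetect = 0.01, maxFailFraction = 0.01) {
    dp <- detectionP(object)
    if (is.null(dp))
        stop("filterDetectionP requires a detectionP assay")
    failFrac <- rowMeans(dp > pDetect)
    drop <- failFrac > maxFailFraction
    report <- list(nProbesIn = nrow(object),
                   nProbesExcluded = sum(drop),
                   excludedProbeIds = rownames(object)[drop],
                   pDetect = pDetect,
                   maxFailFraction = maxFailFraction)
    out <- object[!drop, ]
    out@qc <- report
    out
}

#' Flag cross-reactive and SNP-overlapping probes
#'
#' Sets the \code{crossReactive} and \code{snp} manifest flags for the given
#' probe id sets. Flagged probes are never removed: they are carried through
#' all analyses and reported in result tables. Ids absent from the manifest
#' are ignored with a warning stating their count.
#'
#' @param object a \linkS4class{MethylationExperiment} or a manifest
#'   \code{GRanges}.
#' @param crossReactiveIds,snpIds character vectors of probe ids.
#' @return the object with updated manifest flags.
#' @export
flagProbes <- function(object, crossReactiveIds = character(0),
                       snpIds = character(0)) {
    isExp <- is(object, "MethylationExperiment")
    gr <- if (isExp) rowRanges(object) else object
    unknown <- sum(!(crossReactiveIds %in% names(gr))) +
               sum(!(snpIds %in% names(gr)))
    if (unknown > 0)
        warning(unknown, " flag id(s) not present in the manifest; ignored")
    mc <- S4Vectors::mcols(gr)
    mc$crossReactive <- mc$crossReactive | (names(gr) %in% crossReactiveIds)
    mc$snp <- mc$snp | (names(gr) %in% snpIds)
    S4Vectors::mcols(gr) <- mc
    if (isExp) {
        SummarizedExperiment::rowRanges(object) <- gr
        object
    } else gr
}

#' Quantile normalize beta values across samples
#'
#' Forces every sample onto the common reference distribution of mean order
#' statistics: the rank-k normalized value is the mean across samples of each
#' sample's k-th smallest beta; ties within a sample receive the mean of
#' their tied ranks' reference values. Within-sample rank order is preserved.
#' Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param object a \linkS4class{MethylationExperiment} (or bare numeric
#'   matrix) without missing values.
#' @return the object with normalized betas; a single-sample input is
#'   returned unchanged with a warning.
#' @examples
#' m <- cbind(s1 = c(0.1, 0.2, 0.3), s2 = c(0.2, 0.4, 0.6))
#' rownames(m) <- paste0("cg", 1:3)
#' quantileNormalize(m)  # both columns become 0.15, 0.30, 0.45
#' @export
quantileNormalize <- function(object) {
    b <- if (is(object, "MethylationExperiment")) betaValues(object)
         else as.matrix(object)
    if (anyNA(b))
        stop("quantileNormalize requires complete beta values")
    if (ncol(b) < 2) {
        warning("single-sample matrix: quantile normalization is a no-op")
        return(object)
    }
    nb <- limma::normalizeQuantiles(b, ties = TRUE)
    dimnames(nb) <- dimnames(b)
    if (is(object, "MethylationExperiment")) {
        betaValues(object) <- nb
        object
    } else nb
}
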