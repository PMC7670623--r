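#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#'   queryHits subjectHits
#' @import GenomicRanges
#' @importFrom IRanges IRanges CharacterList isDisjoint
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData rowData
#' @useDynLib methresp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MethylationExperiment: probe x sample beta values with genomic annotation
#'
#' The central container of the package. It extends
#' \linkS4class{RangedSummarizedExperiment} with a mandatory \code{"beta"}
#' assay holding methylation fractions in \eqn{[0,1]} and an optional
#' \code{"detectionP"} assay of per-probe-per-sample detection p-values of the
#' same shape. Row ranges carry the probe manifest (genomic position, QC
#' flags, gene annotation); column data carries the phenotype table
#' (subject, timepoint, sex, age, weights, BMI, intervention arm).
#'
#' @slot qc a list with the most recent probe-QC report (see
#'   \code{\link{filterDetectionP}}), empty before filtering.
#'
#' @seealso \code{\link{MethylationExperiment}} (constructor),
#'   \code{\link{betaValues}}, \code{\link{detectionP}},
#'   \code{\link{probeManifest}}
#' @export
setClass("MethylationExperiment",
    contains = "RangedSummarizedExperiment",
    representation(qc = "list"),
    prototype(qc = list()))

setValidity("MethylationExperiment", function(object) {
    msg <- NULL
    an <- assayNames(object)
    if (!("beta" %in% an))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (anyNA(b))
            msg <- c(msg, "beta values must not contain NA")
        else if (length(b) && (min(b) < 0 || max(b) > 1))
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if ("detectionP" %in% an) {
        dp <- assay(object, "detectionP")
        if (!identical(dim(dp), dim(assay(object, "beta"))))
            msg <- c(msg, "detectionP must match the shape of beta")
        if (length(dp) && !anyNA(dp) && (min(dp) < 0 || max(dp) > 1))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated probe ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationExperiment
#'
#' @param beta numeric probe x sample matrix of beta values in \eqn{[0,1]};
#'   rownames are probe ids, colnames sample ids.
#' @param manifest a \code{GRanges} of probe coordinates, named by probe id,
#'   with optional metadata columns \code{crossReactive}, \code{snp}
#'   (logical flags) and \code{genes} (\code{CharacterList} of gene symbols).
#'   Missing columns are added with defaults (no flag, no gene). Probes are
#'   matched to \code{beta} rows by name and must cover them.
#' @param colData a \code{data.frame}/\code{DataFrame} of per-sample
#'   phenotypes, rownames = sample ids (see \code{\link{simulateCohort}} for
#'   the column convention used throughout).
#' @param detectionP optional detection p-value matrix, same shape and
#'   dimnames as \code{beta}.
#'
#' @return a validated \linkS4class{MethylationExperiment}.
#' @examples
#' cfg <- simConfig(nSubjects = 6, nProbes = 50, nTail = 0, seed = 1)
#' sim <- simulateMethylation(cfg)
#' sim$experiment
#' @export
MethylationExperiment <- function(beta, manifest, colData = NULL,
                                  detectionP = NULL) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("beta must have probe ids as rownames and sample ids as colnames")
    if (!all(rownames(beta) %in% names(manifest)))
        stop("manifest is missing probes: ",
             paste(utils::head(setdiff(rownames(beta), names(manifest)), 5),
                   collapse = ", "))
    manifest <- completeManifest(manifest[rownames(beta)])
    assays <- list(beta = beta)
    if (!is.null(detectionP)) {
        detectionP <- as.matrix(detectionP)
        if (!identical(dim(detectionP), dim(beta)))
            stop("detectionP must match the shape of beta")
        dimnames(detectionP) <- dimnames(beta)
        assays$detectionP <- detectionP
    }
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(beta))
    else {
        colData <- DataFrame(colData)
        if (!is.null(rownames(colData)) &&
            !identical(rownames(colData), colnames(beta))) {
            if (!all(colnames(beta) %in% rownames(colData)))
                stop("colData does not cover all samples in beta")
            colData <- colData[colnames(beta), , drop = FALSE]
        }
    }
    se <- SummarizedExperiment(assays = assays, rowRanges = manifest,
                               colData = colData)
    new("MethylationExperiment", se, qc = list())
}

# fill in default manifest metadata columns so downstream code can rely on them
completeManifest <- function(gr) {
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$crossReactive)) mc$crossReactive <- rep(FALSE, length(gr))
    if (is.null(mc$snp)) mc$snp <- rep(FALSE, length(gr))
    if (is.null(mc$genes))
        mc$genes <- CharacterList(rep(list(character(0)), length(gr)))
    else if (!is(mc$genes, "CharacterList"))
        mc$genes <- CharacterList(lapply(mc$genes, as.character))
    S4Vectors::mcols(gr) <- mc
    gr
}

#' CellReference: mean methylation profiles of purified cell types
#'
#' Marker-probe beta profiles of the leukocyte populations used for
#' Houseman-style reference-based deconvolution.
#'
#' @slot profile numeric marker-probe x cell-type matrix of mean beta values
#'   in \eqn{[0,1]}; rownames are probe ids, colnames cell-type labels.
#' @seealso \code{\link{estimateCellProportions}},
#'   \code{\link{simulateCellReference}}
#' @export
setClass("CellReference", representation(profile = "matrix"))

setValidity("CellReference", function(object) {
    p <- object@profile
    msg <- NULL
    if (is.null(rownames(p)) || is.null(colnames(p)))
        msg <- c(msg, "profile needs probe rownames and cell-type colnames")
    if (ncol(p) < 2)
        msg <- c(msg, "at least 2 cell types required")
    if (length(p) && (anyNA(p) || min(p) < 0 || max(p) > 1))
        msg <- c(msg, "profiles must lie in [0, 1]")
    if (anyDuplicated(colnames(p)))
        msg <- c(msg, "duplicated cell-type labels")
    if (is.null(msg)) TRUE else msg
})

#' @rdname CellReference-class
#' @param profile marker-probe x cell-type matrix of mean betas.
#' @return a validated \code{CellReference}.
#' @export
CellReference <- function(profile) {
    new("CellReference", profile = as.matrix(profile))
}

#' @describeIn CellReference-class cell-type labels.
#' @param x a \code{CellReference}.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname CellReference-class
#' @export
setMethod("cellTypes", "CellReference", function(x) colnames(x@profile))

#' @describeIn CellReference-class the marker profile matrix.
#' @param object a \code{CellReference}.
#' @export
setGeneric("referenceProfile",
    function(object) standardGeneric("referenceProfile"))

#' @rdname CellReference-class
#' @export
setMethod("referenceProfile", "CellReference", function(object) object@profile)

setMethod("show", "CellReference", function(object) {
    cat("CellReference with", ncol(object@profile), "cell types (",
        paste(colnames(object@profile), collapse = ", "), ") and",
        nrow(object@profile), "marker probes\n")
})

setMethod("show", "MethylationExperiment", function(object) {
    callNextMethod()
    if (length(object@qc))
        cat("qc: ", object@qc$nProbesExcluded, " of ", object@qc$nProbesIn,
            " probes excluded by detection filter\n", sep = "")
})
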