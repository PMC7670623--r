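#' @rdname betaValues
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setGeneric("betaValues<-",
    function(object, value) standardGeneric("betaValues<-"))

#' @rdname detectionP
#' @export
setGeneric("detectionP", function(object) standardGeneric("detectionP"))

#' @rdname probeManifest
#' @export
setGeneric("probeManifest", function(object) standardGeneric("probeManifest"))

#' @rdname qcReport
#' @export
setGeneric("qcReport", function(object) standardGeneric("qcReport"))

#' Access the beta-value matrix
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param value replacement probe x sample matrix in \eqn{[0,1]}.
#' @return \code{betaValues} returns the probe x sample matrix of methylation
#'   fractions.
#' @name betaValues
NULL

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationExperiment",
    function(object) assay(object, "beta"))

#' @rdname betaValues
#' @export
setReplaceMethod("betaValues", "MethylationExperiment",
    function(object, value) {
        SummarizedExperiment::assay(object, "beta") <- value
        validObject(object)
        object
    })

#' Access the detection p-value matrix
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @return the detection p-value matrix, or \code{NULL} when the experiment
#'   carries none.
#' @name detectionP
NULL

#' @rdname detectionP
#' @export
setMethod("detectionP", "MethylationExperiment", function(object) {
    if ("detectionP" %in% assayNames(object)) assay(object, "detectionP")
    else NULL
})

#' Access the probe manifest
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @return a named \code{GRanges} with metadata columns \code{crossReactive},
#'   \code{snp} and \code{genes}.
#' @name probeManifest
NULL

#' @rdname probeManifest
#' @export
setMethod("probeManifest", "MethylationExperiment",
    function(object) rowRanges(object))

#' Access the probe-QC report
#'
#' @param object a \linkS4class{MethylationExperiment} that went through
#'   \code{\link{filterDetectionP}}.
#' @return a list with fields \code{nProbesIn}, \code{nProbesExcluded},
#'   \code{excludedProbeIds}, \code{pDetect}, \code{maxFailFraction}; empty
#'   list if no filtering was performed.
#' @name qcReport
NULL

#' @rdname qcReport
#' @export
setMethod("qcReport", "MethylationExperiment", function(object) object@qc)
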