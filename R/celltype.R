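#' Estimate leukocyte proportions by constrained projection
#'
#' Houseman-style reference-based deconvolution: for every sample, the
#' cell-type proportions minimize the squared error between its observed
#' marker betas and the mixture of reference profiles, subject to
#' non-negativity (solved by non-negative least squares,
#' \code{pracma::lsqnonneg}) followed by renormalization onto the unit
#' simplex. The estimate is deterministic given its inputs.
#'
#' @param object a \linkS4class{MethylationExperiment} (or probe x sample
#'   beta matrix).
#' @param reference a \code{\link{CellReference}}; at least as many shared
#'   marker probes as cell types are required.
#' @return sample x cell-type matrix of proportions; rows sum to 1.
#' @examples
#' cfg <- simConfig(nSubjects = 5, nProbes = 200, nMarkerProbes = 100,
#'                  nTail = 0, seed = 4)
#' sim <- simulateMethylation(cfg)
#' p <- estimateCellProportions(sim$experiment, sim$reference)
#' rowSums(p)
#' @export
estimateCellProportions <- function(object, reference) {
    b <- if (is(object, "MethylationExperiment")) betaValues(object)
         else as.matrix(object)
    prof <- referenceProfile(reference)
    shared <- intersect(rownames(prof), rownames(b))
    k <- ncol(prof)
    if (length(shared) < k)
        stop("under-determined: ", length(shared), " shared marker probes for ",
             k, " cell types")
    A <- prof[shared, , drop = FALSE]
    Y <- b[shared, , drop = FALSE]
    est <- t(vapply(seq_len(ncol(Y)), function(j) {
        w <- pracma::lsqnonneg(A, Y[, j])$x
        if (sum(w) <= 0) rep(1 / k, k) else w / sum(w)
    }, numeric(k)))
    dimnames(est) <- list(colnames(b), colnames(prof))
    est
}

#' Paired comparison of cell-type composition between timepoints
#'
#' Tests, per cell type, whether the estimated proportion changed between the
#' two timepoints using the paired Wilcoxon signed-rank test on T18 - T0
#' differences. Zero differences are dropped (standard signed-rank
#' convention); when all pairs are zero the p-value is 1. The exact null
#' distribution is used for up to 25 non-zero pairs (absent ties), the normal
#' approximation with continuity correction otherwise.
#'
#' @param proportions sample x cell-type matrix from
#'   \code{\link{estimateCellProportions}}.
#' @param pheno per-sample phenotype data with \code{subjectId} and
#'   \code{timepoint} columns (rownames = sample ids), e.g.
#'   \code{colData} of the experiment.
#' @param timepoints length-2 character vector, baseline first.
#' @return \code{data.frame} with columns \code{cellType},
#'   \code{medianDifference} (T18 - T0) and \code{p}.
#' @export
compareComposition <- function(proportions, pheno,
                               timepoints = c("T0", "T18")) {
    pheno <- as.data.frame(pheno)
    if (is.null(pheno$subjectId) || is.null(pheno$timepoint))
        stop("pheno must provide subjectId and timepoint columns")
    subj <- unique(pheno$subjectId)
    s0 <- rownames(pheno)[match(paste(subj, timepoints[1]),
                                paste(pheno$subjectId, pheno$timepoint))]
    s1 <- rownames(pheno)[match(paste(subj, timepoints[2]),
                                paste(pheno$subjectId, pheno$timepoint))]
    bad <- subj[is.na(s0) | is.na(s1) | !(s0 %in% rownames(proportions)) |
                !(s1 %in% rownames(proportions))]
    if (length(bad))
        stop("unpaired subject(s): ", paste(utils::head(bad, 5), collapse = ", "))
    res <- lapply(colnames(proportions), function(ct) {
        d <- proportions[s1, ct] - proportions[s0, ct]
        dnz <- d[d != 0]
        p <- if (length(dnz) == 0) 1 else {
            wt <- suppressWarnings(stats::wilcox.test(
                dnz, exact = length(dnz) <= 25, correct = TRUE))
            wt$p.value
        }
        data.frame(cellType = ct, medianDifference = stats::median(d), p = p)
    })
    do.call(rbind, res)
}

#' Adjust beta values for cell-type composition
#'
#' Residualizes every probe on the estimated proportion covariates (intercept
#' plus all cell types but the last, which is collinear with the simplex
#' constraint) and adds back the probe's grand mean, removing the variance
#' component attributable to composition differences while preserving
#' per-probe means. Output values are clipped to \eqn{[0,1]}.
#'
#' @param object a \linkS4class{MethylationExperiment} (or beta matrix).
#' @param proportions sample x cell-type matrix; rownames must cover the
#'   experiment's samples.
#' @return the object with composition-adjusted betas.
#' @export
adjustForComposition <- function(object, proportions) {
    b <- if (is(object, "MethylationExperiment")) betaValues(object)
         else as.matrix(object)
    if (!all(colnames(b) %in% rownames(proportions)))
        stop("proportions do not cover all samples")
    P <- proportions[colnames(b), -ncol(proportions), drop = FALSE]
    X <- cbind(1, P)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        warning("rank-deficient composition covariates; ",
                ncol(X) - qrX$rank, " collinear column(s) dropped")
    resid <- qr.resid(qrX, t(b))
    adj <- clip01(t(resid) + rowMeans(b))
    dimnames(adj) <- dimnames(b)
    if (is(object, "MethylationExperiment")) {
        betaValues(object) <- adj
        object
    } else adj
}
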