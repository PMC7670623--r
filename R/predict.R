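#' Build threshold/sign-selected CpG predictor sets
#'
#' Four methylation predictors from an EWAS table: CpGs correlating
#' negatively with weight change at combined p < 1e-3 and < 1e-4, and CpGs
#' correlating positively at the same two thresholds. For negative sets a
#' higher mean beta predicts greater weight loss; for positive sets a lower
#' one does (encoded in the \code{orientation} field). Empty sets are
#' omitted with a warning.
#'
#' @param assoc EWAS table from \code{\link{ewasScan}} (needs
#'   \code{probeId}, \code{combinedP}, \code{combinedR}).
#' @param thresholds combined-p cutoffs (default \code{c(1e-3, 1e-4)}).
#' @return named list of predictor specs, each a list with \code{name},
#'   \code{cpgIds}, \code{sign}, \code{threshold}, \code{orientation}
#'   (+1: higher score predicts success, -1: lower score does).
#' @export
buildPredictorSets <- function(assoc, thresholds = c(1e-3, 1e-4)) {
    if (!nrow(assoc)) stop("empty association table")
    specs <- list()
    for (sgn in c("negative", "positive")) {
        keep <- if (sgn == "negative") assoc$combinedR < 0
                else assoc$combinedR > 0
        for (th in thresholds) {
            ids <- assoc$probeId[keep & assoc$combinedP < th]
            nm <- sprintf("%s_p%g", sgn, th)
            if (!length(ids)) {
                warning("no CpGs for predictor ", nm, "; omitted")
                next
            }
            specs[[nm]] <- list(name = nm, cpgIds = ids, sign = sgn,
                                threshold = th,
                                orientation = if (sgn == "negative") 1 else -1)
        }
    }
    specs
}

#' Baseline methylation score
#'
#' Per-sample unweighted mean of the beta values over a predictor's CpG set.
#'
#' @param object a \linkS4class{MethylationExperiment} or beta matrix
#'   (baseline samples).
#' @param spec a predictor spec from \code{\link{buildPredictorSets}} or a
#'   character vector of CpG ids.
#' @return named numeric vector of per-sample scores.
#' @export
methylationScore <- function(object, spec) {
    b <- if (is(object, "MethylationExperiment")) betaValues(object)
         else as.matrix(object)
    ids <- if (is.list(spec)) spec$cpgIds else spec
    missing <- setdiff(ids, rownames(b))
    if (length(missing))
        stop("CpGs absent from the matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    colMeans(b[ids, , drop = FALSE])
}

#' Empirical ROC curve and AUC
#'
#' ROC over all score cut-points with the midpoint tie convention; the AUC
#' (trapezoidal area) equals the Mann-Whitney concordance probability
#' \eqn{P(score_{pos} > score_{neg}) + 0.5 P(=)}.
#'
#' @param scores numeric per-sample scores.
#' @param labels binary success labels (logical, or coercible; \code{TRUE} =
#'   positive class).
#' @return list of class \code{"ROCResult"}: \code{fpr}, \code{tpr}
#'   (monotone from (0,0) to (1,1)), \code{thresholds}, \code{auc},
#'   \code{nPos}, \code{nNeg}.
#' @examples
#' rocAuc(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.logical(labels)
    if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
    nPos <- sum(labels); nNeg <- sum(!labels)
    if (nPos == 0 || nNeg == 0)
        stop("undefined AUC: both classes must be present")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    # collapse ties: one ROC vertex per distinct score
    last <- !duplicated(s, fromLast = TRUE)
    tpr <- cumsum(l)[last] / nPos
    fpr <- cumsum(!l)[last] / nNeg
    tpr <- c(0, tpr); fpr <- c(0, fpr)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    structure(list(fpr = fpr, tpr = tpr,
                   thresholds = c(Inf, s[last]), auc = auc,
                   nPos = nPos, nNeg = nNeg),
              class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
    cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
                x$auc, x$nPos, x$nNeg))
    invisible(x)
}

#' AUC-maximizing linear age/BMI score
#'
#' The benchmark predictor \eqn{x \cdot age + y \cdot BMI}: since ranking
#' (hence the ROC) depends only on the direction of \eqn{(x, y)}, the
#' coefficients are searched exhaustively on an angle grid
#' \eqn{(x, y) = (\cos\theta, \sin\theta)}, \eqn{\theta \in [0, 2\pi)}. The
#' AUC-maximizing direction is returned both raw and rescaled to
#' \eqn{x = -1} (when \eqn{x \neq 0}) for comparability across cohorts.
#'
#' @param age,bmi numeric covariates.
#' @param labels binary success labels.
#' @param nAngles grid resolution (default 721; must be \eqn{\ge} 180).
#' @return list: \code{x}, \code{y}, \code{xScaled}, \code{yScaled},
#'   \code{roc} (an \code{ROCResult}).
#' @export
fitAgeBmiPredictor <- function(age, bmi, labels, nAngles = 721L) {
    if (nAngles < 180) stop("grid must have at least 180 angles")
    if (stats::sd(age) == 0 && stats::sd(bmi) == 0)
        stop("degenerate covariates: age and BMI both constant")
    theta <- seq(0, 2 * pi, length.out = nAngles + 1L)[seq_len(nAngles)]
    best <- NULL; bestAuc <- -Inf
    for (th in theta) {
        sc <- cos(th) * age + sin(th) * bmi
        roc <- rocAuc(sc, labels)
        if (roc$auc > bestAuc) {
            bestAuc <- roc$auc
            best <- list(x = cos(th), y = sin(th), roc = roc)
        }
    }
    if (abs(best$x) > 1e-8) {
        best$xScaled <- -1
        best$yScaled <- -best$y / best$x
    } else {
        best$xScaled <- 0
        best$yScaled <- sign(best$y)
    }
    best
}

#' Compare methylation-score predictors with the age/BMI benchmark
#'
#' Evaluates the four threshold/sign-selected methylation scores and the
#' grid-maximized age/BMI linear score on the same samples: the responder /
#' non-responder subjects of the supplied design (male-only when the design
#' was built that way), baseline samples only, success = responder
#' membership. Because the CpG sets are selected on the same data the
#' methylation AUCs are optimistically biased; the output carries a
#' circularity note.
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param assoc EWAS table from \code{\link{ewasScan}}.
#' @param design a \code{GroupDesign} from \code{\link{selectResponders}}.
#' @param timepoint baseline timepoint (default \code{"T0"}).
#' @param thresholds passed to \code{\link{buildPredictorSets}}.
#' @return \code{data.frame} of predictors and AUCs, with attribute
#'   \code{"note"} on selection circularity.
#' @export
evaluatePredictors <- function(object, assoc, design, timepoint = "T0",
                               thresholds = c(1e-3, 1e-4)) {
    pheno <- as.data.frame(colData(object))
    subjects <- c(design$groupA, design$groupB)
    samples <- rownames(pheno)[pheno$subjectId %in% subjects &
                               pheno$timepoint == timepoint]
    lab <- pheno[samples, "subjectId"] %in% design$groupA
    b <- betaValues(object)[, samples, drop = FALSE]
    specs <- buildPredictorSets(assoc, thresholds = thresholds)
    rows <- lapply(specs, function(sp) {
        sc <- sp$orientation * methylationScore(b, sp)
        data.frame(predictor = sp$name, nCpgs = length(sp$cpgIds),
                   auc = rocAuc(sc, lab)$auc)
    })
    ageBmi <- fitAgeBmiPredictor(pheno[samples, "age"],
                                 pheno[samples, "bmi"], lab)
    rows[[length(rows) + 1L]] <- data.frame(
        predictor = "age_bmi", nCpgs = NA_integer_, auc = ageBmi$roc$auc)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "note") <-
        "methylation CpGs were selected on the evaluation data; AUCs are optimistically biased"
    attr(out, "ageBmiCoefficients") <- c(x = ageBmi$xScaled,
                                         y = ageBmi$yScaled)
    out
}
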