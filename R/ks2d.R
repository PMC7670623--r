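#' Two-dimensional Kolmogorov-Smirnov statistic
#'
#' Two-sample 2D-KS statistic over point clouds of (genomic position, beta)
#' pairs, in the Fasano-Franceschini construction: the maximum, over all data
#' points of both samples and all four axis-aligned quadrant orientations
#' (quadrant edges inclusive), of the absolute difference between the two
#' samples' empirical quadrant probabilities. Symmetric in its arguments;
#' 0 for identical point multisets; 1 under complete quadrant separation.
#'
#' @param pointsA,pointsB numeric n x 2 matrices (columns: x, y), both
#'   non-empty.
#' @return the statistic D in \eqn{[0,1]}.
#' @examples
#' a <- cbind(c(0, 1), c(0, 1))
#' b <- cbind(c(0, 1), c(1, 0))
#' ks2dStatistic(a, b)  # 0.5
#' @export
ks2dStatistic <- function(pointsA, pointsB) {
    pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
    if (nrow(pointsA) == 0 || nrow(pointsB) == 0)
        stop("both point sets must be non-empty")
    if (ncol(pointsA) != 2 || ncol(pointsB) != 2)
        stop("point sets must have two columns (x, y)")
    .ks2d_stat_cpp(pointsA, pointsB)
}

# Kolmogorov tail probability Q(lambda) = 2 sum (-1)^{k-1} exp(-2 k^2 lambda^2)
ksTail <- function(lambda) {
    if (lambda < 0.05) return(1)
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' 2D-KS p-value by permutation or asymptotic approximation
#'
#' Permutation mode (default) permutes sample-group labels, so all points
#' contributed by one sample move together, and reports
#' \eqn{p = (1 + \#\{D_{perm} \ge D_{obs}\}) / (n_{perm} + 1)}. The
#' asymptotic mode uses the Fasano-Franceschini large-sample approximation
#' with a correlation correction.
#'
#' @param beta probe x sample numeric matrix of the region's betas (all
#'   samples of both groups).
#' @param positions numeric vector of probe positions (length =
#'   \code{nrow(beta)}); min-max scaled to \eqn{[0,1]} when
#'   \code{scalePositions}.
#' @param group integer/logical vector per sample: 0/FALSE = group A,
#'   1/TRUE = group B.
#' @param method \code{"permutation"} or \code{"asymptotic"}.
#' @param nPerm number of permutations (\eqn{\ge} 100).
#' @param scalePositions scale positions into \eqn{[0,1]} so the two axes are
#'   comparable (default TRUE).
#' @param earlyStop stop permuting once this many exceedances have been seen
#'   (0 = never): clearly-null regions finish after a few dozen permutations
#'   while small p-values still use the full \code{nPerm}; the sequential
#'   p-value \eqn{(1+k)/(1+B_{done})} remains valid.
#'
#' @details Because D is a difference of count fractions it is discrete, and
#' permuted values tie with the observed one; counting ties fully makes
#' \code{p} conservative (stochastically larger than uniform under the
#' null). The returned \code{midP} counts ties half and is approximately
#' uniform under the null — use it for calibration diagnostics, \code{p}
#' for inference.
#' @return list with elements \code{D}, \code{p}, \code{midP} and (for the
#'   permutation method) \code{nPermUsed}.
#' @export
ks2dPValue <- function(beta, positions, group,
                       method = c("permutation", "asymptotic"),
                       nPerm = 1000, scalePositions = TRUE,
                       earlyStop = 0L) {
    method <- match.arg(method)
    beta <- as.matrix(beta)
    group <- as.integer(group)
    stopifnot(length(positions) == nrow(beta), length(group) == ncol(beta))
    if (!all(group %in% c(0L, 1L)) || !any(group == 0L) || !any(group == 1L))
        stop("group must contain both 0 and 1")
    pos <- as.numeric(positions)
    if (scalePositions) {
        rg <- range(pos)
        pos <- if (rg[2] > rg[1]) (pos - rg[1]) / (rg[2] - rg[1])
               else rep(0, length(pos))
    }
    if (method == "permutation") {
        if (nPerm < 100) stop("nPerm must be >= 100")
        .ks2d_perm_cpp(beta, pos, group, as.integer(nPerm),
                       as.integer(earlyStop))
    } else {
        mkPts <- function(cols) {
            do.call(rbind, lapply(cols, function(s) cbind(pos, beta[, s])))
        }
        A <- mkPts(which(group == 0L)); B <- mkPts(which(group == 1L))
        D <- .ks2d_stat_cpp(A, B)
        n1 <- nrow(A); n2 <- nrow(B)
        n <- n1 * n2 / (n1 + n2)
        safeCor <- function(m) {
            if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) 0
            else stats::cor(m[, 1], m[, 2])
        }
        rr <- sqrt(1 - 0.5 * (safeCor(A)^2 + safeCor(B)^2))
        lambda <- sqrt(n) * D / (1 + rr * (0.25 - 0.75 / sqrt(n)))
        pv <- ksTail(lambda)
        list(D = D, p = pv, midP = pv)
    }
}

#' Binary segmentation of a cluster's group-difference signal
#'
#' Recursively splits the per-probe group-difference signal of a CpG cluster
#' at the boundary maximizing the absolute difference between the two
#' sub-segments' mean differences. Recursion stops when a segment has fewer
#' than \code{2 * minProbes} probes or when no split increases the absolute
#' mean difference (|deltaM|) over the unsplit segment. Every emitted
#' candidate has at least \code{minProbes} probes.
#'
#' @param diffSignal numeric vector: per-probe difference of group mean betas
#'   (group A - group B), in genomic order.
#' @param minProbes minimum probes per candidate region (default 3).
#' @return \code{data.frame} with columns \code{start}, \code{end} (probe
#'   indices into \code{diffSignal}) and \code{deltaM} (mean difference of
#'   the candidate).
#' @examples
#' segmentCluster(c(0, 0, 0, 0, 0, .12, .12, .12, .12, .12))
#' @export
segmentCluster <- function(diffSignal, minProbes = 3L) {
    d <- as.numeric(diffSignal)
    out <- list()
    recurse <- function(lo, hi) {
        len <- hi - lo + 1L
        whole <- mean(d[lo:hi])
        if (len < 2L * minProbes) {
            out[[length(out) + 1L]] <<- c(lo, hi, whole)
            return(invisible())
        }
        ks <- seq(lo + minProbes - 1L, hi - minProbes)
        sep <- vapply(ks, function(k)
            abs(mean(d[lo:k]) - mean(d[(k + 1L):hi])), numeric(1))
        k <- ks[which.max(sep)]
        left <- mean(d[lo:k]); right <- mean(d[(k + 1L):hi])
        if (max(abs(left), abs(right)) > abs(whole) + 1e-12) {
            recurse(lo, k)
            recurse(k + 1L, hi)
        } else out[[length(out) + 1L]] <<- c(lo, hi, whole)
    }
    if (length(d) >= minProbes) recurse(1L, length(d))
    if (!length(out))
        return(data.frame(start = integer(0), end = integer(0),
                          deltaM = numeric(0)))
    res <- do.call(rbind, out)
    data.frame(start = as.integer(res[, 1]), end = as.integer(res[, 2]),
               deltaM = res[, 3])
}
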