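# logit-scale helpers; betas are squeezed away from {0,1} before transform
logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

squeezeBeta <- function(b, eps = 1e-4) pmin(pmax(b, eps), 1 - eps)

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, with input
#' validation. Order-preserving: element i of the result corresponds to
#' element i of the input.
#'
#' @param p numeric vector of p-values in \eqn{[0,1]}.
#' @return adjusted p-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must be numeric in [0, 1] without NA")
    stats::p.adjust(p, method = "BH")
}

stopIfNot01 <- function(x, what) {
    if (anyNA(x) || any(x < 0) || any(x > 1))
        stop(what, " must lie in [0, 1]")
    invisible(x)
}

# sample k elements from a vector regardless of its length (avoids the
# base-R sample() scalar pitfall)
sampleVec <- function(x, k) x[sample.int(length(x), k)]
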