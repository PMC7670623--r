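# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive and share no code with the package internals.

# 2D-KS: enumerate every data point of both sets as quadrant origin and all
# four inclusive axis-aligned quadrant orientations.
ks2dOracle <- function(a, b) {
    anchors <- rbind(a, b)
    quads <- list(function(p, x0, y0) p[, 1] <= x0 & p[, 2] <= y0,
                  function(p, x0, y0) p[, 1] <= x0 & p[, 2] >= y0,
                  function(p, x0, y0) p[, 1] >= x0 & p[, 2] <= y0,
                  function(p, x0, y0) p[, 1] >= x0 & p[, 2] >= y0)
    D <- 0
    for (i in seq_len(nrow(anchors)))
        for (q in quads) {
            fa <- mean(q(a, anchors[i, 1], anchors[i, 2]))
            fb <- mean(q(b, anchors[i, 1], anchors[i, 2]))
            D <- max(D, abs(fa - fb))
        }
    D
}

# Benjamini-Hochberg by the step-up definition
bhOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    sorted <- p[ord] * m / seq_len(m)
    for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m]))
    out <- numeric(m)
    out[ord] <- adj
    out
}

# AUC as the Mann-Whitney concordance probability over all pos/neg pairs
aucOracle <- function(scores, labels) {
    pos <- scores[labels]
    neg <- scores[!labels]
    conc <- 0
    for (p in pos)
        for (q in neg)
            conc <- conc + (p > q) + 0.5 * (p == q)
    conc / (length(pos) * length(neg))
}

# all-pairs 1-based inclusive overlap of features with upstream-extended genes
geneOverlapOracle <- function(fChrom, fStart, fEnd,
                              gChrom, gStart, gEnd, gStrand, gName,
                              upstream = 1500) {
    lapply(seq_along(fChrom), function(i) {
        hits <- character(0)
        for (j in seq_along(gChrom)) {
            s <- gStart[j]; e <- gEnd[j]
            if (gStrand[j] == "+") s <- max(1, s - upstream)
            else e <- e + upstream
            if (fChrom[i] == gChrom[j] && fStart[i] <= e && fEnd[i] >= s)
                hits <- c(hits, gName[j])
        }
        hits
    })
}
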