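#' Chromatin-state annotation of features
#'
#' Intersects features (DMRs or CpGs) with per-tissue chromatin-state
#' segmentations: per feature and tissue, every overlapping state with its
#' bp overlap; per tissue the state with the largest overlap (ties
#' multi-reported, slash-separated); per tissue group the modal state across
#' member tissues (ties multi-reported).
#'
#' @param features \code{GRanges} of regions or CpG positions.
#' @param segmentations named list of \code{GRanges}, one per tissue, each
#'   with a \code{state} metadata column; intervals must be non-overlapping
#'   within a tissue.
#' @param tissueGroups named list mapping group label to member tissue
#'   names; defaults to one group per tissue.
#' @return list with \code{detail} (feature, tissue, state, bp) and
#'   \code{summary} (feature x tissue-group modal-state \code{data.frame}
#'   with \code{"."} for features without annotation).
#' @export
intersectStates <- function(features, segmentations, tissueGroups = NULL) {
    if (any(start(features) > end(features)))
        stop("invalid features (end < start)")
    for (tn in names(segmentations)) {
        seg <- segmentations[[tn]]
        if (is.null(seg$state)) stop("segmentation '", tn, "' lacks states")
        if (length(seg) > 1 &&
            !isDisjoint(seg))
            stop("segmentation '", tn, "' has overlapping intervals")
    }
    if (is.null(tissueGroups))
        tissueGroups <- as.list(stats::setNames(names(segmentations),
                                                names(segmentations)))
    fid <- if (!is.null(names(features))) names(features)
           else as.character(seq_along(features))
    detail <- list()
    perTissueState <- matrix(NA_character_, length(features),
                             length(segmentations),
                             dimnames = list(fid, names(segmentations)))
    for (tn in names(segmentations)) {
        seg <- segmentations[[tn]]
        hits <- findOverlaps(features, seg, ignore.strand = TRUE)
        if (length(hits)) {
            ov <- width(pintersect(features[queryHits(hits)],
                                   seg[subjectHits(hits)],
                                   ignore.strand = TRUE))
            detail[[tn]] <- data.frame(
                feature = fid[queryHits(hits)], tissue = tn,
                state = seg$state[subjectHits(hits)], bp = ov)
            for (i in unique(queryHits(hits))) {
                sel <- queryHits(hits) == i
                agg <- tapply(ov[sel], seg$state[subjectHits(hits)][sel], sum)
                best <- names(agg)[agg == max(agg)]
                perTissueState[i, tn] <- paste(sort(best), collapse = "/")
            }
        }
    }
    summary <- data.frame(feature = fid, row.names = NULL)
    for (gn in names(tissueGroups)) {
        members <- tissueGroups[[gn]]
        summary[[gn]] <- vapply(seq_along(features), function(i) {
            st <- perTissueState[i, members]
            st <- st[!is.na(st)]
            if (!length(st)) return(".")
            tab <- table(st)
            paste(sort(names(tab)[tab == max(tab)]), collapse = "/")
        }, character(1))
    }
    list(detail = if (length(detail)) do.call(rbind, c(detail,
                                                       make.row.names = FALSE))
                  else NULL,
         summary = summary)
}

#' Probe-abundance-corrected gene-set enrichment
#'
#' Tests whether the genes of a hit-probe set are over-represented in each
#' gene set, while correcting for the array's probe-per-gene bias: the null
#' draws the same number of probes uniformly from the probe universe (so
#' genes covered by more probes are drawn proportionally more often — this
#' is the bias correction), maps them to genes and counts the overlap with
#' the set. \eqn{p = (1 + \#\{null \ge observed\}) / (n_{resample} + 1)};
#' q is Benjamini-Hochberg across sets.
#'
#' @param hitProbes character vector of hit probe ids (subset of the
#'   universe).
#' @param universe probe manifest \code{GRanges} (named, with a \code{genes}
#'   metadata column) defining the universe and the probe-to-gene map.
#' @param geneSets named list of character gene vectors; empty sets are
#'   skipped with a warning.
#' @param nResample resampling iterations (default 1000).
#' @param seed RNG seed.
#' @return \code{data.frame}: \code{geneSet}, \code{nHitGenes} (set genes
#'   hit), \code{nSetGenes}, \code{p}, \code{q}.
#' @export
geneSetEnrichment <- function(hitProbes, universe, geneSets,
                              nResample = 1000L, seed = 1L) {
    if (!all(hitProbes %in% names(universe)))
        stop("hitProbes must be a subset of the universe")
    keep <- vapply(geneSets, length, integer(1)) > 0
    if (any(!keep)) {
        warning("skipping empty gene set(s): ",
                paste(names(geneSets)[!keep], collapse = ", "))
        geneSets <- geneSets[keep]
    }
    set.seed(seed)
    probeGenes <- as.list(S4Vectors::mcols(universe)$genes)
    names(probeGenes) <- names(universe)
    hitGenes <- unique(unlist(probeGenes[hitProbes]))
    nHit <- length(hitProbes)
    obs <- vapply(geneSets, function(gs)
        length(intersect(hitGenes, gs)), integer(1))
    geCount <- matrix(0L, nResample, length(geneSets))
    for (b in seq_len(nResample)) {
        genes <- unique(unlist(probeGenes[sample.int(length(universe), nHit)]))
        geCount[b, ] <- vapply(seq_along(geneSets), function(k)
            length(intersect(genes, geneSets[[k]])), integer(1))
    }
    p <- vapply(seq_along(geneSets), function(k)
        (1 + sum(geCount[, k] >= obs[k])) / (nResample + 1), numeric(1))
    data.frame(geneSet = names(geneSets), nHitGenes = obs,
               nSetGenes = vapply(geneSets, function(g)
                   length(unique(g)), integer(1)),
               p = p, q = bhAdjust(p), row.names = NULL)
}
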