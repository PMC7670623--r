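#' Read and write pipeline TSV files
#'
#' Plain-text interchange used by every stage: beta / detection-p matrices
#' (probes x samples, header row of sample ids, first column \code{probe_id}),
#' probe manifests (\code{probe_id}, \code{chrom}, \code{pos},
#' \code{cross_reactive} 0/1, \code{snp} 0/1, \code{genes}
#' semicolon-separated), phenotype tables (first column \code{sample_id}),
#' cell references (\code{probe_id} + one column per cell type), gene-body
#' BED6 and chromatin-state BED4 (both 0-based half-open, converted to the
#' 1-based inclusive coordinates used internally), and 2-column gene-set
#' TSVs (\code{set_id}, \code{gene}).
#'
#' @param path file path.
#' @name methresp-io
NULL

#' @rdname methresp-io
#' @return \code{readBetaMatrix}: numeric matrix, probes x samples.
#' @export
readBetaMatrix <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- dt[[1]]
    m
}

#' @rdname methresp-io
#' @param m matrix to write, rownames = probe ids.
#' @export
writeBetaMatrix <- function(m, path) {
    dt <- data.table::data.table(probe_id = rownames(m), m)
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname methresp-io
#' @return \code{readManifest}: a named probe \code{GRanges}.
#' @export
readManifest <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    gr <- GRanges(seqnames = dt$chrom,
                  ranges = IRanges(start = dt$pos, width = 1L))
    names(gr) <- dt$probe_id
    S4Vectors::mcols(gr)$crossReactive <- as.logical(dt$cross_reactive)
    S4Vectors::mcols(gr)$snp <- as.logical(dt$snp)
    S4Vectors::mcols(gr)$genes <- CharacterList(
        lapply(strsplit(ifelse(is.na(dt$genes), "", dt$genes), ";"),
               function(g) g[nzchar(g)]))
    gr
}

#' @rdname methresp-io
#' @param manifest a probe \code{GRanges}.
#' @export
writeManifest <- function(manifest, path) {
    dt <- data.table::data.table(
        probe_id = names(manifest),
        chrom = as.character(seqnames(manifest)),
        pos = start(manifest),
        cross_reactive = as.integer(manifest$crossReactive),
        snp = as.integer(manifest$snp),
        genes = vapply(manifest$genes, paste, character(1), collapse = ";"))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname methresp-io
#' @return \code{readPhenotypes}: \code{data.frame}, rownames = sample ids.
#' @export
readPhenotypes <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    rownames(dt) <- dt$sample_id
    dt$sample_id <- NULL
    dt
}

#' @rdname methresp-io
#' @param pheno phenotype \code{data.frame}, rownames = sample ids.
#' @export
writePhenotypes <- function(pheno, path) {
    dt <- data.table::data.table(sample_id = rownames(pheno),
                                 as.data.frame(pheno))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname methresp-io
#' @return \code{readCellReference}: a \code{\link{CellReference}}.
#' @export
readCellReference <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- dt[[1]]
    CellReference(m)
}

#' @rdname methresp-io
#' @param reference a \code{\link{CellReference}}.
#' @export
writeCellReference <- function(reference, path) {
    prof <- referenceProfile(reference)
    dt <- data.table::data.table(probe_id = rownames(prof), prof)
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname methresp-io
#' @return \code{readGeneBed}: gene \code{GRanges} (named, stranded) from
#'   BED6.
#' @export
readGeneBed <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            data.table = FALSE)
    if (ncol(dt) < 6) stop("gene BED must have 6 columns (strand required)")
    gr <- GRanges(seqnames = dt[[1]],
                  ranges = IRanges(start = dt[[2]] + 1L, end = dt[[3]]),
                  strand = dt[[6]])
    names(gr) <- dt[[4]]
    gr
}

#' @rdname methresp-io
#' @return \code{readStateBed}: \code{GRanges} with a \code{state} column
#'   from BED4.
#' @export
readStateBed <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            data.table = FALSE)
    if (ncol(dt) < 4) stop("state BED must have 4 columns")
    gr <- GRanges(seqnames = dt[[1]],
                  ranges = IRanges(start = dt[[2]] + 1L, end = dt[[3]]))
    S4Vectors::mcols(gr)$state <- dt[[4]]
    gr
}

#' @rdname methresp-io
#' @return \code{readGeneSets}: named list of gene vectors from a 2-column
#'   TSV.
#' @export
readGeneSets <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    split(dt[[2]], dt[[1]])
}

#' Write a DMR table
#'
#' Writes \code{\link{callDMRs}} output as a BED-like TSV with 1-based
#' inclusive coordinates, or as true BED (0-based half-open) with
#' \code{bed = TRUE}.
#'
#' @param dmrs \code{GRanges} from \code{\link{callDMRs}}.
#' @param path file path.
#' @param bed write 0-based half-open BED coordinates.
#' @export
writeDMRs <- function(dmrs, path, bed = FALSE) {
    dt <- data.table::data.table(
        chrom = as.character(seqnames(dmrs)),
        start = if (bed) start(dmrs) - 1L else start(dmrs),
        end = end(dmrs),
        n_probes = dmrs$nProbes,
        delta_m = dmrs$deltaM,
        ks2d_p = dmrs$ks2dP,
        adj_p = dmrs$adjP,
        snp_probes = dmrs$snpProbes,
        cross_reactive = dmrs$crossReactive,
        genes = vapply(dmrs$genes, paste, character(1), collapse = ","))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}
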