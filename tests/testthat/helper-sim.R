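# small study configurations shared across test files

tinyConfig <- function(...) {
    simConfig(nSubjects = 8L, nProbes = 120L, nChromosomes = 2L,
              nMarkerProbes = 0L, nTail = 2L, maleFraction = 1,
              detectionFailFraction = 0, seed = 101L, ...)
}

# a deterministic manifest for hand-built experiments: one probe per 100 nt
gridManifest <- function(n, chrom = "chr1", spacing = 100L) {
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = seq_len(n) * spacing, width = 1L))
    names(gr) <- sprintf("cg%05d", seq_len(n))
    gr
}

# two-timepoint phenotype frame for nSubj subjects with given weight changes
makePheno <- function(changePct, sex = "male", age = NULL, bmi = NULL) {
    n <- length(changePct)
    subj <- sprintf("P%02d", seq_len(n))
    if (is.null(age)) age <- rep(50, n)
    if (is.null(bmi)) bmi <- rep(30, n)
    w0 <- rep(100, n)
    one <- data.frame(subjectId = subj, sex = rep(sex, length.out = n),
                      age = age, bmi = bmi,
                      weightT0 = w0, weightT18 = w0 * (1 + changePct / 100))
    ph <- rbind(cbind(one, timepoint = "T0"), cbind(one, timepoint = "T18"))
    ph <- ph[order(ph$subjectId, ph$timepoint), ]
    rownames(ph) <- paste(ph$subjectId, ph$timepoint, sep = "_")
    ph$weight <- ifelse(ph$timepoint == "T18", ph$weightT18, ph$weightT0)
    ph
}
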