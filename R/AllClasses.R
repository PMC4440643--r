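#' MethylationExperiment: CpG beta-values with annotation and clinical data
#'
#' An S4 container extending \linkS4class{SummarizedExperiment}.  The single
#' assay \code{"beta"} holds per-CpG methylation beta-values in [0, 1]
#' (missing values allowed), \code{rowData} carries the CpG annotation
#' (\code{chrom}, \code{pos} = 1-based coordinate of the C of the CpG,
#' \code{strand}), and \code{colData} carries the clinical table
#' (\code{survival_time} in days, \code{event} in \{0, 1\}, plus arbitrary
#' subtype label columns such as \code{ER}).
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [MethylationExperiment()] for the validating constructor,
#'   [betaValues()], [cpgInfo()], [clinicalInfo()] for accessors.
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    if (!"beta" %in% assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        bad <- which(!is.na(b) & (b < 0 | b > 1))
        if (length(bad))
            msg <- c(msg, sprintf("%d beta value(s) outside [0, 1]", length(bad)))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate CpG ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    rd <- rowData(object)
    need <- c("chrom", "pos", "strand")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, "rowData must have columns chrom, pos, strand")
    else {
        if (any(rd$pos < 1)) msg <- c(msg, "CpG positions must be >= 1")
        if (!all(rd$strand %in% c("+", "-")))
            msg <- c(msg, "CpG strand must be '+' or '-'")
    }
    if (length(msg)) msg else TRUE
})

#' MotifSet: a collection of position weight matrices
#'
#' Each motif is a 4 x width probability matrix (rows A, C, G, T; every
#' column sums to 1 and, after regularisation, every entry is strictly
#' positive).  Motif ids are unique; each motif maps to a transcription
#' factor name, and several motifs may share a TF (motif databases routinely
#' hold multiple matrices per factor).
#'
#' @slot motifs named list of 4 x width numeric matrices.
#' @slot tfName character vector, parallel to \code{motifs}: TF per motif.
#' @seealso [MotifSet()], [readMotifs()], [tfNames()], [motifWidths()],
#'   [motifConsensus()].
#' @export
setClass("MotifSet",
         representation(motifs = "list", tfName = "character"))

setValidity("MotifSet", function(object) {
    msg <- character()
    m <- object@motifs
    if (is.null(names(m)) || anyDuplicated(names(m)))
        msg <- c(msg, "motif ids must be unique and named")
    if (length(object@tfName) != length(m))
        msg <- c(msg, "tfName must be parallel to motifs")
    for (i in seq_along(m)) {
        x <- m[[i]]
        if (!is.matrix(x) || nrow(x) != 4L || ncol(x) < 1L) {
            msg <- c(msg, sprintf("motif %d is not a 4 x w matrix", i))
            next
        }
        if (!identical(rownames(x), c("A", "C", "G", "T")))
            msg <- c(msg, sprintf("motif %d rows must be A,C,G,T", i))
        if (any(x <= 0))
            msg <- c(msg, sprintf("motif %d has non-positive probabilities", i))
        if (any(abs(colSums(x) - 1) > 1e-6))
            msg <- c(msg, sprintf("motif %d columns do not sum to 1", i))
    }
    if (length(msg)) msg else TRUE
})
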