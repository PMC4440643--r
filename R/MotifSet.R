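#' Construct a MotifSet
#'
#' @param motifs named list of 4 x width probability matrices with rownames
#'   A, C, G, T.  Columns must sum to 1; entries must be strictly positive
#'   (use [regularizePWM()] on raw probability or count matrices first).
#' @param tfName character vector of transcription factor names, one per
#'   motif (defaults to the motif ids).
#' @return A \linkS4class{MotifSet}.
#' @examples
#' m <- matrix(c(.97, .01, .01, .01), 4, 6,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' ms <- MotifSet(list(M1 = m), tfName = "TF1")
#' motifWidths(ms)
#' motifConsensus(ms)
#' @export
MotifSet <- function(motifs, tfName = names(motifs)) {
    stopifnot(is.list(motifs))
    tfName <- as.character(tfName)
    names(tfName) <- names(motifs)
    new("MotifSet", motifs = motifs, tfName = tfName)
}

#' Regularize a PWM
#'
#' Converts a count or probability matrix into a strictly positive
#' probability matrix.  Count matrices (any column sum > 1 + 1e-6) get a
#' pseudocount added to every cell before normalisation; probability
#' matrices are floored at \code{floor_prob} and renormalised.  Either way
#' no log-odds score can be -Inf downstream.
#'
#' @param x 4 x width numeric matrix (counts or probabilities), rows A,C,G,T.
#' @param pseudocount added to each cell of a count matrix (default 0.1).
#' @param floor_prob lower bound applied to probability matrices (default 1e-4).
#' @return 4 x width probability matrix, columns summing to 1, entries > 0.
#' @export
regularizePWM <- function(x, pseudocount = 0.1, floor_prob = 1e-4) {
    x <- as.matrix(x)
    if (nrow(x) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
    if (ncol(x) < 1L) stop("zero-width motif")
    if (any(x < 0)) stop("negative value in motif matrix")
    rownames(x) <- c("A", "C", "G", "T")
    cs <- colSums(x)
    if (any(cs == 0)) stop("motif column sums to 0 (uninformative position)")
    if (any(cs > 1.5)) {                 # counts (probability columns sum to ~1)
        x <- x + pseudocount
    } else {                             # probabilities
        x <- sweep(x, 2, cs, "/")
        x[x < floor_prob] <- floor_prob
    }
    sweep(x, 2, colSums(x), "/")
}

#' @describeIn MotifSet number of motifs.
#' @param x a MotifSet.
#' @export
setMethod("length", "MotifSet", function(x) length(x@motifs))

#' @describeIn MotifSet motif ids.
#' @export
setMethod("names", "MotifSet", function(x) names(x@motifs))

#' @describeIn MotifSet TF name per motif (named by motif id).
#' @export
setMethod("tfNames", "MotifSet", function(x) x@tfName)

#' @describeIn MotifSet width per motif (named by motif id).
#' @export
setMethod("motifWidths", "MotifSet",
          function(x) vapply(x@motifs, ncol, integer(1)))

#' @describeIn MotifSet consensus sequence per motif (most probable base at
#'   each position).
#' @export
setMethod("motifConsensus", "MotifSet", function(x) {
    vapply(x@motifs, function(m) {
        paste(rownames(m)[apply(m, 2, which.max)], collapse = "")
    }, character(1))
})

#' @export
setMethod("[", "MotifSet", function(x, i, j, ..., drop = TRUE) {
    MotifSet(x@motifs[i], tfName = x@tfName[i])
})

#' @export
setMethod("[[", "MotifSet", function(x, i) x@motifs[[i]])

setMethod("show", "MotifSet", function(object) {
    w <- motifWidths(object)
    cat("MotifSet:", length(object), "motifs,",
        length(unique(object@tfName)), "TFs, widths",
        if (length(w)) paste0(min(w), "-", max(w)) else "-", "\n")
    invisible(NULL)
})
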