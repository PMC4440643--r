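#' Scan parameters for motif presence calling
#'
#' @param p_threshold per-window exact p-value cutoff; a window counts as a
#'   motif occurrence when the probability (under the background) of a
#'   score at least as high is strictly below this (default 1e-4).
#' @param background \code{"uniform"} (0.25 per base, default) or
#'   \code{"zero_order_from_regions"} (base frequencies estimated from the
#'   scanned regions).
#' @param granularity score discretisation step in bits for the exact null
#'   distribution (default 1e-4); the tail-probability error is bounded by
#'   motif width x granularity.
#' @return list of class \code{"ScanParams"}.
#' @export
scanParams <- function(p_threshold = 1e-4,
                       background = c("uniform", "zero_order_from_regions"),
                       granularity = 1e-4) {
    if (p_threshold <= 0 || p_threshold >= 1)
        stop("p_threshold must lie in (0, 1)")
    structure(list(p_threshold = p_threshold,
                   background = match.arg(background),
                   granularity = granularity),
              class = "ScanParams")
}

#' Build a log-odds scoring matrix from a PWM
#'
#' score(i, b) = log2(p_i(b) / q(b)).  All entries are finite because PWMs
#' are regularised to strictly positive probabilities on input.
#'
#' @param pwm 4 x width probability matrix (rows A, C, G, T, entries > 0).
#' @param background length-4 probability vector over A, C, G, T.
#' @param motif_id optional id carried through for reporting.
#' @return list of class \code{"LogOddsMatrix"}: motif_id, width, scores
#'   (4 x width, bits), background.
#' @export
buildLogOdds <- function(pwm, background = rep(0.25, 4), motif_id = NA_character_) {
    if (length(background) != 4L || any(background <= 0))
        stop("background must be 4 positive probabilities")
    background <- background / sum(background)
    if (any(pwm <= 0)) stop("PWM must be regularised (all probabilities > 0)")
    scores <- log2(sweep(pwm, 1, background, "/"))
    rownames(scores) <- .BASES
    structure(list(motif_id = motif_id, width = ncol(pwm),
                   scores = scores, background = background),
              class = "LogOddsMatrix")
}

# Integerised scores at the given granularity; row 5 (N or other) is a
# large negative value so any window containing N can never reach a
# threshold (the N-window skip rule).
.int_scores <- function(lom, granularity) {
    s <- round(lom$scores / granularity)
    rbind(s, N = -1e9)
}

# Exact null distribution of the integerised window score under the
# background (independent positions), by dynamic programming.
.exact_null_dist <- function(ints4, q) {
    w <- ncol(ints4)
    offset <- 0
    dist <- 1
    for (i in seq_len(w)) {
        v <- ints4[, i]
        mn <- min(v)
        offset <- offset + mn
        vv <- v - mn
        nd <- numeric(length(dist) + max(vv))
        for (b in 1:4) {
            rng <- seq_along(dist) + vv[b]
            nd[rng] <- nd[rng] + dist * q[b]
        }
        dist <- nd
    }
    list(offset = offset, probs = dist)  # P(S = offset + k - 1) = probs[k]
}

#' Exact p-value score threshold for a motif
#'
#' Computes the null distribution of the window log-odds score under the
#' background model (independent positions) by dynamic programming over
#' scores discretised at \code{granularity}, and returns the smallest
#' attainable score s with P(score >= s) < \code{p_threshold}.  Short or
#' low-information motifs may have no such score (e.g. a width-6 consensus
#' motif under the uniform background: even the best word has tail
#' 0.25^6 ~ 2.4e-4 >= 1e-4); these return an unattainable sentinel and can
#' never be called present.
#'
#' @param lom a [buildLogOdds()] result.
#' @param params a [scanParams()].
#' @return list of class \code{"ScoreThreshold"}: \code{int_threshold}
#'   (integerised score, \code{Inf} if unattainable), \code{score} (bits),
#'   \code{attainable}, \code{p_attained} (the actual tail probability at
#'   the threshold), \code{granularity}.
#' @export
exactScoreThreshold <- function(lom, params = scanParams()) {
    stopifnot(inherits(lom, "LogOddsMatrix"))
    ints <- .int_scores(lom, params$granularity)[1:4, , drop = FALSE]
    nd <- .exact_null_dist(ints, lom$background)
    tail <- rev(cumsum(rev(nd$probs)))
    sup_max <- max(which(nd$probs > 0))
    pass <- which(tail < params$p_threshold)
    pass <- pass[pass <= sup_max]
    if (!length(pass)) {
        thr <- structure(list(int_threshold = Inf, score = Inf,
                              attainable = FALSE, p_attained = NA_real_,
                              granularity = params$granularity),
                         class = "ScoreThreshold")
        return(thr)
    }
    i0 <- min(pass)
    int_thr <- nd$offset + i0 - 1
    structure(list(int_threshold = int_thr,
                   score = int_thr * params$granularity,
                   attainable = TRUE, p_attained = tail[i0],
                   granularity = params$granularity),
              class = "ScoreThreshold")
}

# Reverse-complement a 5 x w integer score matrix: scanning the forward
# sequence with this matrix equals scanning the reverse complement with the
# original.
.rc_int_scores <- function(ints) {
    ints[c(4, 3, 2, 1, 5), rev(seq_len(ncol(ints))), drop = FALSE]
}

# Vectorised presence scan over an n x L code matrix (codes 1..5).
.scan_code_matrix <- function(code, ints, int_thr) {
    n <- nrow(code); L <- ncol(code); w <- ncol(ints)
    present <- rep(FALSE, n)
    if (w > L || !is.finite(int_thr)) return(present)
    for (mat in list(ints, .rc_int_scores(ints))) {
        for (off in 0:(L - w)) {
            idx <- which(!present)
            if (!length(idx)) return(present)
            sc <- numeric(length(idx))
            for (i in seq_len(w))
                sc <- sc + mat[code[idx, off + i], i]
            present[idx] <- sc >= int_thr
        }
    }
    present
}

#' Motif presence in a single sequence
#'
#' TRUE iff any window of the sequence, on either strand, reaches the exact
#' p-value score threshold.  Windows containing N are skipped; an
#' unattainable threshold or a sequence shorter than the motif yields
#' FALSE.
#'
#' @param sequence character DNA string (A/C/G/T/N).
#' @param lom a [buildLogOdds()] result.
#' @param threshold an [exactScoreThreshold()] result.
#' @return logical scalar.
#' @export
scanRegionPresence <- function(sequence, lom, threshold) {
    stopifnot(inherits(threshold, "ScoreThreshold"))
    code <- .encode_seq_matrix(toupper(sequence))
    ints <- .int_scores(lom, threshold$granularity)
    .scan_code_matrix(code, ints, threshold$int_threshold)[1]
}

#' Boolean region x motif presence matrix
#'
#' Computes, for every motif, the exact score threshold at the configured
#' per-window p-value, then scans every region sequence on both strands.
#' The result is deterministic; overlapping matches within one region
#' collapse into a single TRUE.
#'
#' @param region_sequences named character vector (names = region ids, e.g.
#'   cpg ids) of equal-length sequences (unequal lengths are grouped and
#'   scanned per length).
#' @param motifs a \linkS4class{MotifSet}.
#' @param params a [scanParams()].
#' @return logical matrix regions x motifs with a \code{"thresholds"}
#'   attribute (data.frame: motif_id, tf_name, width, score_threshold,
#'   p_attained, attainable).
#' @export
buildPresenceMatrix <- function(region_sequences, motifs, params = scanParams()) {
    stopifnot(is(motifs, "MotifSet"), inherits(params, "ScanParams"))
    ids <- names(region_sequences)
    if (is.null(ids) || anyDuplicated(ids)) stop("region ids must be unique and named")
    seqs <- toupper(region_sequences)
    bg <- if (params$background == "uniform") rep(0.25, 4) else {
        cnt <- colSums(Biostrings::letterFrequency(DNAStringSet(seqs),
                                                   letters = .BASES)) + 1
        cnt / sum(cnt)
    }
    by_len <- split(seq_along(seqs), nchar(seqs))
    codes <- lapply(by_len, function(i) .encode_seq_matrix(seqs[i]))

    out <- matrix(FALSE, nrow = length(seqs), ncol = length(motifs),
                  dimnames = list(ids, names(motifs)))
    thr_rows <- vector("list", length(motifs))
    for (j in seq_along(motifs@motifs)) {
        mid <- names(motifs)[j]
        lom <- buildLogOdds(motifs[[j]], background = bg, motif_id = mid)
        thr <- exactScoreThreshold(lom, params)
        ints <- .int_scores(lom, params$granularity)
        for (k in seq_along(codes))
            out[by_len[[k]], j] <- .scan_code_matrix(codes[[k]], ints,
                                                     thr$int_threshold)
        thr_rows[[j]] <- data.frame(motif_id = mid,
                                    tf_name = unname(tfNames(motifs)[mid]),
                                    width = lom$width,
                                    score_threshold = thr$score,
                                    p_attained = thr$p_attained,
                                    attainable = thr$attainable)
    }
    attr(out, "thresholds") <- do.call(rbind, thr_rows)
    out
}
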