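#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric point probabilities (margins fixed) of every
#' table at most as probable as the observed one, with the conventional
#' (1 + 1e-7) relative tolerance on "at most as probable".  Computed in log
#' space, so tables with N around 1e5 are safe.  Any zero margin carries no
#' information and returns p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts: a = foreground with
#'   motif, b = foreground without, c = background with, d = background
#'   without.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherTwoSided(3, 1, 1, 3)   # 34/70
#' @export
fisherTwoSided <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
        stop("cell counts must be non-negative integers")
    m1 <- a + b; m2 <- c + d; k <- a + c
    if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
    lo <- max(0, k - m2); hi <- min(k, m1)
    xs <- lo:hi
    ld <- dhyper(xs, m1, m2, k, log = TRUE)
    lobs <- dhyper(a, m1, m2, k, log = TRUE)
    p <- sum(exp(ld[ld <= lobs + log1p(1e-7)]))
    min(1, max(p, exp(lobs)))
}

#' Relative enrichment of a motif
#'
#' Ratio of motif-presence proportions, foreground over background:
#' (a / (a + b)) / (c / (c + d)).  Values above 1 mean enrichment, below 1
#' depletion.  A motif present in the foreground but absent from the whole
#' background returns +Inf (flagged by the caller).
#'
#' @inheritParams fisherTwoSided
#' @return non-negative ratio (possibly Inf, or NaN when absent from both).
#' @export
relativeEnrichment <- function(a, b, c, d) {
    if ((a + b) == 0 || (c + d) == 0) stop("empty foreground or background")
    (a / (a + b)) / (c / (c + d))
}

#' Motif enrichment of a foreground region set versus background
#'
#' For each motif, builds the 2x2 presence table over the disjoint
#' foreground and background region sets, computes the two-sided Fisher
#' p-value and the relative enrichment, and BH-adjusts across the motif
#' family (m = number of motifs tested).  Motifs absent from every region
#' have a zero margin: reported flat with p = 1 and undefined (NA) relative
#' enrichment.
#'
#' @param presence logical region x motif matrix from
#'   [buildPresenceMatrix()].
#' @param foreground_ids,background_ids disjoint, non-empty sets of region
#'   ids (rownames of \code{presence}).
#' @param motifs optional \linkS4class{MotifSet} supplying TF names.
#' @param analysis label stored in the result (e.g. "ER-:protective").
#' @return data.frame ordered by adjusted then raw p then motif id:
#'   motif_id, tf_name, a, b, c, d, relative_enrichment, raw_p, adjusted_p,
#'   direction in \{enriched, depleted, flat\}, analysis.
#' @export
motifEnrichment <- function(presence, foreground_ids, background_ids,
                            motifs = NULL, analysis = NA_character_) {
    if (!length(foreground_ids) || !length(background_ids))
        stop("foreground and background must be non-empty")
    if (length(intersect(foreground_ids, background_ids)))
        stop("foreground and background overlap")
    missing_ids <- setdiff(c(foreground_ids, background_ids), rownames(presence))
    if (length(missing_ids))
        stop("region id(s) absent from presence matrix: ",
             paste(head(missing_ids, 5), collapse = ", "))
    fg <- presence[foreground_ids, , drop = FALSE]
    bg <- presence[background_ids, , drop = FALSE]
    a <- colSums(fg); b <- nrow(fg) - a
    cc <- colSums(bg); d <- nrow(bg) - cc
    re <- (a / (a + b)) / (cc / (cc + d))
    re[a > 0 & cc == 0] <- Inf
    re[a == 0 & cc == 0] <- NA_real_
    raw_p <- mapply(fisherTwoSided, a, b, cc, d)
    adj <- bhAdjust(raw_p)
    direction <- ifelse(is.na(re), "flat",
                 ifelse(re > 1, "enriched", ifelse(re < 1, "depleted", "flat")))
    tf <- if (!is.null(motifs)) unname(tfNames(motifs)[colnames(presence)])
          else colnames(presence)
    out <- data.frame(motif_id = colnames(presence), tf_name = tf,
                      a = unname(a), b = unname(b), c = unname(cc),
                      d = unname(d), relative_enrichment = unname(re),
                      raw_p = unname(raw_p), adjusted_p = unname(adj),
                      direction = direction, analysis = analysis,
                      stringsAsFactors = FALSE)
    out[order(out$adjusted_p, out$raw_p, out$motif_id), , drop = FALSE]
}

#' Truncate two scored CpG sets to a common size
#'
#' Power control for comparing enrichment between two CpG sets of unequal
#' size: both sets are cut to their n most significant CpGs, where n is the
#' smaller set size.  Ties at the boundary are broken by genomic coordinate
#' (chrom, pos) then cpg_id, deterministically.
#'
#' @param setA,setB data.frames with columns \code{cpg_id}, \code{p_value}
#'   and (for tie-breaking) optionally \code{chrom}, \code{pos}.
#' @return list with elements \code{A} and \code{B}, each of n rows.
#' @export
matchSetSizes <- function(setA, setB) {
    if (!NROW(setA) || !NROW(setB)) stop("empty CpG set")
    n <- min(nrow(setA), nrow(setB))
    top_n <- function(s) {
        chrom <- if ("chrom" %in% colnames(s)) s$chrom else ""
        pos <- if ("pos" %in% colnames(s)) s$pos else 0
        s[order(s$p_value, chrom, pos, s$cpg_id)[seq_len(n)], , drop = FALSE]
    }
    list(A = top_n(setA), B = top_n(setB))
}
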