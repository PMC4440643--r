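#' Build 102-bp regions centred on selected CpGs
#'
#' The window decomposes as 50 bp flank + CG dinucleotide + 50 bp flank:
#' for a 1-based C position p the region is [p - 51, p + 51) in 0-based
#' half-open coordinates, i.e. GRanges start p - 50, end p + 51.  Windows
#' are never clipped: CpGs whose window would leave the chromosome are
#' dropped (with a warning count) so every scanned region has identical
#' length and identical motif-presence probability under the null.
#'
#' @param selected data.frame with columns \code{cpg_id}, \code{p_value}
#'   and optionally \code{category} (selection p from the upstream screen).
#' @param annotation CpG annotation data.frame (cpg_id, chrom, pos, strand).
#' @param genome \code{DNAStringSet}; supplies chromosome lengths.
#' @return \code{GRanges} of width-102 regions with mcols \code{cpg_id},
#'   \code{p_value}, \code{category}, sorted by coordinate.
#' @export
makeRegions <- function(selected, annotation, genome) {
    selected <- as.data.frame(selected)
    stopifnot(all(c("cpg_id", "p_value") %in% colnames(selected)))
    idx <- match(selected$cpg_id, annotation$cpg_id)
    if (anyNA(idx))
        stop("CpG(s) absent from annotation: ",
             paste(head(selected$cpg_id[is.na(idx)], 5), collapse = ", "))
    ann <- annotation[idx, , drop = FALSE]
    unknown <- setdiff(unique(ann$chrom), names(genome))
    if (length(unknown))
        stop("CpG on unknown chromosome: ", paste(unknown, collapse = ", "))
    lens <- setNames(width(genome), names(genome))
    start1 <- ann$pos - 50L
    end1 <- ann$pos + 51L
    ok <- start1 >= 1L & end1 <= lens[ann$chrom]
    if (any(!ok))
        warning(sprintf("%d CpG(s) dropped: 102-bp window exits chromosome",
                        sum(!ok)))
    ann <- ann[ok, , drop = FALSE]
    selected <- selected[ok, , drop = FALSE]
    gr <- GRanges(ann$chrom, IRanges(start1[ok], end1[ok]), strand = ann$strand,
                  cpg_id = selected$cpg_id, p_value = selected$p_value,
                  category = if ("category" %in% colnames(selected))
                      selected$category else NA_character_)
    gr[order(as.character(seqnames(gr)), start(gr), gr$cpg_id)]
}

#' Greedy removal of overlapping CpG regions
#'
#' Within each (chromosome, strand) pair, regions are grouped into connected
#' components of the interval-overlap graph; within each component the
#' region with the smallest selection p-value is kept as the reference, all
#' regions overlapping it are discarded, and the rule is repeated on the
#' remainder until the component is exhausted.  Regions on different
#' chromosomes or strands never conflict.  Ties in p are broken by smaller
#' start coordinate, then lexicographic cpg_id, so the output is
#' deterministic.  The result is pairwise non-overlapping per (chromosome,
#' strand) and the operation is idempotent.
#'
#' @param regions \code{GRanges} from [makeRegions()] (mcols must carry
#'   \code{p_value} and \code{cpg_id}).
#' @return the kept \code{GRanges}, coordinate-sorted.
#' @export
filterOverlappingRegions <- function(regions) {
    if (!length(regions)) return(regions)
    chr <- as.character(seqnames(regions))
    str <- as.character(strand(regions))
    st <- start(regions); en <- end(regions)
    p <- regions$p_value; id <- regions$cpg_id
    keep_idx <- integer()
    for (grp in split(seq_along(regions), paste(chr, str))) {
        o <- grp[order(st[grp])]
        # connected components via running max of interval ends
        run_end <- cummax(en[o])
        comp <- cumsum(c(TRUE, st[o][-1] > head(run_end, -1)))
        for (members in split(o, comp)) {
            cand <- members
            while (length(cand)) {
                best <- cand[order(p[cand], st[cand], id[cand])][1]
                keep_idx <- c(keep_idx, best)
                overlaps <- st[cand] <= en[best] & en[cand] >= st[best]
                cand <- cand[!overlaps]
            }
        }
    }
    out <- regions[sort(keep_idx)]
    out[order(as.character(seqnames(out)), start(out), out$cpg_id)]
}

#' Extract region sequences
#'
#' Returns the plus-strand genomic substring for every region, regardless
#' of the region's strand annotation: motif scanning is strand-symmetric,
#' so minus-strand regions need no reverse complement.
#'
#' @param regions \code{GRanges} within chromosome bounds.
#' @param genome \code{DNAStringSet}.
#' @return named character vector (names = cpg_id), uppercase, N allowed.
#' @export
extractRegionSequences <- function(regions, genome) {
    chr <- as.character(seqnames(regions))
    lens <- setNames(width(genome), names(genome))
    if (any(start(regions) < 1L | end(regions) > lens[chr]))
        stop("region out of chromosome bounds")
    out <- character(length(regions))
    for (ch in unique(chr)) {
        i <- which(chr == ch)
        v <- Biostrings::extractAt(genome[[ch]],
                                   IRanges(start(regions)[i], end(regions)[i]))
        out[i] <- as.character(v)
    }
    names(out) <- regions$cpg_id
    out
}
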