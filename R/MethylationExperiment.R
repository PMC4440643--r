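#' Construct a MethylationExperiment
#'
#' Validates and aligns a beta-value matrix, a CpG annotation table and a
#' clinical table into a single \linkS4class{MethylationExperiment}.
#'
#' Samples present in the beta matrix but absent from the clinical table are
#' retained (their clinical columns become \code{NA}) and reported with a
#' warning; survival screens later use only samples with complete clinical
#' information.  CpGs must all be annotated.
#'
#' @param beta numeric matrix, CpGs x samples, values in [0, 1] (NA allowed),
#'   with row and column names.
#' @param annotation data.frame with columns \code{cpg_id}, \code{chrom},
#'   \code{pos} (1-based coordinate of the C of the CpG) and \code{strand}
#'   (\code{"+"} or \code{"-"}).
#' @param clinical data.frame with columns \code{sample_id},
#'   \code{survival_time} (days, > 0), \code{event} (0/1) and any number of
#'   subtype label columns (e.g. \code{ER}).
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' beta <- matrix(c(.1, .9, .2, .8, .3, .7), 2,
#'                dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
#' ann  <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "chr1",
#'                    pos = c(100L, 400L), strand = "+")
#' cli  <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                    survival_time = c(100, 200, 300), event = c(1, 0, 1))
#' me <- MethylationExperiment(beta, ann, cli)
#' dim(me)
#' @export
MethylationExperiment <- function(beta, annotation, clinical) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("beta matrix must have CpG row names and sample column names")
    bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("beta value out of [0, 1] at CpG '%s', sample '%s' (value %g)",
                     rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                     beta[bad[1, , drop = FALSE]]))
    if (anyDuplicated(rownames(beta))) stop("duplicate CpG ids in beta matrix")
    if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in beta matrix")

    annotation <- as.data.frame(annotation)
    need <- c("cpg_id", "chrom", "pos", "strand")
    if (!all(need %in% colnames(annotation)))
        stop("annotation needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(annotation$cpg_id)) stop("duplicate CpG ids in annotation")
    missing_ann <- setdiff(rownames(beta), annotation$cpg_id)
    if (length(missing_ann))
        stop("CpGs missing from annotation: ", paste(head(missing_ann, 5), collapse = ", "))
    ann <- annotation[match(rownames(beta), annotation$cpg_id), , drop = FALSE]

    clinical <- as.data.frame(clinical)
    if (!all(c("sample_id", "survival_time", "event") %in% colnames(clinical)))
        stop("clinical needs columns: sample_id, survival_time, event")
    if (anyDuplicated(clinical$sample_id)) stop("duplicate sample ids in clinical table")
    ev <- clinical$event[!is.na(clinical$event)]
    if (!all(ev %in% c(0, 1))) stop("clinical event must be 0/1")
    tt <- clinical$survival_time[!is.na(clinical$survival_time)]
    if (any(tt <= 0)) stop("clinical survival_time must be > 0")
    unmatched <- setdiff(colnames(beta), clinical$sample_id)
    if (length(unmatched))
        warning(sprintf("%d sample(s) in beta matrix without clinical data: %s",
                        length(unmatched), paste(head(unmatched, 5), collapse = ", ")))
    cli <- clinical[match(colnames(beta), clinical$sample_id), , drop = FALSE]
    cli$sample_id <- colnames(beta)
    rownames(cli) <- colnames(beta)

    rd <- DataFrame(chrom = as.character(ann$chrom), pos = as.integer(ann$pos),
                    strand = as.character(ann$strand), row.names = rownames(beta))
    se <- SummarizedExperiment(assays = list(beta = beta), rowData = rd,
                               colData = DataFrame(cli))
    new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment the beta-value matrix (CpGs x samples).
#' @param x a MethylationExperiment.
#' @export
setMethod("betaValues", "MethylationExperiment",
          function(x) assay(x, "beta"))

#' @describeIn MethylationExperiment the CpG annotation as a data.frame with
#'   columns cpg_id, chrom, pos, strand.
#' @export
setMethod("cpgInfo", "MethylationExperiment", function(x) {
    rd <- rowData(x)
    data.frame(cpg_id = rownames(x), chrom = rd$chrom, pos = rd$pos,
               strand = rd$strand, stringsAsFactors = FALSE)
})

#' @describeIn MethylationExperiment the clinical table as a data.frame.
#' @export
setMethod("clinicalInfo", "MethylationExperiment",
          function(x) as.data.frame(colData(x)))

setMethod("show", "MethylationExperiment", function(object) {
    cat("MethylationExperiment:", nrow(object), "CpGs x", ncol(object), "samples\n")
    n_ev <- sum(colData(object)$event == 1, na.rm = TRUE)
    cat("  events:", n_ev, " clinical columns:",
        paste(colnames(colData(object)), collapse = ", "), "\n")
    invisible(NULL)
})
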