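#' Load a methylation dataset from TSV files
#'
#' Reads the beta matrix, CpG annotation and clinical table (tab-separated,
#' header row, '.' decimal) and returns a validated
#' \linkS4class{MethylationExperiment}.  Samples present in the beta matrix
#' but missing from the clinical table are retained and reported with a
#' warning; range/uniqueness violations are errors naming the offending
#' entry.
#'
#' @param beta_path TSV with first column \code{cpg_id} and one column per
#'   sample.
#' @param annotation_path TSV with columns cpg_id, chrom, pos, strand.
#' @param clinical_path TSV with columns sample_id, survival_time, event,
#'   plus subtype columns.
#' @return A \linkS4class{MethylationExperiment}.
#' @seealso [MethylationExperiment()] for the validation contract,
#'   [writeSimulatedStudy()] which emits these formats.
#' @export
loadMethylationDataset <- function(beta_path, annotation_path, clinical_path) {
    b <- .read_tsv(beta_path)
    if (colnames(b)[1] != "cpg_id") stop("beta TSV must start with a cpg_id column")
    beta <- as.matrix(b[, -1, drop = FALSE])
    rownames(beta) <- b$cpg_id
    MethylationExperiment(beta, .read_tsv(annotation_path), .read_tsv(clinical_path))
}

#' Read position weight matrices
#'
#' Parses one of three common motif dialects into a \linkS4class{MotifSet}.
#' Count matrices (JASPAR PFM, TRANSFAC-style) get a pseudocount of 0.1 per
#' cell before normalisation; probability matrices (MEME minimal) are
#' floored at 1e-4 and renormalised, so downstream log-odds scores are
#' always finite.
#'
#' \describe{
#'   \item{meme}{MEME minimal text: \code{MOTIF id [altname]} headers
#'     followed by \code{letter-probability matrix:} blocks.}
#'   \item{jaspar_pfm}{\code{>id name} header then 4 count rows, either
#'     bare numbers or \code{A [ 1 2 3 ]} style.}
#'   \item{transfac_counts}{\code{ID}/\code{NA} fields and numbered count
#'     rows, records separated by \code{//}.}
#' }
#'
#' @param path motif file.
#' @param format one of \code{"meme"}, \code{"jaspar_pfm"},
#'   \code{"transfac_counts"}.
#' @param tf_map optional named character vector motif_id -> TF name,
#'   overriding names parsed from the file.
#' @return A \linkS4class{MotifSet}.
#' @export
readMotifs <- function(path, format = c("meme", "jaspar_pfm", "transfac_counts"),
                       tf_map = NULL) {
    format <- match.arg(format)
    lines <- readLines(path)
    ms <- switch(format,
                 meme = .parse_meme(lines),
                 jaspar_pfm = .parse_jaspar(lines),
                 transfac_counts = .parse_transfac(lines))
    if (!length(ms$mats)) stop("no motifs found in ", path)
    if (!is.null(tf_map)) {
        hit <- names(ms$mats) %in% names(tf_map)
        ms$tf[hit] <- tf_map[names(ms$mats)[hit]]
    }
    MotifSet(ms$mats, tfName = ms$tf)
}

.parse_meme <- function(lines) {
    mats <- list(); tf <- character()
    i <- 1L
    while (i <= length(lines)) {
        ln <- trimws(lines[i])
        if (startsWith(ln, "MOTIF")) {
            tok <- strsplit(ln, "\\s+")[[1]]
            id <- tok[2]
            alt <- if (length(tok) >= 3) tok[3] else id
            j <- i + 1L
            while (j <= length(lines) &&
                   !grepl("^letter-probability matrix", trimws(lines[j])))
                j <- j + 1L
            if (j > length(lines)) stop("MEME motif ", id, " has no matrix block")
            hdr <- trimws(lines[j])
            w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
            if (is.na(w) || w < 1L) stop("zero-width motif ", id)
            rows <- lines[(j + 1L):(j + w)]
            vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
            m <- t(do.call(rbind, vals))   # 4 x w, rows A,C,G,T
            rownames(m) <- .BASES
            mats[[id]] <- regularizePWM(m)
            tf[id] <- alt
            i <- j + w + 1L
        } else i <- i + 1L
    }
    list(mats = mats, tf = tf)
}

.parse_jaspar <- function(lines) {
    mats <- list(); tf <- character()
    hdr_idx <- grep("^>", lines)
    for (h in seq_along(hdr_idx)) {
        tok <- strsplit(sub("^>\\s*", "", lines[hdr_idx[h]]), "\\s+")[[1]]
        id <- tok[1]
        name <- if (length(tok) >= 2) tok[2] else id
        block_end <- if (h < length(hdr_idx)) hdr_idx[h + 1] - 1L else length(lines)
        rows <- lines[(hdr_idx[h] + 1L):block_end]
        rows <- rows[nzchar(trimws(rows))][1:4]
        counts <- lapply(rows, function(r) {
            r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
            r <- gsub("[][]", " ", r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1]])
        })
        if (length(unique(lengths(counts))) != 1L)
            stop("ragged JASPAR matrix for ", id)
        m <- do.call(rbind, counts)
        rownames(m) <- .BASES
        if (any(m < 0)) stop("negative count in JASPAR matrix ", id)
        mats[[id]] <- regularizePWM(m)
        tf[id] <- name
    }
    list(mats = mats, tf = tf)
}

.parse_transfac <- function(lines) {
    mats <- list(); tf <- character()
    recs <- split(lines, cumsum(c(TRUE, grepl("^//", head(lines, -1)))))
    for (rec in recs) {
        rec <- rec[!grepl("^//", rec)]
        if (!length(rec)) next
        id_ln <- grep("^(ID|AC)\\s", rec, value = TRUE)
        na_ln <- grep("^NA\\s", rec, value = TRUE)
        num <- grep("^\\d\\d\\s", rec, value = TRUE)
        if (!length(num)) next
        if (!length(id_ln)) stop("TRANSFAC record without ID/AC line")
        id <- strsplit(trimws(id_ln[1]), "\\s+")[[1]][2]
        name <- if (length(na_ln)) strsplit(trimws(na_ln[1]), "\\s+")[[1]][2] else id
        vals <- lapply(strsplit(trimws(num), "\\s+"), function(tok)
            as.numeric(tok[2:5]))
        m <- t(do.call(rbind, vals))
        rownames(m) <- .BASES
        if (anyNA(m)) stop("malformed TRANSFAC count row in ", id)
        if (any(m < 0)) stop("negative count in TRANSFAC matrix ", id)
        mats[[id]] <- regularizePWM(m)
        tf[id] <- name
    }
    list(mats = mats, tf = tf)
}

#' Write a MotifSet as a MEME minimal file
#'
#' @param motifs a \linkS4class{MotifSet}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMotifsMeme <- function(motifs, path) {
    stopifnot(is(motifs, "MotifSet"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
    tf <- tfNames(motifs)
    for (id in names(motifs)) {
        m <- motifs[[id]]
        writeLines(sprintf("MOTIF %s %s", id, tf[[id]]), con)
        writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                           ncol(m)), con)
        writeLines(apply(m, 2, function(p) paste(sprintf("%.6f", p), collapse = " ")),
                   con)
        writeLines("", con)
    }
    invisible(path)
}

#' Read a genome FASTA file
#'
#' Sequences are uppercased; characters outside A/C/G/T/N are mapped to N
#' with a warning giving the replacement count.
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet} named by record.
#' @export
readGenomeFasta <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    if (!length(raw)) stop("empty FASTA file: ", path)
    chr <- toupper(as.character(raw))
    n_bad <- sum(vapply(gregexpr("[^ACGTN]", chr), function(m)
        if (m[1] == -1L) 0L else length(m), integer(1)))
    if (n_bad > 0) {
        warning(sprintf("%d non-ACGTN character(s) replaced by N", n_bad))
        chr <- gsub("[^ACGTN]", "N", chr)
    }
    out <- DNAStringSet(chr)
    names(out) <- sub("\\s.*", "", names(raw))
    if (anyDuplicated(names(out))) stop("duplicate chromosome names in FASTA")
    out
}

#' Write CpG regions as BED6
#'
#' 0-based half-open coordinates; name = cpg_id, score = -log10(p) capped at
#' 999, strand from the region.
#'
#' @param regions a \code{GRanges} from [makeRegions()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRegionsBED <- function(regions, path) {
    score <- pmin(999, -log10(regions$p_value))  # p = 0 maps to the 999 cap
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = regions$cpg_id, score = sprintf("%.4g", score),
                     strand = as.character(strand(regions)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BED6 region file back into GRanges
#'
#' @param path BED6 file written by [writeRegionsBED()].
#' @return A \code{GRanges} with mcols \code{cpg_id} and \code{score}.
#' @export
readRegionsBED <- function(path) {
    df <- as.data.frame(data.table::fread(path, header = FALSE,
                                          col.names = c("chrom", "start", "end",
                                                        "name", "score", "strand"),
                                          showProgress = FALSE))
    GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand,
            cpg_id = df$name, score = as.numeric(df$score))
}

#' Write the result bundle of a pipeline run
#'
#' Deterministic, idempotent writer: regions as BED6, tabular results as
#' TSV with fixed column order, network as GraphML plus node/edge TSVs.
#'
#' @param results named list; recognised elements: \code{regions} (named
#'   list of GRanges), \code{tables} (named list of data.frames),
#'   \code{network} (a [buildSubnetwork()] result).
#' @param out_dir output directory (created if needed).
#' @return invisibly, character vector of files written.
#' @export
writeResultsBundle <- function(results, out_dir) {
    if (!dir.exists(out_dir)) {
        ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
    }
    written <- character()
    for (nm in names(results$regions)) {
        p <- file.path(out_dir, paste0("regions_", nm, ".bed"))
        writeRegionsBED(results$regions[[nm]], p)
        written <- c(written, p)
    }
    for (nm in names(results$tables)) {
        p <- file.path(out_dir, paste0(nm, ".tsv"))
        .write_tsv(results$tables[[nm]], p)
        written <- c(written, p)
    }
    if (!is.null(results$network)) {
        p <- file.path(out_dir, "network.graphml")
        writeNetworkGraphML(results$network, p)
        .write_tsv(results$network$nodes, file.path(out_dir, "network_nodes.tsv"))
        .write_tsv(results$network$edges, file.path(out_dir, "network_edges.tsv"))
        written <- c(written, p, file.path(out_dir, "network_nodes.tsv"),
                     file.path(out_dir, "network_edges.tsv"))
    }
    invisible(written)
}
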