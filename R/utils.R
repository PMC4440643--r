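# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

.BASES <- c("A", "C", "G", "T")

.revcomp_chr <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

# Encode sequences (equal length) as an n x L matrix of codes 1..5 (N/other = 5).
.encode_seq_matrix <- function(seqs) {
    L <- unique(nchar(seqs))
    stopifnot(length(L) == 1L)
    m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      c("A", "C", "G", "T")),
                nrow = length(seqs), ncol = L, byrow = TRUE)
    m[is.na(m)] <- 5L
    m
}

.write_tsv <- function(df, path) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) {
        out <- sprintf("%.12g", x)
        out[is.na(x)] <- "NA"
        out
    })
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                    na.strings = "NA", showProgress = FALSE))
}
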