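test_that("simulated study round-trips through the on-disk formats", {
    cfg <- tiny_config(seed = 21, n_cpgs = 80L, n_samples = 20L)
    study <- simulateMethylationStudy(cfg)
    dir <- withr::local_tempdir()
    paths <- writeSimulatedStudy(study, dir)
    me <- loadMethylationDataset(paths["beta"], paths["annotation"], paths["clinical"])
    expect_equal(betaValues(me), betaValues(study$experiment), tolerance = 1e-11)
    expect_identical(cpgInfo(me), cpgInfo(study$experiment))
    cli1 <- clinicalInfo(me); cli2 <- clinicalInfo(study$experiment)
    expect_identical(cli1$sample_id, cli2$sample_id)
    expect_equal(cli1$survival_time, cli2$survival_time, tolerance = 1e-11)
    expect_identical(cli1$event, cli2$event)
    g <- readGenomeFasta(paths["genome"])
    expect_identical(as.character(g), as.character(study$genome))
    ms <- readMotifs(paths["motifs"], format = "meme")
    expect_identical(names(ms), names(study$motifs))
    expect_identical(unname(tfNames(ms)), unname(tfNames(study$motifs)))
    for (id in names(ms))
        expect_equal(ms[[id]], study$motifs[[id]], tolerance = 2e-5)
})

test_that("beta/clinical validation errors name the offending entry", {
    beta <- matrix(c(.1, .9, 1.2, .8, .3, .7), 2,
                   dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
    ann <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "chr1",
                      pos = c(100L, 400L), strand = "+")
    cli <- data.frame(sample_id = c("s1", "s2", "s3"),
                      survival_time = c(100, 200, 300), event = c(1, 0, 1))
    expect_error(MethylationExperiment(beta, ann, cli), "cg1.*s2")
    beta2 <- beta; beta2[1, 2] <- 0.5
    cli_bad <- cli; cli_bad$event[2] <- 2
    expect_error(MethylationExperiment(beta2, ann, cli_bad), "event")
    ann_dup <- ann; ann_dup$cpg_id <- c("cg1", "cg1")
    rownames(beta2) <- c("cg1", "cg1")
    expect_error(MethylationExperiment(beta2, ann_dup, cli), "[Dd]uplicate")
    # sample missing from clinical: retained with a warning
    rownames(beta2) <- c("cg1", "cg2")
    expect_warning(me <- MethylationExperiment(beta2, ann, cli[1:2, ]),
                   "1 sample")
    expect_equal(ncol(me), 3L)
})

test_that("JASPAR counts get the 0.1-per-cell pseudocount", {
    f <- withr::local_tempfile(fileext = ".pfm")
    writeLines(c(">MA0001.1 TFX",
                 "A [ 10  0 ]",
                 "C [  0 10 ]",
                 "G [  0  0 ]",
                 "T [  0  0 ]"), f)
    ms <- readMotifs(f, format = "jaspar_pfm")
    expect_equal(unname(ms[["MA0001.1"]][, 1]),
                 c(10.1, 0.1, 0.1, 0.1) / 10.4, tolerance = 1e-12)
    expect_identical(unname(tfNames(ms)), "TFX")
})

test_that("TRANSFAC-style count records parse and bad rows error", {
    f <- withr::local_tempfile(fileext = ".dat")
    writeLines(c("ID T00001", "NA TFY", "P0  A  C  G  T",
                 "01  8  0  1  1  A", "02  0 10  0  0  C", "//"), f)
    ms <- readMotifs(f, format = "transfac_counts")
    expect_equal(motifWidths(ms)[["T00001"]], 2L)
    expect_equal(unname(ms[["T00001"]][, 2]), c(0.1, 10.1, 0.1, 0.1) / 10.4,
                 tolerance = 1e-12)
    # a column summing to zero is uninformative
    m0 <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4)
    expect_error(regularizePWM(m0), "0")
    expect_error(regularizePWM(matrix(-1, 4, 3)), "negative")
})

test_that("MEME minimal parsing returns the declared motifs", {
    f <- withr::local_tempfile(fileext = ".meme")
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "MOTIF M8 TF8",
                 "letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0",
                 rep("0.970000 0.010000 0.010000 0.010000", 8)), f)
    ms <- readMotifs(f, format = "meme")
    expect_equal(length(ms), 1L)
    expect_equal(motifWidths(ms)[["M8"]], 8L)
    expect_equal(motifConsensus(ms)[["M8"]], "AAAAAAAA")
})

test_that("genome FASTA reading normalises case and alphabet", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">chrA", "acgtACGT", ">chrB desc", "AARGT"), f)
    expect_warning(g <- readGenomeFasta(f), "1 non-ACGTN")
    expect_identical(as.character(g[["chrA"]]), "ACGTACGT")
    expect_identical(as.character(g[["chrB"]]), "AANGT")
    empty <- withr::local_tempfile(fileext = ".fa")
    writeLines(character(), empty)
    expect_error(readGenomeFasta(empty), "empty|no line")
})

test_that("BED output follows 0-based half-open convention and round-trips", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(950, 1051),
                                 strand = "+", cpg_id = "cgX", p_value = 1e-3)
    f <- withr::local_tempfile(fileext = ".bed")
    writeRegionsBED(gr, f)
    fields <- strsplit(readLines(f), "\t")[[1]]
    expect_identical(fields[1:4], c("chr1", "949", "1051", "cgX"))
    expect_equal(as.numeric(fields[5]), 3)        # -log10(1e-3)
    back <- readRegionsBED(f)
    expect_equal(IRanges::start(back), 950)
    expect_equal(IRanges::end(back), 1051)
})

test_that("results bundle writes are idempotent", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 201), strand = "+",
                                 cpg_id = "cg1", p_value = 0.01)
    tbl <- data.frame(motif_id = character(), raw_p = numeric())
    dir <- withr::local_tempdir()
    res <- list(regions = list(fg = gr), tables = list(enrichment = tbl))
    writeResultsBundle(res, dir)
    first <- vapply(list.files(dir, full.names = TRUE),
                    function(f) unname(tools::md5sum(f)), character(1))
    writeResultsBundle(res, dir)
    second <- vapply(list.files(dir, full.names = TRUE),
                     function(f) unname(tools::md5sum(f)), character(1))
    expect_identical(first, second)
    # empty table still yields a header-only TSV
    expect_identical(readLines(file.path(dir, "enrichment.tsv")), "motif_id\traw_p")
})
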