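test_that("generator is deterministic and CpG annotations are true CG sites", {
    cfg <- tiny_config(seed = 3)
    a <- simulateGenomeCpGs(cfg)
    b <- simulateGenomeCpGs(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$annotation, b$annotation)
    expect_equal(nrow(a$annotation), cfg$n_cpgs)

    g <- as.character(a$genome[[1]])
    dinuc <- substring(g, a$annotation$pos, a$annotation$pos + 1L)
    expect_true(all(dinuc == "CG"))
    # every 102-bp window fully inside the chromosome
    expect_true(all(a$annotation$pos - 51L >= 0L))
    expect_true(all(a$annotation$pos + 51L <= cfg$chrom_length))
})

test_that("requesting more CpGs than available CG sites errors with the shortfall", {
    cfg <- tiny_config(seed = 4, chrom_length = 500L, n_cpgs = 400L,
                       n_causal_survival_cpgs = 5L, n_diffmeth_cpgs = 5L)
    expect_error(simulateGenomeCpGs(cfg), "shortfall")
})

test_that("plants land inside the CpG window and are recoverable verbatim", {
    cfg <- tiny_config(seed = 5, plant_rate_foreground = 1, plant_rate_background = 0)
    gen <- simulateGenomeCpGs(cfg)
    mp <- simulateMotifsAndPlant(gen$genome, gen$annotation, cfg)
    plants <- mp$truth$plants
    expect_equal(nrow(plants), cfg$n_causal_survival_cpgs)
    expect_setequal(unique(plants$cpg_id), mp$truth$causal_cpg_ids)
    ann <- gen$annotation
    pos <- ann$pos[match(plants$cpg_id, ann$cpg_id)]
    w <- motifWidths(mp$motifs)[plants$motif_id]
    # plant lies within the 102-bp window [pos-50, pos+51]
    expect_true(all(plants$start >= pos - 50L))
    expect_true(all(plants$start + w - 1L <= pos + 51L))
    # overwrite semantics: sampled word (or its reverse complement) sits at
    # the recorded coordinate in the emitted genome
    g <- as.character(mp$genome)
    seen <- unname(substring(g[plants$chrom], plants$start, plants$start + w - 1L))
    expected <- ifelse(plants$strand == "-", rc_chr(plants$word), plants$word)
    # a later plant may overwrite an earlier one where windows overlap; every
    # plant not clobbered by a subsequent plant must be verbatim
    pe <- plants$start + w - 1L
    clobbered <- vapply(seq_len(nrow(plants)), function(i) {
        later <- seq_len(nrow(plants)) > i & plants$chrom == plants$chrom[i]
        any(later & plants$start <= pe[i] & pe >= plants$start[i])
    }, logical(1))
    expect_identical(seen[!clobbered], expected[!clobbered])
    expect_gt(mean(!clobbered), 0.5)
    # planted PWMs are high-information and wide enough to be callable
    ic <- vapply(mp$truth$planted_motif_ids, function(id) {
        m <- mp$motifs[[id]]
        mean(2 + colSums(m * log2(m)))
    }, numeric(1))
    expect_true(all(ic >= 1.5))
    expect_true(all(motifWidths(mp$motifs)[mp$truth$planted_motif_ids] >= 7L))
})

test_that("plant count concentrates at rate x causal count", {
    cfg <- tiny_config(seed = 6, n_cpgs = 1500L, chrom_length = 500000L,
                       n_causal_survival_cpgs = 1000L,
                       plant_rate_foreground = 0.6, plant_rate_background = 0)
    gen <- simulateGenomeCpGs(cfg)
    mp <- simulateMotifsAndPlant(gen$genome, gen$annotation, cfg)
    n <- nrow(mp$truth$plants)
    sd3 <- 3 * sqrt(1000 * 0.6 * 0.4)
    expect_gt(n, 600 - sd3)
    expect_lt(n, 600 + sd3)
})

test_that("null phenotypes are calibrated and censoring hits its target", {
    # no group effect: two-sample t p-values approximately uniform
    cfg <- tiny_config(seed = 7, n_cpgs = 800L, chrom_length = 250000L,
                       n_samples = 60L, diffmeth_effect = 0,
                       n_causal_survival_cpgs = 0L, n_diffmeth_cpgs = 100L)
    gen <- simulateGenomeCpGs(cfg)
    ph <- simulatePhenotypes(gen$annotation, NULL, cfg)
    me <- ph$experiment
    cli <- clinicalInfo(me)
    groups <- setNames(cli$group, cli$sample_id)
    dm <- diffMethylation(me, groups)
    ks <- suppressWarnings(stats::ks.test(dm$raw_p[dm$tested], "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_true(all(betaValues(me) >= 0 & betaValues(me) <= 1))
    # censoring within +/- 0.1 of target for n >= 200
    cfg2 <- tiny_config(seed = 8, n_samples = 250L, censoring_rate = 0.3)
    gen2 <- simulateGenomeCpGs(cfg2)
    mp2 <- simulateMotifsAndPlant(gen2$genome, gen2$annotation, cfg2)
    ph2 <- simulatePhenotypes(gen2$annotation, mp2$truth, cfg2)
    cens <- mean(clinicalInfo(ph2$experiment)$event == 0)
    expect_lt(abs(cens - 0.3), 0.1)
})

test_that("degenerate censoring targets warn", {
    x <- runif(50)
    expect_warning(simulateSurvivalData(x, 1, censoring_rate = 0, seed = 1),
                   "censoring")
    expect_warning(simulateSurvivalData(x, 1, censoring_rate = 1, seed = 1),
                   "censoring")
})

test_that("TF edge simulation respects edge probability and determinism", {
    cfg0 <- tiny_config(seed = 9, edge_probability = 0)
    expect_equal(nrow(simulateTFEdges(cfg0, c("A", "B", "C"))), 0L)
    cfg1 <- tiny_config(seed = 9, edge_probability = 1, n_tf_nodes = 4L)
    e <- simulateTFEdges(cfg1, c("A", "B", "C", "D"))
    expect_equal(nrow(e), 6L)                       # complete graph on 4 nodes
    expect_true(all(e$tf1 != e$tf2))
    cfg <- tiny_config(seed = 10, edge_probability = 0.3)
    expect_identical(simulateTFEdges(cfg, c("A", "B", "C")),
                     simulateTFEdges(cfg, c("A", "B", "C")))
})

test_that("full study bundle is reproducible for a fixed seed", {
    cfg <- tiny_config(seed = 12)
    s1 <- simulateMethylationStudy(cfg)
    s2 <- simulateMethylationStudy(cfg)
    expect_identical(as.character(s1$genome), as.character(s2$genome))
    expect_identical(betaValues(s1$experiment), betaValues(s2$experiment))
    expect_identical(clinicalInfo(s1$experiment), clinicalInfo(s2$experiment))
    expect_identical(s1$edges, s2$edges)
    expect_identical(s1$truth$plants, s2$truth$plants)
})
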