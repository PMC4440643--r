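test_that("Fisher p matches hand-enumerated tables", {
    expect_equal(fisherTwoSided(5, 5, 5, 5), 1)
    expect_equal(fisherTwoSided(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
    expect_equal(fisherTwoSided(10, 0, 0, 10), 2 / choose(20, 10),
                 tolerance = 1e-12)
    # zero margins carry no information
    expect_equal(fisherTwoSided(0, 5, 0, 5), 1)
    expect_equal(fisherTwoSided(0, 0, 3, 4), 1)
    expect_error(fisherTwoSided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p agrees with the enumeration oracle and fisher.test", {
    set.seed(401)
    for (rep in 1:300) {
        tab <- as.integer(sample(0:12, 4, replace = TRUE))
        p <- fisherTwoSided(tab[1], tab[2], tab[3], tab[4])
        expect_equal(p, bf_fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                     tolerance = 1e-10)
    }
    # large tables vs the reference implementation in stats
    for (rep in 1:50) {
        tab <- as.integer(sample(0:3000, 4, replace = TRUE))
        p <- fisherTwoSided(tab[1], tab[2], tab[3], tab[4])
        ft <- fisher.test(matrix(tab, 2))$p.value
        expect_equal(p, ft, tolerance = 1e-8)
    }
})

test_that("relative enrichment is a ratio of presence proportions", {
    expect_equal(relativeEnrichment(2, 8, 1, 9), 2)
    expect_equal(relativeEnrichment(3, 7, 6, 14), 1)
    expect_identical(relativeEnrichment(2, 8, 0, 10), Inf)
    expect_error(relativeEnrichment(0, 0, 1, 1), "empty")
    # RE > 1 iff a exceeds its hypergeometric expectation
    set.seed(402)
    for (rep in 1:100) {
        t4 <- sample(1:30, 4, replace = TRUE)
        a <- t4[1]; b <- t4[2]; cc <- t4[3]; d <- t4[4]
        re <- relativeEnrichment(a, b, cc, d)
        a_exp <- (a + b) * (a + cc) / (a + b + cc + d)
        if (re != 1) expect_identical(re > 1, a > a_exp)
    }
})

test_that("swapping foreground and background inverts RE and keeps p", {
    set.seed(403)
    for (rep in 1:50) {
        t4 <- sample(1:40, 4, replace = TRUE)
        re1 <- relativeEnrichment(t4[1], t4[2], t4[3], t4[4])
        re2 <- relativeEnrichment(t4[3], t4[4], t4[1], t4[2])
        expect_equal(re2, 1 / re1, tolerance = 1e-12)
        expect_equal(fisherTwoSided(t4[1], t4[2], t4[3], t4[4]),
                     fisherTwoSided(t4[3], t4[4], t4[1], t4[2]),
                     tolerance = 1e-12)
    }
})

make_presence <- function(n_fg, n_bg, p_fg, p_bg, n_motifs = 10, seed = 1) {
    set.seed(seed)
    ids <- c(sprintf("f%03d", seq_len(n_fg)), sprintf("b%03d", seq_len(n_bg)))
    pm <- matrix(FALSE, n_fg + n_bg, n_motifs,
                 dimnames = list(ids, sprintf("M%02d", seq_len(n_motifs))))
    for (j in seq_len(n_motifs)) {
        pf <- if (j == 1) p_fg else p_bg
        pm[, j] <- runif(n_fg + n_bg) < c(rep(pf, n_fg), rep(p_bg, n_bg))
    }
    pm
}

test_that("a planted enriched motif tops the enrichment table", {
    pm <- make_presence(200, 800, p_fg = 0.6, p_bg = 0.05, seed = 404)
    fg <- grep("^f", rownames(pm), value = TRUE)
    bg <- grep("^b", rownames(pm), value = TRUE)
    enr <- motifEnrichment(pm, fg, bg, analysis = "toy")
    expect_identical(enr$motif_id[1], "M01")
    expect_gt(enr$relative_enrichment[1], 1.5)
    expect_identical(enr$direction[1], "enriched")
    expect_true(all(enr$adjusted_p >= enr$raw_p - 1e-15))
    expect_equal(enr$a + enr$b, rep(length(fg), nrow(enr)))
    expect_equal(enr$c + enr$d, rep(length(bg), nrow(enr)))
    # errors on malformed inputs
    expect_error(motifEnrichment(pm, fg, c(bg, fg[1])), "overlap")
    expect_error(motifEnrichment(pm, character(), bg), "non-empty")
    expect_error(motifEnrichment(pm, c(fg, "zzz"), bg), "absent")
})

test_that("a motif absent everywhere is flat with p = 1", {
    pm <- make_presence(50, 50, 0.3, 0.3, n_motifs = 3, seed = 405)
    pm[, 2] <- FALSE
    enr <- motifEnrichment(pm, grep("^f", rownames(pm), value = TRUE),
                           grep("^b", rownames(pm), value = TRUE))
    row <- enr[enr$motif_id == "M02", ]
    expect_equal(row$raw_p, 1)
    expect_identical(row$direction, "flat")
    expect_true(is.na(row$relative_enrichment))
})

test_that("null enrichment p-values are roughly uniform", {
    set.seed(406)
    frac <- mean(replicate(200, {
        pm <- matrix(runif(1000 * 1) < 0.3, 1000, 1,
                     dimnames = list(sprintf("r%04d", 1:1000), "M"))
        fg <- sample(rownames(pm), 200)
        bg <- setdiff(rownames(pm), fg)
        motifEnrichment(pm, fg, bg)$raw_p < 0.05
    }))
    # Fisher is discrete and slightly conservative; the rate sits near but
    # below the nominal 0.05
    expect_gt(frac, 0.02)
    expect_lt(frac, 0.07)
})

test_that("set-size matching truncates both sets to the smaller n", {
    set.seed(407)
    A <- data.frame(cpg_id = sprintf("a%03d", 1:100), p_value = runif(100),
                    chrom = "chr1", pos = sample(1e5, 100))
    B <- data.frame(cpg_id = sprintf("b%03d", 1:60), p_value = runif(60),
                    chrom = "chr2", pos = sample(1e5, 60))
    m <- matchSetSizes(A, B)
    expect_equal(nrow(m$A), 60)
    expect_equal(nrow(m$B), 60)
    expect_true(all(m$A$p_value <= sort(A$p_value)[60] + 1e-15))
    m2 <- matchSetSizes(B, B)
    expect_equal(nrow(m2$A), 60)
    # boundary tie: deterministic choice by coordinate
    C <- data.frame(cpg_id = c("x", "y", "z"), p_value = c(0.1, 0.5, 0.5),
                    chrom = "chr1", pos = c(10L, 900L, 20L))
    D <- data.frame(cpg_id = c("u", "v"), p_value = c(0.2, 0.3),
                    chrom = "chr1", pos = c(1L, 2L))
    m3 <- matchSetSizes(C, D)
    expect_identical(m3$A$cpg_id, c("x", "z"))   # tie broken by pos 20 < 900
    expect_error(matchSetSizes(C[0, ], D), "empty")
})
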