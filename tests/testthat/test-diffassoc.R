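test_that("pooled Student t matches hand arithmetic and t.test on small groups", {
    # hand oracle: g1 = (.8,.7,.9), g2 = (.2,.3,.1), pooled variance, df = 4
    g1 <- c(.8, .7, .9); g2 <- c(.2, .3, .1)
    sp2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / 4
    t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    p_hand <- 2 * pt(-abs(t_hand), df = 4)
    beta <- matrix(c(g1, g2), nrow = 1,
                   dimnames = list("cg1", paste0("s", 1:6)))
    groups <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
    res <- diffMethylation(beta, groups, alpha = 0.05)
    expect_equal(res$statistic, t_hand, tolerance = 1e-12)
    expect_equal(res$raw_p, p_hand, tolerance = 1e-12)
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$raw_p, tt$p.value, tolerance = 1e-12)
    expect_identical(res$direction, "hyper")
})

test_that("row-wise t equals the t.test oracle on 100 random instances", {
    set.seed(101)
    for (rep in 1:4) {
        n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
        x <- matrix(runif(25 * (n1 + n2)), nrow = 25)
        colnames(x) <- paste0("s", seq_len(n1 + n2))
        rownames(x) <- paste0("cg", 1:25)
        groups <- setNames(rep(c("A", "B"), c(n1, n2)), colnames(x))
        res <- diffMethylation(x, groups)
        for (i in seq_len(25)) {
            tt <- t.test(x[i, 1:n1], x[i, n1 + 1:n2], var.equal = TRUE)
            expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
            expect_equal(res$raw_p[i], tt$p.value, tolerance = 1e-10)
        }
    }
})

test_that("degenerate and antisymmetric cases behave", {
    x <- matrix(rep(c(.4, .6), each = 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("cg1", "cg2"), paste0("s", 1:4)))
    groups <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
    res <- diffMethylation(x, groups)
    expect_equal(res$statistic, c(0, 0))
    expect_equal(res$raw_p, c(1, 1))
    expect_identical(res$direction, c("none", "none"))
    # swapping labels negates t, p unchanged
    set.seed(5)
    y <- matrix(runif(40), 5, dimnames = list(paste0("cg", 1:5), paste0("s", 1:8)))
    gA <- setNames(rep(c("A", "B"), each = 4), colnames(y))
    # same assignment, reversed level order: group 1 and group 2 swap roles
    rA <- diffMethylation(y, factor(gA, levels = c("A", "B")))
    rB <- diffMethylation(y, factor(gA, levels = c("B", "A")))
    expect_equal(rA$statistic, -rB$statistic, tolerance = 1e-12)
    expect_equal(rA$raw_p, rB$raw_p, tolerance = 1e-12)
    expect_error(diffMethylation(y, setNames(rep("A", 8), colnames(y))),
                 "2 labels")
})

test_that("CpGs with too few complete values are untested and excluded from BH", {
    x <- matrix(runif(16), 4, dimnames = list(paste0("cg", 1:4), paste0("s", 1:4)))
    x[1, 1:2] <- NA                       # group A has 0 complete samples
    groups <- setNames(c("A", "A", "B", "B"), colnames(x))
    res <- suppressWarnings(diffMethylation(x, groups))
    expect_false(res$tested[1])
    expect_true(all(res$tested[2:4]))
    expect_equal(res$adjusted_p[res$tested],
                 bf_bh_oracle(res$raw_p[res$tested]), tolerance = 1e-12)
})

test_that("Wilcoxon screen gives the exact enumeration p on tie-free groups", {
    expr <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:6)))
    groups <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
    de <- diffExpression(expr, groups)
    expect_equal(de$raw_p, 0.1, tolerance = 1e-12)   # most extreme of C(6,3)=20 splits
    expect_equal(de$fold_change, mean(1:3) / mean(4:6), tolerance = 1e-12)
    # same data through the methylation screen's wilcoxon method
    dm <- diffMethylation(expr / 10, groups, method = "wilcoxon")
    expect_equal(dm$raw_p, 0.1, tolerance = 1e-12)
    expect_identical(dm$direction, "none")
})

test_that("fold change is a plain ratio of means with an Inf sentinel", {
    expr <- rbind(gA = c(2, 4, 6, 1, 2, 3),
                  gB = c(5, 5, 5, 5, 5, 5),
                  gC = c(1, 2, 3, 0, 0, 0))
    colnames(expr) <- paste0("s", 1:6)
    groups <- setNames(rep(c("T", "N"), each = 3), colnames(expr))
    expect_warning(de <- diffExpression(expr, groups), "Inf")
    expect_equal(de$fold_change[1], 2, tolerance = 1e-12)
    expect_equal(de$fold_change[2], 1, tolerance = 1e-12)
    expect_equal(de$raw_p[2], 1)
    expect_identical(de$fold_change[3], Inf)
})

test_that("BH adjustment follows the step-up formula", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3), tolerance = 1e-12)
    expect_equal(bhAdjust(0.04), 0.04)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.1, 1.3)), "\\[0, 1\\]")
    set.seed(7)
    for (rep in 1:50) {
        p <- runif(sample(1:40, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bf_bh_oracle(p), tolerance = 1e-12)
        expect_true(all(adj >= p - 1e-15))
        expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in rank
    }
    # explicit m larger than the vector
    expect_equal(bhAdjust(c(0.01, 0.02), m = 4), bf_bh_oracle(c(0.01, 0.02), m = 4),
                 tolerance = 1e-12)
})

test_that("null simulation yields nominal raw rejection rates", {
    set.seed(42)
    x <- matrix(rbeta(10000 * 100, 2, 2), nrow = 10000,
                dimnames = list(sprintf("cg%05d", 1:10000), sprintf("s%03d", 1:100)))
    groups <- setNames(rep(c("A", "B"), each = 50), colnames(x))
    res <- diffMethylation(x, groups)
    frac <- mean(res$raw_p < 0.05)
    expect_gt(frac, 0.035)
    expect_lt(frac, 0.065)
})
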