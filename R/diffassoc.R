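#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: adjusted p_(i) = min over j >= i of
#' m * p_(j) / j, capped at 1.  Thin wrapper over \code{stats::p.adjust}
#' exposing the effective number of tests \code{m} (features that yielded no
#' p-value are excluded from \code{m} by the callers in this package).
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, passed through).
#' @param m number of tests (default \code{length(p)} after removing NA).
#' @return adjusted p-values, same order as input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))   # all 0.03
#' @export
bhAdjust <- function(p, m = sum(!is.na(p))) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    if (m < sum(!is.na(p))) stop("m must be >= number of non-missing p-values")
    p.adjust(p, method = "BH", n = m)
}

# Vectorised pooled-variance two-sample t over matrix rows; pairwise-complete.
.row_pooled_t <- function(x, g1, g2) {
    m1 <- !is.na(x[, g1, drop = FALSE]); m2 <- !is.na(x[, g2, drop = FALSE])
    n1 <- rowSums(m1); n2 <- rowSums(m2)
    x1 <- x[, g1, drop = FALSE]; x1[!m1] <- 0
    x2 <- x[, g2, drop = FALSE]; x2[!m2] <- 0
    s1 <- rowSums(x1); s2 <- rowSums(x2)
    mu1 <- s1 / n1; mu2 <- s2 / n2
    ss1 <- rowSums(x1^2) - n1 * mu1^2
    ss2 <- rowSums(x2^2) - n2 * mu2^2
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t <- (mu1 - mu2) / se
    t[se == 0 & mu1 == mu2] <- 0           # identical groups: no evidence
    p <- 2 * pt(-abs(t), df)
    p[t == 0] <- 1
    list(statistic = t, p = p, n1 = n1, n2 = n2, df = df)
}

# Welch variant, available behind the var_equal flag.
.row_welch_t <- function(x, g1, g2) {
    m1 <- !is.na(x[, g1, drop = FALSE]); m2 <- !is.na(x[, g2, drop = FALSE])
    n1 <- rowSums(m1); n2 <- rowSums(m2)
    x1 <- x[, g1, drop = FALSE]; x1[!m1] <- 0
    x2 <- x[, g2, drop = FALSE]; x2[!m2] <- 0
    mu1 <- rowSums(x1) / n1; mu2 <- rowSums(x2) / n2
    v1 <- (rowSums(x1^2) - n1 * mu1^2) / (n1 - 1)
    v2 <- (rowSums(x2^2) - n2 * mu2^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    t <- (mu1 - mu2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t[se2 == 0 & mu1 == mu2] <- 0
    p <- 2 * pt(-abs(t), df)
    p[t == 0] <- 1
    list(statistic = t, p = p, n1 = n1, n2 = n2, df = df)
}

.resolve_groups <- function(sample_ids, groups) {
    if (is.null(names(groups))) stop("groups must be a named vector (sample -> label)")
    g <- groups[sample_ids]
    lv <- if (is.factor(groups)) levels(groups) else unique(groups[!is.na(groups)])
    lv <- lv[lv %in% g]
    if (length(lv) != 2L) stop("groups must define exactly 2 labels among the samples")
    list(g1 = which(g == lv[1]), g2 = which(g == lv[2]), levels = lv)
}

#' Differential methylation screen
#'
#' Two-group per-CpG tests: pooled-variance two-tailed Student t (default;
#' Welch via \code{var_equal = FALSE}) or Wilcoxon rank-sum.  P-values are
#' BH-adjusted across all tested CpGs; CpGs with fewer than 2 complete
#' samples in either group are flagged untested and excluded from the BH
#' denominator.  Direction at adjusted p < alpha: \code{hyper} when group 1
#' exceeds group 2 (positive statistic), \code{hypo} when below.
#'
#' @param beta \linkS4class{MethylationExperiment} or CpG x sample matrix.
#' @param groups named vector sample -> group label (exactly two labels);
#'   the first level is "group 1" (e.g. ER+).
#' @param method \code{"student_t"} or \code{"wilcoxon"}.
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return data.frame: cpg_id, statistic (t, or rank-sum W with direction
#'   taken from W minus its null mean), raw_p, adjusted_p, direction in
#'   \{hyper, hypo, none\}, tested flag.
#' @export
diffMethylation <- function(beta, groups, method = c("student_t", "wilcoxon"),
                            alpha = 0.05, var_equal = TRUE) {
    method <- match.arg(method)
    x <- if (is(beta, "MethylationExperiment")) betaValues(beta) else as.matrix(beta)
    gr <- .resolve_groups(colnames(x), groups)
    if (!length(gr$g1) || !length(gr$g2)) stop("a group is empty")

    if (method == "student_t") {
        r <- if (var_equal) .row_pooled_t(x, gr$g1, gr$g2)
             else .row_welch_t(x, gr$g1, gr$g2)
        tested <- r$n1 >= 2 & r$n2 >= 2
        stat <- r$statistic; rawp <- r$p
        dir_stat <- stat
    } else {
        n <- nrow(x)
        stat <- rawp <- rep(NA_real_, n)
        tested <- logical(n)
        for (i in seq_len(n)) {
            a <- x[i, gr$g1]; b <- x[i, gr$g2]
            a <- a[!is.na(a)]; b <- b[!is.na(b)]
            if (length(a) < 2 || length(b) < 2) next
            if (length(unique(c(a, b))) == 1L) {
                stat[i] <- length(a) * length(b) / 2; rawp[i] <- 1
            } else {
                exact <- length(a) <= 25 && length(b) <= 25 &&
                    !anyDuplicated(c(a, b))
                wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
                stat[i] <- unname(wt$statistic)
                rawp[i] <- wt$p.value
            }
            tested[i] <- TRUE
        }
        # center W at its null mean so sign encodes direction like t
        n1 <- rowSums(!is.na(x[, gr$g1, drop = FALSE]))
        n2 <- rowSums(!is.na(x[, gr$g2, drop = FALSE]))
        dir_stat <- stat - n1 * n2 / 2
    }
    stat[!tested] <- NA_real_; rawp[!tested] <- NA_real_
    adj <- rep(NA_real_, length(rawp))
    adj[tested] <- bhAdjust(rawp[tested])
    direction <- rep("none", length(rawp))
    sig <- tested & !is.na(adj) & adj < alpha
    direction[sig & dir_stat > 0] <- "hyper"
    direction[sig & dir_stat < 0] <- "hypo"
    direction[!tested] <- NA_character_
    data.frame(cpg_id = rownames(x), statistic = stat, raw_p = rawp,
               adjusted_p = adj, direction = direction, tested = tested,
               stringsAsFactors = FALSE)
}

#' Differential expression screen
#'
#' Wilcoxon rank-sum per gene (exact for group sizes <= 25 without ties,
#' normal approximation with tie correction otherwise) plus fold change =
#' mean(group 1) / mean(group 2) on the provided scale (no implicit log;
#' set \code{log_input = TRUE} if the matrix is already log-scale, in which
#' case the fold change is computed on the anti-logged values).
#'
#' @param expr genes x samples numeric matrix.
#' @param groups named vector sample -> label (two labels).
#' @param log_input expression values are log2-scale.
#' @return data.frame: gene_id, statistic (W), raw_p, adjusted_p,
#'   fold_change, tested.
#' @export
diffExpression <- function(expr, groups, log_input = FALSE) {
    x <- as.matrix(expr)
    gr <- .resolve_groups(colnames(x), groups)
    if (!length(gr$g1) || !length(gr$g2)) stop("a group is empty")
    n <- nrow(x)
    stat <- rawp <- fc <- rep(NA_real_, n)
    tested <- logical(n)
    warn_zero <- FALSE
    xfc <- if (log_input) 2^x else x
    for (i in seq_len(n)) {
        a <- x[i, gr$g1]; b <- x[i, gr$g2]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2) next
        if (length(unique(c(a, b))) == 1L) {     # no variation at all
            stat[i] <- length(a) * length(b) / 2; rawp[i] <- 1
        } else {
            exact <- length(a) <= 25 && length(b) <= 25 &&
                !anyDuplicated(c(a, b))
            wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
            stat[i] <- unname(wt$statistic); rawp[i] <- wt$p.value
        }
        m2 <- mean(xfc[i, gr$g2], na.rm = TRUE)
        m1 <- mean(xfc[i, gr$g1], na.rm = TRUE)
        if (m2 == 0) { fc[i] <- Inf; warn_zero <- TRUE } else fc[i] <- m1 / m2
        tested[i] <- TRUE
    }
    if (warn_zero) warning("zero group-2 mean: fold change reported as Inf")
    adj <- rep(NA_real_, n)
    adj[tested] <- bhAdjust(rawp[tested])
    data.frame(gene_id = rownames(x), statistic = stat, raw_p = rawp,
               adjusted_p = adj, fold_change = fc, tested = tested,
               stringsAsFactors = FALSE)
}
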