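# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by enumeration / first principles and
# never call the package code paths they are used to check.

# -- PWM fixtures ------------------------------------------------------------

# High-information "consensus" PWM: dominant base 0.94, others 0.02.
consensus_pwm <- function(word) {
    b <- strsplit(word, "")[[1]]
    m <- matrix(0.02, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(b, rownames(m)), seq_along(b))] <- 0.94
    regularizePWM(m)
}

random_pwm <- function(w) {
    m <- matrix(rgamma(4 * w, 1), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
    regularizePWM(sweep(m, 2, colSums(m), "/"))
}

rc_chr <- function(x) chartr("ACGT", "TGCA",
                             vapply(strsplit(x, ""), function(s)
                                 paste(rev(s), collapse = ""), character(1)))

# -- motif scanning oracle: enumerate all 4^w words -------------------------

# Integerised scores, word probabilities and exact tail p per word.
bf_scan_oracle <- function(pwm, q = rep(0.25, 4), granularity = 1e-4) {
    w <- ncol(pwm)
    s <- round(log2(sweep(pwm, 1, q, "/")) / granularity)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- numeric(nrow(words)); pr <- rep(1, nrow(words))
    for (i in seq_len(w)) {
        sc <- sc + s[words[, i], i]
        pr <- pr * q[words[, i]]
    }
    mass <- tapply(pr, sc, sum)
    uniq <- as.numeric(names(mass))
    o <- order(uniq)
    uniq <- uniq[o]; mass <- as.numeric(mass)[o]
    tail_p <- rev(cumsum(rev(mass)))
    list(words = words, int_scores = sc, probs = pr,
         score_levels = uniq, level_mass = mass, level_tail = tail_p,
         word_tail = tail_p[match(sc, uniq)])
}

word_string <- function(codes) paste(c("A", "C", "G", "T")[codes], collapse = "")

# -- Fisher oracle: exhaustive fixed-margin enumeration ---------------------

bf_fisher_oracle <- function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
    if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
    xs <- max(0, k - m2):min(k, m1)
    pt <- choose(m1, xs) * choose(m2, k - xs) / choose(N, k)
    pobs <- choose(m1, a) * choose(m2, k - a) / choose(N, k)
    sum(pt[pt <= pobs * (1 + 1e-7)])
}

# -- overlap-filter oracle: quadratic global greedy per (chrom, strand) -----

bf_filter_oracle <- function(df) {
    kept <- character()
    for (key in unique(paste(df$chrom, df$strand))) {
        sub <- df[paste(df$chrom, df$strand) == key, , drop = FALSE]
        while (nrow(sub)) {
            o <- order(sub$p_value, sub$start, sub$cpg_id)
            best <- sub[o[1], ]
            kept <- c(kept, best$cpg_id)
            ov <- sub$start <= best$end & sub$end >= best$start
            sub <- sub[!ov, , drop = FALSE]
        }
    }
    sort(kept)
}

random_region_df <- function(n, chrom_n = 2, span = 3000) {
    if (n == 0)
        return(data.frame(cpg_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), p_value = numeric()))
    pos <- sample(52:(span - 52), n, replace = TRUE)
    data.frame(cpg_id = sprintf("r%03d", seq_len(n)),
               chrom = paste0("chr", sample.int(chrom_n, n, replace = TRUE)),
               strand = sample(c("+", "-"), n, replace = TRUE),
               start = pos - 50L, end = pos + 51L,
               p_value = round(runif(n), 3))
}

regions_to_granges <- function(df) {
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, cpg_id = df$cpg_id,
                           p_value = df$p_value)
}

# -- Cox partial-likelihood oracle (tie-free, all-subjects risk sets) -------

bf_cox_loglik <- function(beta, x, time, event) {
    o <- order(time)
    x <- x[o]; event <- event[o]
    n <- length(x)
    s <- 0
    for (i in seq_len(n))
        if (event[i] == 1)
            s <- s + beta * x[i] - log(sum(exp(beta * x[i:n])))
    s
}

# -- BH step-up oracle -------------------------------------------------------

bf_bh_oracle <- function(p, m = length(p)) {
    o <- order(p)
    ranked <- p[o] * m / seq_along(p)
    adj <- rev(cummin(rev(ranked)))
    pmin(1, adj)[order(o)]
}

# -- misc --------------------------------------------------------------------

tiny_config <- function(seed = 11, ...) {
    defaults <- list(seed = seed, n_chromosomes = 1L, chrom_length = 60000L,
                     n_samples = 60L, n_cpgs = 200L, n_motifs_decoy = 4L,
                     n_causal_survival_cpgs = 40L, n_diffmeth_cpgs = 40L,
                     n_tf_nodes = 10L)
    args <- utils::modifyList(defaults, list(...))
    do.call(simulationConfig, args)
}
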