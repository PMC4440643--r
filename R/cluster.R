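# k-means++ seeding: first center uniform, then points weighted by squared
# distance to the nearest chosen center.
.kmpp_centers <- function(x, k) {
    n <- nrow(x)
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    d2 <- colSums((t(x) - x[idx[1], ])^2)
    for (j in seq_len(k - 1L)) {
        if (all(d2 <= 0)) idx[j + 1L] <- sample(setdiff(seq_len(n), idx[seq_len(j)]), 1L)
        else idx[j + 1L] <- sample.int(n, 1L, prob = d2)
        d2 <- pmin(d2, colSums((t(x) - x[idx[j + 1L], ])^2))
    }
    x[idx, , drop = FALSE]
}

.impute_row_means <- function(x) {
    if (!anyNA(x)) return(x)
    rm <- rowMeans(x, na.rm = TRUE)
    rm[is.nan(rm)] <- 0.5          # all-missing row: neutral beta
    na <- which(is.na(x), arr.ind = TRUE)
    x[na] <- rm[na[, 1]]
    x
}

# One Lloyd run from k-means++ seeding; empty-cluster failures are retried
# with a fresh seeding draw.
.kmeans_once <- function(x, k, attempts = 5L) {
    for (t in seq_len(attempts)) {
        fit <- tryCatch(kmeans(x, centers = .kmpp_centers(x, k),
                               iter.max = 100L, algorithm = "Lloyd"),
                        error = function(e) NULL)
        if (!is.null(fit)) return(fit)
    }
    stop("k-means failed to find ", k, " non-empty clusters")
}

#' K-means clustering of CpGs by beta-value profiles
#'
#' Lloyd's algorithm with k-means++ seeding, best of \code{restarts}
#' independent starts by total within-cluster sum of squares (WCSS).
#' Missing beta-values are imputed by the CpG's row mean before clustering.
#' Cluster indices are relabelled in descending order of centroid mean
#' beta, so cluster 1 is always the most methylated.
#'
#' @param beta \linkS4class{MethylationExperiment} or CpG x sample matrix.
#' @param k number of clusters (1 <= k <= number of CpGs).
#' @param restarts independent k-means++ starts (default 10).
#' @param seed RNG seed; fixed seed gives identical assignments.
#' @return list of class \code{"ClusterResult"}: assignments (named 1..k),
#'   centroids (k x samples), wcss_total, wcss_per_cluster, k, restarts,
#'   seed.
#' @export
kmeansBeta <- function(beta, k, restarts = 10L, seed = NULL) {
    x <- if (is(beta, "MethylationExperiment")) betaValues(beta) else as.matrix(beta)
    if (!nrow(x) || !ncol(x)) stop("empty beta matrix")
    if (k < 1L || k > nrow(x)) stop("k must lie in 1..number of CpGs")
    x <- .impute_row_means(x)
    .with_seed(seed, {
        best <- NULL
        for (r in seq_len(restarts)) {
            fit <- .kmeans_once(x, k)
            if (is.null(best) || sum(fit$withinss) < sum(best$withinss))
                best <- fit
        }
        ord <- order(rowMeans(best$centers), decreasing = TRUE)
        relabel <- match(seq_len(k), ord)
        assignments <- setNames(relabel[best$cluster], rownames(x))
        centroids <- best$centers[ord, , drop = FALSE]
        rownames(centroids) <- paste0("C", seq_len(k))
        structure(list(assignments = assignments, centroids = centroids,
                       wcss_total = sum(best$withinss),
                       wcss_per_cluster = setNames(best$withinss[ord],
                                                   rownames(centroids)),
                       k = k, restarts = restarts, seed = seed),
                  class = "ClusterResult")
    })
}

#' @export
print.ClusterResult <- function(x, ...) {
    cat(sprintf("k-means: k=%d, %d CpGs, WCSS %.4g\n",
                x$k, length(x$assignments), x$wcss_total))
    print(table(cluster = x$assignments))
    invisible(x)
}

# WCSS of assigning rows of x to their nearest center (no Lloyd).
.assign_wcss <- function(x, centers) {
    d2 <- vapply(seq_len(nrow(centers)), function(j)
        colSums((t(x) - centers[j, ])^2), numeric(nrow(x)))
    sum(apply(d2, 1, min))
}

#' WCSS curve over a range of k
#'
#' Best-of-restarts total within-cluster sum of squares for k = 1..k_max,
#' for choosing k by the elbow rule.  Each k additionally warm-starts from
#' the previous k's centroids plus the point farthest from its centroid,
#' which guarantees a non-increasing curve.
#'
#' @inheritParams kmeansBeta
#' @param k_max largest k (default 10).
#' @return data.frame with columns \code{k} and \code{wcss}.
#' @export
wcssCurve <- function(beta, k_max = 10L, restarts = 10L, seed = NULL) {
    x <- if (is(beta, "MethylationExperiment")) betaValues(beta) else as.matrix(beta)
    x <- .impute_row_means(x)
    k_max <- min(k_max, nrow(x))
    .with_seed(seed, {
        wcss <- numeric(k_max)
        prev_centers <- NULL
        for (k in seq_len(k_max)) {
            best <- Inf
            best_fit <- NULL
            for (r in seq_len(restarts)) {
                fit <- .kmeans_once(x, k)
                if (sum(fit$withinss) < best) { best <- sum(fit$withinss); best_fit <- fit }
            }
            if (!is.null(prev_centers)) {
                d2 <- vapply(seq_len(nrow(prev_centers)), function(j)
                    colSums((t(x) - prev_centers[j, ])^2), numeric(nrow(x)))
                d2min <- if (is.matrix(d2)) apply(d2, 1, min) else d2
                warm <- rbind(prev_centers, x[which.max(d2min), ])
                wfit <- tryCatch(kmeans(x, centers = warm, iter.max = 100L,
                                        algorithm = "Lloyd"),
                                 error = function(e) NULL)
                wv <- if (!is.null(wfit)) sum(wfit$withinss)
                      else .assign_wcss(x, warm)
                if (wv < best) {
                    best <- wv
                    if (!is.null(wfit)) best_fit <- wfit
                }
            }
            wcss[k] <- best
            prev_centers <- if (!is.null(best_fit)) best_fit$centers else prev_centers
        }
        data.frame(k = seq_len(k_max), wcss = wcss)
    })
}
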