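#' Univariate Cox proportional-hazards fit
#'
#' Fits a single-covariate Cox model (Efron tie handling by default,
#' Newton-Raphson with tolerance 1e-9, at most 50 iterations) and reports
#' the Wald test of the coefficient.  Samples with a missing covariate,
#' time or event are dropped.  Monotone partial likelihood (perfect
#' separation) is flagged with \code{converged = FALSE} and a missing
#' p-value.
#'
#' @param x numeric covariate per sample (e.g. a CpG's beta-values).
#' @param time survival time (days, > 0).
#' @param event status, 1 = event, 0 = censored.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return list of class \code{"CoxFit"}: coefficient, se, hazard_ratio,
#'   wald_z, wald_p, n, n_events, converged.
#' @examples
#' set.seed(1)
#' x <- runif(80)
#' d <- simulateSurvivalData(x, gamma = 1, seed = 2)
#' coxFitUnivariate(x, d$survival_time, d$event)
#' @export
coxFitUnivariate <- function(x, time, event, ties = c("efron", "breslow")) {
    ties <- match.arg(ties)
    ok <- !(is.na(x) | is.na(time) | is.na(event))
    x <- as.numeric(x[ok]); time <- as.numeric(time[ok])
    event <- as.numeric(event[ok])
    if (sum(event) < 1) stop("no events")
    if (length(unique(x)) < 2L) stop("degenerate covariate (constant)")
    maxiter <- 50L
    fit <- suppressWarnings(
        coxph.fit(matrix(x, ncol = 1), Surv(time, event),
                  strata = NULL, offset = NULL, init = 0,
                  control = coxph.control(eps = 1e-9, iter.max = maxiter),
                  weights = NULL, method = ties, rownames = NULL))
    coef <- unname(fit$coefficients)
    v <- unname(fit$var[1, 1])
    se <- if (is.finite(v) && v >= 0) sqrt(v) else NaN
    converged <- is.finite(coef) && is.finite(se) && fit$iter < maxiter
    z <- coef / se
    p <- if (converged) 2 * pnorm(-abs(z)) else NA_real_
    out <- list(coefficient = coef, se = se, hazard_ratio = exp(coef),
                wald_z = z, wald_p = p, n = length(x),
                n_events = sum(event), converged = converged)
    class(out) <- "CoxFit"
    out
}

#' @export
print.CoxFit <- function(x, ...) {
    cat(sprintf("Cox fit: coef %.4f (se %.4f), HR %.3f, Wald p %.3g, %d/%d events%s\n",
                x$coefficient, x$se, x$hazard_ratio, x$wald_p,
                x$n_events, x$n,
                if (x$converged) "" else " [NOT CONVERGED]"))
    invisible(x)
}

#' Per-CpG univariate Cox survival screen
#'
#' Fits one univariate Cox model per CpG (beta-values as the covariate,
#' untransformed) within an optional sample stratum, and classifies each
#' CpG at unadjusted Wald p < \code{p_cut}: \code{protective} when the
#' hazard ratio is < 1, \code{hazardous} when > 1, otherwise \code{none}.
#' Samples missing time, event or the CpG's beta are dropped per CpG;
#' untestable CpGs (constant beta, no events after removal) are flagged and
#' excluded.
#'
#' @param me a \linkS4class{MethylationExperiment}.
#' @param stratum optional list(column =, value =) selecting samples whose
#'   clinical \code{column} equals \code{value}; NULL = all samples.
#' @param p_cut unadjusted Wald p cutoff defining categories (default 0.02,
#'   deliberately not multiplicity-adjusted).
#' @param min_samples,min_events floors on the stratum (defaults 20 and 5).
#' @param ties passed to [coxFitUnivariate()].
#' @return data.frame: cpg_id, coefficient, se, hazard_ratio, wald_z,
#'   wald_p, n, n_events, category, tested, stratum.
#' @export
screenSurvivalCpGs <- function(me, stratum = NULL, p_cut = 0.02,
                               min_samples = 20L, min_events = 5L,
                               ties = "efron") {
    stopifnot(is(me, "MethylationExperiment"))
    cli <- clinicalInfo(me)
    keep <- !is.na(cli$survival_time) & !is.na(cli$event)
    label <- "all"
    if (!is.null(stratum)) {
        col <- stratum$column
        if (!col %in% colnames(cli))
            stop("clinical table has no column '", col, "'; available: ",
                 paste(setdiff(colnames(cli), c("sample_id")), collapse = ", "))
        vals <- unique(cli[[col]][!is.na(cli[[col]])])
        if (!stratum$value %in% vals)
            stop("no samples with ", col, " = '", stratum$value,
                 "'; available labels: ", paste(vals, collapse = ", "))
        keep <- keep & !is.na(cli[[col]]) & cli[[col]] == stratum$value
        label <- paste0(col, "=", stratum$value)
    }
    if (sum(keep) < min_samples)
        stop(sprintf("stratum '%s' has %d samples (< %d required)",
                     label, sum(keep), min_samples))
    if (sum(cli$event[keep]) < min_events)
        stop(sprintf("stratum '%s' has %d events (< %d required)",
                     label, sum(cli$event[keep]), min_events))

    b <- betaValues(me)[, keep, drop = FALSE]
    time <- as.numeric(cli$survival_time[keep])
    event <- as.numeric(cli$event[keep])
    n_cpg <- nrow(b)
    coef <- se <- z <- p <- rep(NA_real_, n_cpg)
    nn <- nev <- rep(NA_integer_, n_cpg)
    tested <- logical(n_cpg)
    ctrl <- coxph.control(eps = 1e-9, iter.max = 50L)
    has_na <- anyNA(b)
    y_full <- Surv(time, event)
    for (i in seq_len(n_cpg)) {
        x <- b[i, ]
        if (has_na && anyNA(x)) {
            ok <- !is.na(x)
            xi <- x[ok]; yi <- Surv(time[ok], event[ok]); ei <- event[ok]
        } else { xi <- x; yi <- y_full; ei <- event }
        if (sum(ei) < 1 || length(unique(xi)) < 2L) next
        fit <- suppressWarnings(
            coxph.fit(matrix(xi, ncol = 1), yi, strata = NULL,
                      offset = NULL, init = 0, control = ctrl,
                      weights = NULL, method = ties, rownames = NULL))
        cf <- unname(fit$coefficients)
        v <- unname(fit$var[1, 1])
        s <- if (is.finite(v) && v >= 0) sqrt(v) else NaN
        if (!is.finite(cf) || !is.finite(s) || fit$iter >= 50L) next
        coef[i] <- cf; se[i] <- s; z[i] <- cf / s
        p[i] <- 2 * pnorm(-abs(cf / s))
        nn[i] <- length(xi); nev[i] <- sum(ei)
        tested[i] <- TRUE
    }
    category <- rep("none", n_cpg)
    category[tested & p < p_cut & exp(coef) < 1] <- "protective"
    category[tested & p < p_cut & exp(coef) > 1] <- "hazardous"
    category[!tested] <- NA_character_
    data.frame(cpg_id = rownames(b), coefficient = coef, se = se,
               hazard_ratio = exp(coef), wald_z = z, wald_p = p,
               n = nn, n_events = nev, category = category, tested = tested,
               stratum = label, stringsAsFactors = FALSE)
}
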