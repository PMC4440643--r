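#' Configuration for the synthetic methylation study generator
#'
#' Bundles every knob of the generator with validated defaults.  The default
#' sizes describe the study conditions used throughout the package's own
#' end-to-end experiments: two 1-Mb chromosomes, 10,000 CpGs, 300 samples,
#' 40 decoy plus 2 planted motifs, motif plant rates 0.6 (foreground) and
#' 0.05 (background), and 300 causal survival CpGs.
#'
#' @param seed integer RNG seed; every generator stage derives its own
#'   sub-seed from it so each stage is individually reproducible.
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param n_samples number of patient samples.
#' @param group_fractions named fractions per sample group (must sum to 1);
#'   the names become the levels of the clinical \code{group} column.
#' @param n_cpgs number of annotated CpG sites (true CG dinucleotides).
#' @param n_motifs_decoy,n_motifs_planted motif counts; planted motifs are
#'   high-information (>= 1.5 bits/column) and at least 7 bp wide.
#' @param motif_width_range integer \code{c(min, max)} motif width, >= 4.
#' @param plant_rate_foreground,plant_rate_background probability that a
#'   causal (resp. background) CpG's 102-bp window receives a planted motif
#'   occurrence.
#' @param n_causal_survival_cpgs CpGs whose methylation drives the hazard;
#'   by default the same set is the motif-planting foreground.
#' @param log_hazard_coefficient gamma: log hazard per unit beta.
#' @param baseline_hazard events per day at beta = 0.
#' @param censoring_rate target fraction of censored samples.
#' @param diffmeth_effect mean beta shift between the two sample groups at
#'   differential CpGs.
#' @param n_diffmeth_cpgs number of differentially methylated CpGs.
#' @param n_tf_nodes,edge_probability Erdos-Renyi TF-TF interaction graph.
#' @param n_clusters if > 0, CpG baseline methylation is drawn around
#'   \code{n_clusters} distinct levels (planted cluster structure);
#'   \code{cluster_sd} is the within-cluster beta standard deviation.
#' @param cluster_sd see \code{n_clusters}.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_length = 1e6,
                             n_samples = 300L,
                             group_fractions = c("ER+" = 0.77, "ER-" = 0.23),
                             n_cpgs = 10000L,
                             n_motifs_decoy = 40L,
                             n_motifs_planted = 2L,
                             motif_width_range = c(8L, 12L),
                             plant_rate_foreground = 0.6,
                             plant_rate_background = 0.05,
                             n_causal_survival_cpgs = 300L,
                             log_hazard_coefficient = 3,
                             baseline_hazard = 1 / 2000,
                             censoring_rate = 0.3,
                             diffmeth_effect = 0.15,
                             n_diffmeth_cpgs = 500L,
                             n_tf_nodes = 50L,
                             edge_probability = 0.08,
                             n_clusters = 0L,
                             cluster_sd = 0.05) {
    cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                chrom_length = as.integer(chrom_length),
                n_samples = as.integer(n_samples),
                group_fractions = group_fractions, n_cpgs = as.integer(n_cpgs),
                n_motifs_decoy = as.integer(n_motifs_decoy),
                n_motifs_planted = as.integer(n_motifs_planted),
                motif_width_range = as.integer(motif_width_range),
                plant_rate_foreground = plant_rate_foreground,
                plant_rate_background = plant_rate_background,
                n_causal_survival_cpgs = as.integer(n_causal_survival_cpgs),
                log_hazard_coefficient = log_hazard_coefficient,
                baseline_hazard = baseline_hazard,
                censoring_rate = censoring_rate,
                diffmeth_effect = diffmeth_effect,
                n_diffmeth_cpgs = as.integer(n_diffmeth_cpgs),
                n_tf_nodes = as.integer(n_tf_nodes),
                edge_probability = edge_probability,
                n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd)
    probs <- c(cfg$plant_rate_foreground, cfg$plant_rate_background,
               cfg$censoring_rate, cfg$edge_probability, cfg$group_fractions)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities/fractions must lie in [0, 1]")
    if (abs(sum(cfg$group_fractions) - 1) > 1e-9)
        stop("group_fractions must sum to 1")
    if (is.null(names(cfg$group_fractions)))
        stop("group_fractions must be named")
    if (length(cfg$motif_width_range) != 2L || any(cfg$motif_width_range < 4L))
        stop("motif widths must be >= 4")
    if (cfg$chrom_length <= 102L) stop("chrom_length must exceed 102")
    if (cfg$n_samples < 2L) stop("need at least 2 samples")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate a genome with annotated CpG sites
#'
#' Generates uniform-random chromosomes over A/C/G/T, then annotates
#' \code{n_cpgs} sites drawn (without replacement) from the genome's true CG
#' dinucleotides, restricted to positions whose 102-bp window lies fully
#' inside the chromosome.  Fixed seed gives byte-identical output.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{genome} (\code{DNAStringSet}) and
#'   \code{annotation} (data.frame: cpg_id, chrom, pos, strand), sorted by
#'   coordinate.
#' @export
simulateGenomeCpGs <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .with_seed(config$seed, {
        L <- config$chrom_length
        chroms <- paste0("chr", seq_len(config$n_chromosomes))
        genome <- DNAStringSet(vapply(chroms, function(ch)
            paste(sample(.BASES, L, replace = TRUE), collapse = ""),
            character(1)))
        names(genome) <- chroms
        hits <- vmatchPattern("CG", genome)
        cand <- do.call(rbind, lapply(chroms, function(ch) {
            p <- start(hits[[ch]])
            p <- p[p >= 51L & p <= L - 51L]
            if (length(p)) data.frame(chrom = ch, pos = p) else NULL
        }))
        if (is.null(cand) || nrow(cand) < config$n_cpgs)
            stop(sprintf(paste0("requested %d CpGs but only %d window-feasible ",
                                "CG dinucleotides exist (shortfall %d)"),
                         config$n_cpgs, NROW(cand),
                         config$n_cpgs - NROW(cand)))
        idx <- sort(sample.int(nrow(cand), config$n_cpgs))
        ann <- cand[idx, , drop = FALSE]
        ann <- ann[order(ann$chrom, ann$pos), , drop = FALSE]
        ann$cpg_id <- sprintf("cg%06d", seq_len(nrow(ann)))
        ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
        rownames(ann) <- NULL
        list(genome = genome,
             annotation = ann[, c("cpg_id", "chrom", "pos", "strand")])
    })
}

# Sample one sequence from a probability PWM.
.sample_pwm_word <- function(pwm) {
    paste(apply(pwm, 2, function(p) sample(.BASES, 1L, prob = p)),
          collapse = "")
}

#' Simulate motifs and plant occurrences into the genome
#'
#' Builds a motif set of random decoy PWMs (Dirichlet columns, moderate
#' information content) plus high-information planted PWMs (dominant base
#' probability 0.94 per column, >= 1.58 bits/column, width >= 7).  For each
#' causal CpG, with probability \code{plant_rate_foreground}, a sequence
#' sampled from a uniformly chosen planted PWM overwrites the genome at a
#' uniform offset inside the CpG's 102-bp window on a uniform strand
#' (reverse-complemented before insertion when minus); non-causal CpGs
#' receive plants at \code{plant_rate_background}.  Every plant is recorded
#' in the returned ground truth.
#'
#' @param genome,annotation output of [simulateGenomeCpGs()].
#' @param config a [simulationConfig()].
#' @return list with \code{motifs} (\linkS4class{MotifSet}), \code{genome}
#'   (modified \code{DNAStringSet}) and \code{truth} (list:
#'   \code{planted_motif_ids}, \code{causal_cpg_ids}, \code{plants}
#'   data.frame with chrom, start, strand, motif_id, cpg_id, word).
#' @export
simulateMotifsAndPlant <- function(genome, annotation, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .with_seed(config$seed + 1L, {
        wr <- config$motif_width_range
        if (max(wr) > 102L) stop("motif width > 102 cannot fit a 102-bp window")
        mats <- list(); tf <- character()
        for (j in seq_len(config$n_motifs_decoy)) {
            w <- sample(seq(wr[1], wr[2]), 1L)
            m <- matrix(stats::rgamma(4L * w, shape = 1), nrow = 4L)
            m <- sweep(m, 2, colSums(m), "/")
            rownames(m) <- .BASES
            id <- sprintf("DM%02d", j)
            mats[[id]] <- regularizePWM(m)
            tf[id] <- sprintf("DTF%02d", ceiling(j / 2))  # ~2 motifs per decoy TF
        }
        for (j in seq_len(config$n_motifs_planted)) {
            w <- max(7L, sample(seq(wr[1], wr[2]), 1L))
            m <- matrix(0.02, nrow = 4L, ncol = w, dimnames = list(.BASES, NULL))
            dom <- sample.int(4L, w, replace = TRUE)
            m[cbind(dom, seq_len(w))] <- 0.94
            id <- sprintf("PM%d", j)
            mats[[id]] <- regularizePWM(m)
            tf[id] <- sprintf("PTF%d", j)
        }
        motifs <- MotifSet(mats, tfName = tf)
        planted_ids <- grep("^PM", names(mats), value = TRUE)

        causal <- sort(sample(annotation$cpg_id, config$n_causal_survival_cpgs))
        is_causal <- annotation$cpg_id %in% causal
        plant_prob <- ifelse(is_causal, config$plant_rate_foreground,
                             config$plant_rate_background)
        gets_plant <- runif(nrow(annotation)) < plant_prob

        gchr <- as.character(genome)
        plants <- vector("list", sum(gets_plant))
        k <- 0L
        for (i in which(gets_plant)) {
            mid <- planted_ids[sample.int(length(planted_ids), 1L)]
            w <- ncol(mats[[mid]])
            word <- .sample_pwm_word(mats[[mid]])
            offset <- sample.int(102L - w + 1L, 1L) - 1L
            strand <- sample(c("+", "-"), 1L)
            start <- annotation$pos[i] - 50L + offset   # 1-based insert start
            ins <- if (strand == "-") .revcomp_chr(word) else word
            ch <- annotation$chrom[i]
            substr(gchr[[ch]], start, start + w - 1L) <- ins
            k <- k + 1L
            plants[[k]] <- data.frame(chrom = ch, start = start, strand = strand,
                                      motif_id = mid,
                                      cpg_id = annotation$cpg_id[i], word = word)
        }
        plants <- if (k) do.call(rbind, plants)
                  else data.frame(chrom = character(), start = integer(),
                                  strand = character(), motif_id = character(),
                                  cpg_id = character(), word = character())
        genome2 <- DNAStringSet(gchr)
        names(genome2) <- names(genome)
        list(motifs = motifs, genome = genome2,
             truth = list(planted_motif_ids = planted_ids,
                          causal_cpg_ids = causal, plants = plants))
    })
}

# Exponential censoring rate achieving (approximately) the target censored
# fraction given per-sample event rates lambda: mean(c / (c + lambda)) = target.
.censoring_rate_for <- function(lambda, target) {
    f <- function(lc) mean(exp(lc) / (exp(lc) + lambda)) - target
    exp(uniroot(f, lower = log(min(lambda)) - 20,
                upper = log(max(lambda)) + 20, tol = 1e-10)$root)
}

.sim_surv_times <- function(lambda, censoring_rate) {
    n <- length(lambda)
    t_event <- rexp(n, rate = lambda)
    if (censoring_rate <= 0) {
        if (censoring_rate == 0) warning("censoring_rate = 0: no censoring (degenerate)")
        t_cens <- rep(Inf, n)
    } else if (censoring_rate >= 1) {
        warning("censoring_rate = 1: all samples censored (degenerate)")
        t_cens <- rexp(n, rate = 1e6 * mean(lambda))
    } else {
        t_cens <- rexp(n, rate = .censoring_rate_for(lambda, censoring_rate))
    }
    data.frame(survival_time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
}

#' Simulate beta-values and right-censored survival outcomes
#'
#' Samples are split into groups per \code{group_fractions}.  Each sample
#' carries a latent methylation risk score m_j ~ Beta(4, 4); causal CpGs'
#' beta-values are drawn from Beta distributions centred on m_j
#' (concentration 60), so causal CpGs are mutually correlated through the
#' latent factor and the per-CpG survival screen can recover them.
#' Non-causal CpGs get independent Beta baselines; differential CpGs shift
#' their group-2 mean by \code{diffmeth_effect} (alternating sign).  The
#' hazard for sample j is \code{baseline_hazard * exp(gamma * mean beta over
#' causal CpGs)}; event times are exponential, censoring times are
#' exponential with rate tuned so the expected censored fraction matches
#' \code{censoring_rate}.
#'
#' @param annotation CpG annotation from [simulateGenomeCpGs()].
#' @param truth ground truth from [simulateMotifsAndPlant()], or \code{NULL}
#'   for no causal CpGs (null survival structure).
#' @param config a [simulationConfig()].
#' @return list with \code{experiment} (\linkS4class{MethylationExperiment})
#'   and \code{truth} (input truth extended with \code{diffmeth_cpg_ids},
#'   \code{diffmeth_direction} and \code{cluster_of_cpg}).
#' @export
simulatePhenotypes <- function(annotation, truth, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (is.null(truth)) truth <- list(causal_cpg_ids = character())
    .with_seed(config$seed + 2L, {
        n <- config$n_samples
        ncp <- nrow(annotation)
        sample_id <- sprintf("S%04d", seq_len(n))
        counts <- floor(config$group_fractions * n)
        counts[1] <- counts[1] + n - sum(counts)
        group <- rep(names(config$group_fractions), counts)

        causal <- which(annotation$cpg_id %in% truth$causal_cpg_ids)
        noncausal <- setdiff(seq_len(ncp), causal)

        cluster_of <- NULL
        if (config$n_clusters > 0L) {
            centers <- seq(0.1, 0.9, length.out = config$n_clusters)
            cl <- sample.int(config$n_clusters, ncp, replace = TRUE)
            mu <- centers[cl]
            kappa <- pmax(2, mu * (1 - mu) / config$cluster_sd^2 - 1)
            cluster_of <- setNames(cl, annotation$cpg_id)
        } else {
            mu <- runif(ncp, 0.05, 0.95)
            kappa <- rep(30, ncp)
        }

        n_dm <- min(config$n_diffmeth_cpgs, length(noncausal))
        dm <- sort(sample(noncausal, n_dm))
        dm_sign <- rep_len(c(1, -1), n_dm)   # alternate hyper/hypo

        mu_mat <- matrix(mu, nrow = ncp, ncol = n)
        if (n_dm) {
            g2 <- group == names(config$group_fractions)[2]
            shift <- dm_sign * config$diffmeth_effect
            mu_mat[dm, g2] <- pmin(0.98, pmax(0.02, mu[dm] + shift))
        }
        kap_mat <- matrix(kappa, nrow = ncp, ncol = n)

        m_latent <- rbeta(n, 4, 4)
        if (length(causal)) {
            mu_mat[causal, ] <- matrix(m_latent, nrow = length(causal),
                                       ncol = n, byrow = TRUE)
            kap_mat[causal, ] <- 60
        }
        beta <- matrix(rbeta(ncp * n, mu_mat * kap_mat, (1 - mu_mat) * kap_mat),
                       nrow = ncp, ncol = n,
                       dimnames = list(annotation$cpg_id, sample_id))

        risk <- if (length(causal)) colMeans(beta[causal, , drop = FALSE])
                else rep(0, n)
        lambda <- config$baseline_hazard *
            exp(config$log_hazard_coefficient * risk)
        surv <- .sim_surv_times(lambda, config$censoring_rate)

        clinical <- data.frame(sample_id = sample_id,
                               survival_time = surv$survival_time,
                               event = surv$event, group = group,
                               stringsAsFactors = FALSE)
        truth$diffmeth_cpg_ids <- annotation$cpg_id[dm]
        truth$diffmeth_direction <- setNames(ifelse(dm_sign > 0, "hyper_g2", "hypo_g2"),
                                             annotation$cpg_id[dm])
        truth$cluster_of_cpg <- cluster_of
        list(experiment = MethylationExperiment(beta, annotation, clinical),
             truth = truth)
    })
}

#' Simulate survival outcomes for a given covariate
#'
#' Convenience generator for calibration and parameter-recovery experiments:
#' hazard per sample is \code{baseline_hazard * exp(gamma * x)}, event times
#' are exponential, censoring is independent exponential tuned to the target
#' censored fraction.
#'
#' @param x numeric covariate per sample.
#' @param gamma log hazard per unit of \code{x}.
#' @param baseline_hazard baseline event rate (per day).
#' @param censoring_rate target censored fraction.
#' @param seed optional RNG seed.
#' @return data.frame with \code{survival_time} and \code{event}.
#' @export
simulateSurvivalData <- function(x, gamma, baseline_hazard = 1 / 2000,
                                 censoring_rate = 0.3, seed = NULL) {
    .with_seed(seed, .sim_surv_times(baseline_hazard * exp(gamma * x),
                                     censoring_rate))
}

#' Simulate an undirected TF-TF interaction edge list
#'
#' Erdos-Renyi graph over the supplied TF names (typically the motif set's
#' TFs) padded with unrelated TF nodes up to \code{n_tf_nodes}.
#'
#' @param config a [simulationConfig()].
#' @param tf_names TF names that must appear as nodes.
#' @return data.frame with columns \code{tf1}, \code{tf2}; no self-loops,
#'   no duplicate unordered pairs.
#' @export
simulateTFEdges <- function(config, tf_names = character()) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (config$edge_probability < 0 || config$edge_probability > 1)
        stop("edge_probability must lie in [0, 1]")
    .with_seed(config$seed + 3L, {
        nodes <- unique(tf_names)
        extra <- config$n_tf_nodes - length(nodes)
        if (extra > 0) nodes <- c(nodes, sprintf("NTF%02d", seq_len(extra)))
        if (length(nodes) < 2L) stop("need at least 2 TF nodes")
        pairs <- t(utils::combn(nodes, 2L))
        keep <- runif(nrow(pairs)) < config$edge_probability
        data.frame(tf1 = pairs[keep, 1], tf2 = pairs[keep, 2],
                   stringsAsFactors = FALSE)
    })
}

#' Simulate a complete synthetic methylation study
#'
#' Runs the four generator stages in order and returns the full input bundle
#' the analysis pipeline consumes, together with the planted ground truth.
#'
#' @param config a [simulationConfig()].
#' @return list of class \code{"MethylationStudy"}: \code{genome},
#'   \code{annotation}, \code{motifs}, \code{experiment}, \code{edges},
#'   \code{truth}, \code{config}.
#' @examples
#' cfg <- simulationConfig(seed = 7, n_chromosomes = 1, chrom_length = 50000,
#'                         n_samples = 40, n_cpgs = 150, n_motifs_decoy = 4,
#'                         n_causal_survival_cpgs = 30, n_diffmeth_cpgs = 40,
#'                         n_tf_nodes = 10)
#' study <- simulateMethylationStudy(cfg)
#' study$experiment
#' @export
simulateMethylationStudy <- function(config = simulationConfig()) {
    gen <- simulateGenomeCpGs(config)
    mp <- simulateMotifsAndPlant(gen$genome, gen$annotation, config)
    ph <- simulatePhenotypes(gen$annotation, mp$truth, config)
    edges <- simulateTFEdges(config, tf_names = unname(tfNames(mp$motifs)))
    out <- list(genome = mp$genome, annotation = gen$annotation,
                motifs = mp$motifs, experiment = ph$experiment,
                edges = edges, truth = ph$truth, config = config)
    class(out) <- "MethylationStudy"
    out
}

#' @export
print.MethylationStudy <- function(x, ...) {
    cat("Synthetic methylation study:\n")
    cat("  genome:", length(x$genome), "chromosome(s),",
        sum(width(x$genome)), "bp\n")
    cat("  CpGs:", nrow(x$annotation), " samples:", ncol(x$experiment), "\n")
    cat("  motifs:", length(x$motifs),
        sprintf("(%d planted)", length(x$truth$planted_motif_ids)), "\n")
    cat("  TF edges:", nrow(x$edges), "\n")
    invisible(x)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits \code{genome.fasta}, \code{beta.tsv}, \code{annotation.tsv},
#' \code{clinical.tsv}, \code{motifs.meme} (MEME minimal),
#' \code{tf_edges.tsv} and \code{ground_truth.tsv} under \code{dir}.
#'
#' @param study a [simulateMethylationStudy()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSimulatedStudy <- function(study, dir) {
    stopifnot(inherits(study, "MethylationStudy"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fasta"),
               beta = file.path(dir, "beta.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               clinical = file.path(dir, "clinical.tsv"),
               motifs = file.path(dir, "motifs.meme"),
               edges = file.path(dir, "tf_edges.tsv"),
               truth = file.path(dir, "ground_truth.tsv"))
    writeXStringSet(study$genome, paths["genome"])
    b <- as.data.frame(betaValues(study$experiment))
    .write_tsv(cbind(cpg_id = rownames(b), b), paths["beta"])
    .write_tsv(study$annotation, paths["annotation"])
    .write_tsv(clinicalInfo(study$experiment), paths["clinical"])
    writeMotifsMeme(study$motifs, paths["motifs"])
    .write_tsv(study$edges, paths["edges"])
    .write_tsv(study$truth$plants, paths["truth"])
    invisible(paths)
}
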