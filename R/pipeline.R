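#' Pipeline configuration
#'
#' Declarative description of a full analysis run: input source (a
#' simulation config, or paths to on-disk inputs), the list of analyses
#' (screen + foreground definition + optional sample stratum), and all
#' thresholds.
#'
#' @param simulate a [simulationConfig()]; used when \code{inputs} is NULL.
#' @param inputs optional named list of paths: beta, annotation, clinical,
#'   genome, motifs, motif_format, edges.
#' @param analyses list of analysis descriptors, each a list with
#'   \code{name}, \code{screen} ("survival" or "diffmeth"),
#'   \code{foreground} ("protective", "hazardous", "pro+haz", "hyper",
#'   "hypo"), optional \code{stratum} (list(column=, value=)) and
#'   \code{group_col} (clinical column defining the two diffmeth groups,
#'   default "group").  NULL = the standard five: survival
#'   protective/hazardous/pro+haz on all samples plus diffmeth hyper/hypo.
#' @param diffmeth_alpha BH-adjusted cutoff for differential CpGs (0.05).
#' @param survival_p unadjusted Wald cutoff for survival CpGs (0.02).
#' @param scan_p per-window motif presence p cutoff (1e-4).
#' @param enrichment_alpha reporting threshold carried in outputs (0.01).
#' @param network_alpha adjusted-p cutoff for TFs entering the network (0.01).
#' @param background enrichment background: \code{"complement"} (all
#'   overlap-filtered tested regions not in the foreground, default) or
#'   \code{"nonsignificant"} (filtered regions of tested non-significant
#'   CpGs only).
#' @param k_clusters if > 0, also run k-means CpG clustering (with a WCSS
#'   curve up to k = 10) and per-cluster enrichment analyses.
#' @param restarts k-means restarts.
#' @param seed overrides the simulation seed when not NULL.
#' @param out_dir results directory; NULL = do not write.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulate = simulationConfig(), inputs = NULL,
                           analyses = NULL, diffmeth_alpha = 0.05,
                           survival_p = 0.02, scan_p = 1e-4,
                           enrichment_alpha = 0.01, network_alpha = 0.01,
                           background = c("complement", "nonsignificant"),
                           k_clusters = 0L, restarts = 10L,
                           seed = NULL, out_dir = NULL) {
    background <- match.arg(background)
    thr <- c(diffmeth_alpha, survival_p, scan_p, enrichment_alpha, network_alpha)
    if (any(thr <= 0 | thr >= 1)) stop("all thresholds must lie in (0, 1)")
    if (is.null(analyses))
        analyses <- list(
            list(name = "protective", screen = "survival", foreground = "protective"),
            list(name = "hazardous", screen = "survival", foreground = "hazardous"),
            list(name = "pro_haz", screen = "survival", foreground = "pro+haz"),
            list(name = "hyper", screen = "diffmeth", foreground = "hyper"),
            list(name = "hypo", screen = "diffmeth", foreground = "hypo"))
    ok_fg <- c("protective", "hazardous", "pro+haz", "hyper", "hypo")
    for (a in analyses) {
        if (!a$screen %in% c("survival", "diffmeth"))
            stop("unknown screen in analysis '", a$name, "'")
        if (!a$foreground %in% ok_fg)
            stop("invalid foreground '", a$foreground, "' in analysis '", a$name, "'")
    }
    if (!is.null(seed)) simulate$seed <- as.integer(seed)
    structure(list(simulate = simulate, inputs = inputs, analyses = analyses,
                   diffmeth_alpha = diffmeth_alpha, survival_p = survival_p,
                   scan_p = scan_p, enrichment_alpha = enrichment_alpha,
                   network_alpha = network_alpha, background = background,
                   k_clusters = as.integer(k_clusters),
                   restarts = as.integer(restarts),
                   seed = seed, out_dir = out_dir),
              class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, per configured analysis: screen (differential methylation or
#' univariate Cox survival, within the analysis's stratum) -> category
#' foreground set -> 102-bp regions -> greedy overlap filter -> sequence
#' extraction -> motif presence (the presence matrix is computed once over
#' the union of all regions and reused across analyses) -> Fisher
#' enrichment against the configured background.  Optionally adds CpG
#' k-means clustering with per-cluster enrichment, and a first-neighbour TF
#' subnetwork built from the protective/hazardous enrichments.  A manifest
#' records seed, thresholds and the entity counts at every stage.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, list with \code{study} (inputs), \code{screens},
#'   \code{analyses} (per analysis: foreground regions, id sets,
#'   enrichment), \code{presence}, \code{clustering}, \code{network},
#'   \code{manifest}; written to \code{out_dir} when configured.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    manifest <- list()
    note <- function(stage, key, value)
        manifest[[length(manifest) + 1L]] <<- data.frame(
            stage = stage, key = key, value = as.character(value))

    ## ---- inputs -----------------------------------------------------
    stage <- "inputs"
    res <- tryCatch({
        if (is.null(config$inputs)) {
            study <- simulateMethylationStudy(config$simulate)
            note("inputs", "source", "simulated")
            note("inputs", "seed", config$simulate$seed)
        } else {
            ip <- config$inputs
            me <- loadMethylationDataset(ip$beta, ip$annotation, ip$clinical)
            study <- list(genome = readGenomeFasta(ip$genome),
                          annotation = cpgInfo(me),
                          motifs = readMotifs(ip$motifs,
                                              format = ip$motif_format %||% "meme"),
                          experiment = me,
                          edges = if (!is.null(ip$edges)) .read_tsv(ip$edges)
                                  else data.frame(tf1 = character(),
                                                  tf2 = character()),
                          truth = NULL, config = NULL)
            class(study) <- "MethylationStudy"
            note("inputs", "source", "files")
        }
        me <- study$experiment
        annotation <- study$annotation
        note("inputs", "n_cpgs", nrow(me))
        note("inputs", "n_samples", ncol(me))
        note("inputs", "n_motifs", length(study$motifs))

        ## ---- screens (cached per stratum / group column) ----------------
        stage <- "screen"
        surv_cache <- list(); dm_cache <- list()
        get_surv <- function(stratum) {
            key <- if (is.null(stratum)) "all"
                   else paste0(stratum$column, "=", stratum$value)
            if (is.null(surv_cache[[key]])) {
                surv_cache[[key]] <<- screenSurvivalCpGs(me, stratum,
                                                         p_cut = config$survival_p)
                note("screen", paste0("survival[", key, "]:tested"),
                     sum(surv_cache[[key]]$tested))
            }
            surv_cache[[key]]
        }
        get_dm <- function(group_col) {
            if (is.null(dm_cache[[group_col]])) {
                cli <- clinicalInfo(me)
                if (!group_col %in% colnames(cli))
                    stop("clinical table has no column '", group_col, "'")
                groups <- setNames(cli[[group_col]], cli$sample_id)
                dm_cache[[group_col]] <<- diffMethylation(me, groups,
                                                          alpha = config$diffmeth_alpha)
                note("screen", paste0("diffmeth[", group_col, "]:tested"),
                     sum(dm_cache[[group_col]]$tested))
            }
            dm_cache[[group_col]]
        }

        ## ---- per-analysis foreground/background id sets -----------------
        stage <- "regions"
        filtered_ids <- function(sel_df) {
            if (!nrow(sel_df)) return(character())
            gr <- filterOverlappingRegions(
                suppressWarnings(makeRegions(sel_df, annotation, study$genome)))
            gr$cpg_id
        }
        ana <- list()
        for (a in config$analyses) {
            if (a$screen == "survival") {
                scr <- get_surv(a$stratum)
                tested <- scr[scr$tested, , drop = FALSE]
                sel <- switch(a$foreground,
                              "protective" = tested[tested$category == "protective", ],
                              "hazardous" = tested[tested$category == "hazardous", ],
                              "pro+haz" = tested[tested$category %in%
                                                     c("protective", "hazardous"), ])
                sel_df <- data.frame(cpg_id = sel$cpg_id, p_value = sel$wald_p,
                                     category = rep(a$foreground, nrow(sel)))
                all_df <- data.frame(cpg_id = tested$cpg_id, p_value = tested$wald_p)
                nonsig_df <- data.frame(
                    cpg_id = tested$cpg_id[tested$category == "none"],
                    p_value = tested$wald_p[tested$category == "none"])
            } else {
                dm <- get_dm(a$group_col %||% "group")
                tested <- dm[dm$tested, , drop = FALSE]
                sel <- tested[tested$direction == a$foreground, , drop = FALSE]
                sel_df <- data.frame(cpg_id = sel$cpg_id, p_value = sel$raw_p,
                                     category = rep(a$foreground, nrow(sel)))
                all_df <- data.frame(cpg_id = tested$cpg_id, p_value = tested$raw_p)
                nonsig_df <- data.frame(
                    cpg_id = tested$cpg_id[tested$direction == "none"],
                    p_value = tested$raw_p[tested$direction == "none"])
            }
            fg_regions <- filterOverlappingRegions(
                suppressWarnings(makeRegions(sel_df, annotation, study$genome)))
            fg_ids <- fg_regions$cpg_id
            bg_ids <- if (config$background == "complement")
                setdiff(filtered_ids(all_df), fg_ids)
            else setdiff(filtered_ids(nonsig_df), fg_ids)
            note("regions", paste0(a$name, ":selected"), nrow(sel_df))
            note("regions", paste0(a$name, ":foreground_filtered"), length(fg_ids))
            note("regions", paste0(a$name, ":background"), length(bg_ids))
            ana[[a$name]] <- list(spec = a, selected = sel_df,
                                  regions = fg_regions,
                                  foreground_ids = fg_ids,
                                  background_ids = bg_ids)
        }

        ## ---- clustering -------------------------------------------------
        clustering <- NULL
        if (config$k_clusters > 0L) {
            stage <- "cluster"
            km <- kmeansBeta(me, config$k_clusters, restarts = config$restarts,
                             seed = config$simulate$seed %||% 1L)
            curve <- wcssCurve(me, k_max = 10L, restarts = config$restarts,
                               seed = config$simulate$seed %||% 1L)
            clustering <- list(kmeans = km, wcss = curve)
            note("cluster", "k", config$k_clusters)
            note("cluster", "wcss_total", format(km$wcss_total))
            all_cpgs <- data.frame(cpg_id = names(km$assignments), p_value = 1)
            all_filt <- filtered_ids(all_cpgs)
            for (ci in seq_len(config$k_clusters)) {
                ids <- names(km$assignments)[km$assignments == ci]
                sel_df <- data.frame(cpg_id = ids,
                                     p_value = rep(1, length(ids)),
                                     category = rep(paste0("cluster_", ci),
                                                    length(ids)))
                fg_ids <- intersect(all_filt, ids)
                ana[[paste0("cluster_", ci)]] <- list(
                    spec = list(name = paste0("cluster_", ci),
                                screen = "cluster",
                                foreground = paste0("cluster_", ci)),
                    selected = sel_df,
                    regions = NULL,
                    foreground_ids = fg_ids,
                    background_ids = setdiff(all_filt, fg_ids))
                note("regions", paste0("cluster_", ci, ":foreground_filtered"),
                     length(fg_ids))
            }
        }

        ## ---- presence matrix (once, over the union of regions) ----------
        stage <- "scan"
        union_ids <- sort(unique(unlist(lapply(ana, function(x)
            c(x$foreground_ids, x$background_ids)))))
        presence <- NULL
        if (length(union_ids)) {
            ugr <- makeRegions(data.frame(cpg_id = union_ids, p_value = 1),
                               annotation, study$genome)
            seqs <- extractRegionSequences(ugr, study$genome)
            presence <- buildPresenceMatrix(seqs, study$motifs,
                                            scanParams(p_threshold = config$scan_p))
            note("scan", "regions_scanned", length(seqs))
            note("scan", "motifs", length(study$motifs))
            note("scan", "attainable_motifs",
                 sum(attr(presence, "thresholds")$attainable))
        }

        ## ---- enrichment -------------------------------------------------
        stage <- "enrich"
        for (nm in names(ana)) {
            fg <- ana[[nm]]$foreground_ids; bg <- ana[[nm]]$background_ids
            if (!length(fg) || !length(bg)) {
                note("enrich", paste0(nm, ":skipped"),
                     "empty foreground or background")
                next
            }
            ana[[nm]]$enrichment <- motifEnrichment(presence, fg, bg,
                                                    motifs = study$motifs,
                                                    analysis = nm)
            note("enrich", paste0(nm, ":motifs_tested"),
                 nrow(ana[[nm]]$enrichment))
        }

        ## ---- network ----------------------------------------------------
        stage <- "network"
        network <- NULL
        surv_enr <- do.call(rbind, lapply(ana, function(x)
            if (!is.null(x$enrichment) &&
                x$spec$foreground %in% c("protective", "hazardous"))
                x$enrichment else NULL))
        if (!is.null(surv_enr) && nrow(surv_enr)) {
            tf_table <- aggregateTFPvalues(surv_enr, alpha = config$network_alpha)
            network <- buildSubnetwork(tf_table, study$edges)
            note("network", "significant_tfs", nrow(tf_table))
            note("network", "nodes", nrow(network$nodes))
            note("network", "edges", nrow(network$edges))
        }

        list(study = study, screens = list(survival = surv_cache,
                                           diffmeth = dm_cache),
             analyses = ana, presence = presence, clustering = clustering,
             network = network)
    }, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))

    manifest_df <- do.call(rbind, manifest)
    res$manifest <- manifest_df

    if (!is.null(config$out_dir)) {
        tables <- list(manifest = manifest_df)
        for (nm in names(res$screens$survival))
            tables[[paste0("survival_", gsub("[^A-Za-z0-9+-]", "_", nm))]] <-
                res$screens$survival[[nm]]
        for (nm in names(res$screens$diffmeth))
            tables[[paste0("diffmeth_", nm)]] <- res$screens$diffmeth[[nm]]
        enr <- do.call(rbind, lapply(res$analyses, `[[`, "enrichment"))
        if (!is.null(enr)) { rownames(enr) <- NULL; tables$enrichment <- enr }
        if (!is.null(res$presence)) {
            tables$motif_thresholds <- attr(res$presence, "thresholds")
            pm <- as.data.frame(res$presence * 1L)
            tables$presence_matrix <- cbind(cpg_id = rownames(res$presence), pm)
        }
        if (!is.null(res$clustering)) {
            tables$cluster_assignments <- data.frame(
                cpg_id = names(res$clustering$kmeans$assignments),
                cluster = unname(res$clustering$kmeans$assignments))
            tables$wcss_curve <- res$clustering$wcss
        }
        regions_out <- lapply(res$analyses, `[[`, "regions")
        regions_out <- regions_out[!vapply(regions_out, is.null, logical(1))]
        writeResultsBundle(list(regions = regions_out, tables = tables,
                                network = res$network),
                           config$out_dir)
    }
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
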