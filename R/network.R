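#' Aggregate motif-level enrichment to transcription-factor level
#'
#' Keeps motifs that are significantly enriched (adjusted p below
#' \code{alpha} and relative enrichment above 1; depleted motifs are
#' excluded) and averages, per TF, the p-values of its contributing motifs
#' (databases often hold several matrices per factor).  The TF category
#' records which screens contributed: \code{protective}, \code{hazardous},
#' or \code{both}.
#'
#' @param enrichment one or more [motifEnrichment()] tables (rbind-ed),
#'   with an \code{analysis} column whose labels contain "protective" or
#'   "hazardous".
#' @param alpha significance threshold on adjusted p (default 0.01).
#' @return data.frame: tf_name, mean_p (mean raw p of contributing motifs),
#'   mean_adjusted_p, n_motifs, category.  Empty (zero rows) when nothing
#'   is significant.
#' @export
aggregateTFPvalues <- function(enrichment, alpha = 0.01) {
    e <- as.data.frame(enrichment)
    need <- c("tf_name", "raw_p", "adjusted_p", "relative_enrichment", "analysis")
    stopifnot(all(need %in% colnames(e)))
    sig <- !is.na(e$adjusted_p) & e$adjusted_p < alpha &
        !is.na(e$relative_enrichment) & e$relative_enrichment > 1
    e <- e[sig, , drop = FALSE]
    if (!nrow(e))
        return(data.frame(tf_name = character(), mean_p = numeric(),
                          mean_adjusted_p = numeric(), n_motifs = integer(),
                          category = character(), stringsAsFactors = FALSE))
    kind <- ifelse(grepl("protective", e$analysis), "protective",
            ifelse(grepl("hazardous", e$analysis), "hazardous",
                   as.character(e$analysis)))
    out <- do.call(rbind, lapply(split(seq_len(nrow(e)), e$tf_name), function(i) {
        kinds <- sort(unique(kind[i]))
        data.frame(tf_name = e$tf_name[i[1]],
                   mean_p = mean(e$raw_p[i]),
                   mean_adjusted_p = mean(e$adjusted_p[i]),
                   n_motifs = length(i),
                   category = if (all(c("protective", "hazardous") %in% kinds))
                       "both" else paste(kinds, collapse = "+"),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out[order(out$mean_p, out$tf_name), , drop = FALSE]
}

#' First-order TF-TF interaction subnetwork
#'
#' Node set = significant TFs plus their first-degree neighbours in the
#' interaction list; edge set = the induced subgraph on that node set (so
#' neighbour-neighbour edges are retained).  Significant TFs absent from
#' the edge list appear as isolated nodes.  Node degree is computed within
#' the emitted graph.
#'
#' @param tf_table an [aggregateTFPvalues()] result.
#' @param edges data.frame of undirected TF pairs (columns tf1, tf2).
#' @return list of class \code{"TFNetwork"}: \code{nodes} (tf_name, mean_p,
#'   degree, category — \code{"neighbor"} for neighbour-only nodes),
#'   \code{edges}, and \code{graph} (an igraph object with the node
#'   attributes attached).
#' @export
buildSubnetwork <- function(tf_table, edges) {
    edges <- as.data.frame(edges)
    if (nrow(edges)) {
        stopifnot(ncol(edges) >= 2)
        g <- igraph::simplify(igraph::graph_from_data_frame(edges[, 1:2],
                                                            directed = FALSE))
    } else g <- igraph::make_empty_graph(0, directed = FALSE)
    sig <- tf_table$tf_name
    in_graph <- intersect(sig, igraph::V(g)$name)
    nbrs <- if (length(in_graph))
        igraph::V(g)$name[unique(unlist(igraph::adjacent_vertices(g, in_graph)))]
    else character()
    nodeset <- union(sig, nbrs)
    sub <- igraph::induced_subgraph(g, intersect(nodeset, igraph::V(g)$name))
    iso <- setdiff(nodeset, igraph::V(sub)$name)
    if (length(iso)) sub <- igraph::add_vertices(sub, length(iso), name = iso)
    nm <- igraph::V(sub)$name
    deg <- igraph::degree(sub)
    idx <- match(nm, tf_table$tf_name)
    nodes <- data.frame(tf_name = nm,
                        mean_p = tf_table$mean_p[idx],
                        degree = unname(deg),
                        category = ifelse(is.na(idx), "neighbor",
                                          tf_table$category[idx]),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(sub)
    edges_out <- data.frame(tf1 = el[, 1], tf2 = el[, 2],
                            stringsAsFactors = FALSE)
    igraph::V(sub)$mean_p <- ifelse(is.na(nodes$mean_p), NaN, nodes$mean_p)
    igraph::V(sub)$degree <- nodes$degree
    igraph::V(sub)$category <- nodes$category
    structure(list(nodes = nodes, edges = edges_out, graph = sub),
              class = "TFNetwork")
}

#' @export
print.TFNetwork <- function(x, ...) {
    cat(sprintf("TF subnetwork: %d nodes (%d significant TFs), %d edges\n",
                nrow(x$nodes), sum(x$nodes$category != "neighbor"),
                nrow(x$edges)))
    invisible(x)
}

#' Write a TF subnetwork as GraphML
#'
#' Node attributes mean_p, degree and category travel with the file so any
#' graph viewer can map them to size/colour.
#'
#' @param network a [buildSubnetwork()] result.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNetworkGraphML <- function(network, path) {
    stopifnot(inherits(network, "TFNetwork"))
    igraph::write_graph(network$graph, path, format = "graphml")
    invisible(path)
}
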