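# Node centralities and keystone-OTU identification.  Degree counts
# incident edges; betweenness uses Brandes' algorithm normalized by
# (n-1)(n-2)/2; closeness is the reciprocal of the mean shortest-path
# length to all reachable nodes (computed within connected components,
# matching Cytoscape's NetworkAnalyzer); an isolated node has
# closeness 0.

#' Node centralities
#'
#' @param network An `ng_network` or an undirected igraph graph with
#'   at least one node.
#' @return Data.frame with one row per node: `otu_id`, `degree`,
#'   `betweenness` and `closeness` (both normalized to 0-1), plus
#'   `phylum`, `genus` and `n_function` when the graph carries those
#'   node attributes.
#' @export
centralities <- function(network) {
  g <- if (inherits(network, "ng_network")) network$graph else network
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0) stop("network has no nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = igraph::vcount(g) > 2)
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  out <- data.frame(otu_id = ids, degree = unname(deg),
                    betweenness = unname(btw), closeness = unname(cls),
                    stringsAsFactors = FALSE)
  for (attr in c("phylum", "genus", "n_function"))
    if (attr %in% igraph::vertex_attr_names(g))
      out[[attr]] <- igraph::vertex_attr(g, attr)
  out
}

#' Identify potential keystone OTUs
#'
#' Ranks nodes by degree (descending), breaking ties by higher
#' closeness, then lower betweenness, then lexicographic OTU id, and
#' returns the top `k` — highly connected, topologically central
#' nodes hypothesized to disproportionately structure the community.
#'
#' @param records Centrality table from [centralities()].
#' @param k Number of keystones to return (default 7); must not exceed
#'   the node count.
#' @return The top-`k` rows of `records`, ranked; empty input gives an
#'   empty data.frame.
#' @export
identify_keystones <- function(records, k = 7) {
  if (nrow(records) == 0) return(records)
  if (k > nrow(records))
    stop(sprintf("k (%d) exceeds node count (%d)", k, nrow(records)))
  ord <- order(-records$degree, -records$closeness, records$betweenness,
               records$otu_id)
  out <- records[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a keystone table as TSV
#'
#' Column layout mirrors the keystone summary of the workflow:
#' Phylum, Genus, Degree, Betweenness, Closeness, Function in N cycle.
#'
#' @param keystones Output of [identify_keystones()].
#' @param path Output path.
#' @export
write_keystones <- function(keystones, path) {
  cols <- c(phylum = "Phylum", genus = "Genus", degree = "Degree",
            betweenness = "Betweenness Centrality",
            closeness = "Closeness Centrality",
            n_function = "Function in N cycle")
  df <- data.frame(otu_id = keystones$otu_id, stringsAsFactors = FALSE)
  for (nm in names(cols))
    df[[cols[[nm]]]] <- if (nm %in% names(keystones)) keystones[[nm]] else NA
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
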