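# Network export: GraphML (node/edge attributes preserved, readable by
# Cytoscape and igraph) and a flat edge TSV mirroring the per-edge
# record fields, plus a round-trip reader for the latter.

#' Write a network to GraphML or edge TSV
#'
#' GraphML carries the node attributes set by [annotate_network()]
#' (phylum, class, mean abundance, centralities, N function) and edge
#' attributes `sign` (`"+"` co-presence, `"-"` exclusion), `p_merged`
#' and `q`.  The edge TSV mirrors the full per-edge record (scores,
#' p-values, bootstrap intervals, stability, merged p, q, sign) and
#' round-trips through [read_edge_table()].
#'
#' @param net An `ng_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(net, "ng_network"))
  if (!format[1] %in% c("graphml", "edge_tsv"))
    stop("unknown format: ", format[1])
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net$graph
    if (igraph::ecount(g) > 0)
      igraph::E(g)$sign <- ifelse(igraph::E(g)$sign == "co-presence",
                                  "+", "-")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read an edge TSV back into an edge table
#'
#' @param path Path written by [write_network(format = "edge_tsv")].
#' @return Data.frame of edge records.
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  need <- c("otu_a", "otu_b")
  if (!all(need %in% names(df)))
    stop("edge TSV must contain columns otu_a and otu_b")
  for (col in intersect(c("stable", "retained"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}
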