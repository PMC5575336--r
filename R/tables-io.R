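# Readers and writers for every tabular artifact the pipeline touches:
# classic OTU-table TSV (QIIME convention, optional trailing taxonomy
# column), taxonomy TSV, guild-annotation TSV, qPCR TSV.  TSV is the
# canonical dialect (BIOM-convertible layout: OTUs in rows, samples in
# columns).

#' Parse seven-rank lineage strings
#'
#' Accepts both Greengenes-style lineages (`k__Bacteria; p__...`) and
#' Silva-style lineages (semicolon-separated, no rank prefixes),
#' auto-detected per string; rank prefixes are stripped and empty ranks
#' become `NA`.
#'
#' @param lineage Character vector of lineage strings.
#' @param otu_id Optional OTU ids used as rownames of the result.
#' @return A `taxonomy_map`: data.frame with columns `otu_id` and the
#'   seven ranks domain...species.
#' @export
parse_lineage <- function(lineage, otu_id = NULL) {
  if (is.null(otu_id)) otu_id <- paste0("OTU_", seq_along(lineage))
  ranks <- matrix(NA_character_, nrow = length(lineage), ncol = 7,
                  dimnames = list(NULL, NG_RANKS))
  for (i in seq_along(lineage)) {
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    # strip Greengenes/Silva rank prefixes such as k__, d__, g__
    parts <- sub("^[a-zA-Z]__", "", parts)
    parts[parts == ""] <- NA_character_
    n <- min(length(parts), 7L)
    if (n > 0) ranks[i, seq_len(n)] <- parts[seq_len(n)]
  }
  out <- data.frame(otu_id = otu_id, ranks, stringsAsFactors = FALSE)
  rownames(out) <- otu_id
  taxonomy_map(out)
}

#' Construct and validate a taxonomy map
#'
#' @param df Data.frame with column `otu_id` and any of the seven rank
#'   columns (domain, phylum, class, order, family, genus, species).
#' @return Validated `taxonomy_map` data.frame.
#' @export
taxonomy_map <- function(df) {
  stopifnot(is.data.frame(df), "otu_id" %in% names(df))
  for (r in NG_RANKS) if (!r %in% names(df)) df[[r]] <- NA_character_
  df <- df[, c("otu_id", NG_RANKS)]
  if (anyDuplicated(df$otu_id))
    stop("duplicate OTU ids in taxonomy: ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  known <- c("Bacteria", "Archaea", "Eukaryota", "Fungi")
  bad <- setdiff(unique(df$domain[!is.na(df$domain)]), known)
  if (length(bad) > 0)
    stop("unknown domain(s): ", paste(bad, collapse = ", "),
         " (expected Bacteria, Archaea, Eukaryota or Fungi)")
  rownames(df) <- df$otu_id
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a classic OTU-table TSV
#'
#' First column holds OTU ids, remaining columns sample counts; an
#' optional trailing `taxonomy` column (classic QIIME convention) is
#' split off and parsed into a taxonomy map.
#'
#' @param path Path to a TSV file.
#' @param scale Declared scale of the values (see [sample_table()]).
#' @return A list with elements `table` (a [sample_table()]) and
#'   `taxonomy` (a `taxonomy_map` or `NULL`).
#' @export
read_otu_table <- function(path, scale = "counts") {
  fields <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad, fields[bad], fields[1]))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("OTU table needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxonomy <- NULL
  last <- names(df)[ncol(df)]
  if (tolower(last) %in% c("taxonomy", "consensus lineage", "consensuslineage")) {
    taxonomy <- parse_lineage(as.character(df[[ncol(df)]]), otu_id = ids)
    df <- df[, -ncol(df), drop = FALSE]
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance values in ", path)
  rownames(vals) <- ids
  tab <- sample_table(vals, scale = scale)
  list(table = tab, taxonomy = taxonomy)
}

#' Write an OTU table as TSV
#'
#' @param table A [sample_table()].
#' @param path Output path.
#' @param taxonomy Optional `taxonomy_map`; if given, a trailing
#'   Greengenes-style `taxonomy` column is appended.
#' @export
write_otu_table <- function(table, path, taxonomy = NULL) {
  stopifnot(inherits(table, "sample_table"))
  df <- data.frame(`#OTU ID` = otu_ids(table), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    tax <- taxonomy[otu_ids(table), NG_RANKS, drop = FALSE]
    pref <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
    lin <- apply(tax, 1, function(row) {
      row[is.na(row)] <- ""
      paste0(pref, row, collapse = "; ")
    })
    df$taxonomy <- lin
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy TSV (OTU id, lineage string)
#'
#' @param path Two-column TSV: OTU id and lineage string.
#' @return A `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("taxonomy TSV needs id and lineage columns")
  parse_lineage(as.character(df[[2]]), otu_id = as.character(df[[1]]))
}

#' Construct a genus-to-gene guild annotation
#'
#' @param genus Character vector of genus names.
#' @param genes Character vector (same length) of gene symbols, each a
#'   single symbol or a comma-separated list.
#' @return A `guild_annotation`: named list genus -> character vector of
#'   gene symbols from the fixed vocabulary (napA, narG, nirK, nirS,
#'   norB, nosZ, nrfA, nifH, amoA).
#' @export
guild_annotation <- function(genus, genes) {
  stopifnot(length(genus) == length(genes))
  if (any(is.na(genus) | genus == ""))
    stop("genus names must be non-empty")
  out <- list()
  for (i in seq_along(genus)) {
    gs <- trimws(strsplit(as.character(genes[i]), ",", fixed = TRUE)[[1]])
    bad <- setdiff(gs, NG_GENES)
    if (length(bad) > 0)
      stop("unknown gene symbol ", paste(bad, collapse = ", "),
           " (expected one of ", paste(NG_GENES, collapse = ", "), ")")
    g <- as.character(genus[i])
    out[[g]] <- sort(unique(c(out[[g]], gs)))
  }
  structure(out, class = "guild_annotation")
}

#' Read a guild-annotation TSV
#'
#' Expects columns `genus` and `gene` (one pair per row, or a
#' comma-separated gene list per genus); genes of a genus appearing in
#' several rows are unioned.
#'
#' @param path Path to the TSV.
#' @return A [guild_annotation()].
#' @export
read_guild_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("guild annotation needs genus and gene columns")
  guild_annotation(as.character(df[[1]]), as.character(df[[2]]))
}

#' Write a guild annotation as TSV
#' @param annotation A [guild_annotation()].
#' @param path Output path.
#' @export
write_guild_annotation <- function(annotation, path) {
  df <- data.frame(genus = names(annotation),
                   gene = vapply(annotation, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a qPCR abundance table
#'
#' Per-sample SSU gene copy numbers (copies per ng DNA) for the
#' bacterial, archaeal and fungal domains, as produced by
#' standard-curve quantification.
#'
#' @param sample_id Sample identifiers.
#' @param bacterial,archaeal,fungal Non-negative copies per ng DNA.
#' @return A `qpcr_table` data.frame.
#' @export
qpcr_table <- function(sample_id, bacterial, archaeal = 0, fungal = 0) {
  df <- data.frame(sample_id = as.character(sample_id),
                   bacterial = bacterial, archaeal = archaeal,
                   fungal = fungal, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in qPCR table")
  if (any(as.matrix(df[, -1]) < 0)) stop("qPCR copy numbers must be >= 0")
  rownames(df) <- df$sample_id
  class(df) <- c("qpcr_table", "data.frame")
  df
}

#' Read a qPCR TSV (sample_id, bacterial, archaeal, fungal)
#' @param path Path to the TSV.
#' @return A [qpcr_table()].
#' @export
read_qpcr_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "bacterial")
  if (!all(need %in% names(df)))
    stop("qPCR TSV needs at least columns: ", paste(need, collapse = ", "))
  qpcr_table(df$sample_id, df$bacterial,
             archaeal = if ("archaeal" %in% names(df)) df$archaeal else 0,
             fungal = if ("fungal" %in% names(df)) df$fungal else 0)
}

#' Write a qPCR table as TSV
#' @param qpcr A [qpcr_table()].
#' @param path Output path.
#' @export
write_qpcr_table <- function(qpcr, path) {
  write.table(as.data.frame(qpcr), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
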