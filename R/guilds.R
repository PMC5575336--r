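# Nitrogen-cycle functional guild quantification: OTUs inherit the
# N-cycle marker genes of their genus, genes map to pathways, and
# pathway abundance is the summed absolute abundance of member OTUs
# (membership counting: an OTU counts once per pathway no matter how
# many of the pathway's genes it carries).

#' Gene-to-pathway vocabulary
#'
#' The fixed mapping of marker genes to nitrogen-cycle pathways:
#' nitrate reduction (napA, narG), denitrification (nirK, nirS, norB,
#' nosZ), DNRA (nrfA), N2 fixation (nifH) and ammonia oxidation (amoA).
#'
#' @return Named list pathway -> character vector of gene symbols.
#' @export
gene_pathways <- function() NG_PATHWAYS

#' Assign nitrogen-cycle pathways to OTUs
#'
#' Each OTU inherits the gene set annotated for its genus; genes are
#' mapped to pathways via [gene_pathways()].  OTUs without a genus or
#' with an unannotated genus receive the empty set (their number is
#' reported via a message).
#'
#' @param taxonomy A `taxonomy_map`.
#' @param annotation A [guild_annotation()].
#' @return Named list OTU id -> character vector of pathway names.
#' @export
assign_guilds <- function(taxonomy, annotation) {
  stopifnot(inherits(annotation, "guild_annotation"))
  path_of_gene <- setNames(
    rep(names(NG_PATHWAYS), lengths(NG_PATHWAYS)), unlist(NG_PATHWAYS))
  out <- setNames(vector("list", nrow(taxonomy)), taxonomy$otu_id)
  n_unassigned <- 0L
  for (i in seq_len(nrow(taxonomy))) {
    g <- taxonomy$genus[i]
    if (is.na(g) || g == "" || is.null(annotation[[g]])) {
      out[[i]] <- character(0)
      n_unassigned <- n_unassigned + 1L
    } else {
      out[[i]] <- sort(unique(unname(path_of_gene[annotation[[g]]])))
    }
  }
  if (n_unassigned > 0)
    message(sprintf("%d of %d OTUs carry no N-cycle annotation",
                    n_unassigned, nrow(taxonomy)))
  out
}

#' Quantify functional guild abundances
#'
#' Per sample and pathway, sums the absolute abundance of all member
#' OTUs (each OTU counted once per pathway).  A gene-level tally
#' (OTUs carrying each gene) is returned alongside, together with the
#' OTU-to-pathway provenance.
#'
#' @param absolute A [sample_table()] on `absolute` scale (run
#'   [to_absolute()] first).
#' @param guild_map Output of [assign_guilds()].
#' @param annotation Optional [guild_annotation()] plus `taxonomy`, used
#'   for the gene-level tally; if omitted only pathway sums are filled.
#' @param taxonomy Optional `taxonomy_map` (needed with `annotation`).
#' @return A `pathway_abundance` object: list with `pathways` (matrix
#'   pathway x sample), `genes` (matrix gene x sample), `provenance`
#'   (named list OTU -> pathways) and `group`.
#' @export
quantify_guilds <- function(absolute, guild_map, annotation = NULL,
                            taxonomy = NULL) {
  stopifnot(inherits(absolute, "sample_table"))
  if (absolute$scale != "absolute")
    stop("quantify_guilds requires an absolute-scale table; run to_absolute")
  ids <- otu_ids(absolute)
  pw <- matrix(0, length(NG_PATHWAYS), ncol(absolute$values),
               dimnames = list(names(NG_PATHWAYS), sample_ids(absolute)))
  for (p in names(NG_PATHWAYS)) {
    members <- ids[vapply(guild_map[ids], function(s) p %in% s, TRUE)]
    if (length(members) > 0)
      pw[p, ] <- colSums(absolute$values[members, , drop = FALSE])
  }
  genes <- matrix(0, length(NG_GENES), ncol(absolute$values),
                  dimnames = list(NG_GENES, sample_ids(absolute)))
  if (!is.null(annotation) && !is.null(taxonomy)) {
    genus <- taxonomy[ids, "genus"]
    for (g in NG_GENES) {
      carriers <- names(annotation)[vapply(annotation,
                                           function(s) g %in% s, TRUE)]
      members <- ids[!is.na(genus) & genus %in% carriers]
      if (length(members) > 0)
        genes[g, ] <- colSums(absolute$values[members, , drop = FALSE])
    }
  }
  structure(list(pathways = pw, genes = genes,
                 provenance = guild_map[ids], group = absolute$group),
            class = "pathway_abundance")
}

#' @export
print.pathway_abundance <- function(x, ...) {
  cat("pathway_abundance over", ncol(x$pathways), "samples\n")
  print(round(rowMeans(x$pathways), 2))
  invisible(x)
}

#' Denitrification-to-DNRA ratio
#'
#' Ratio of group-mean denitrification-capable abundance to group-mean
#' DNRA-capable abundance; the headline contrast of the nitrogen-loss
#' potential between communities.  Per-sample ratios are attached as an
#' attribute for dispersion estimates.
#'
#' @param pa A [quantify_guilds()] result.
#' @param grouping Optional sample -> group labels; defaults to the
#'   table's group, or a single pooled group.
#' @return Named numeric of per-group ratios; `+Inf` with a warning
#'   when a group's mean DNRA abundance is zero.  Per-sample ratios in
#'   `attr(, "per_sample")`.
#' @export
denit_dnra_ratio <- function(pa, grouping = NULL) {
  stopifnot(inherits(pa, "pathway_abundance"))
  if (is.null(grouping)) grouping <- pa$group
  if (is.null(grouping))
    grouping <- setNames(rep("all", ncol(pa$pathways)),
                         colnames(pa$pathways))
  grouping <- grouping[colnames(pa$pathways)]
  denit <- pa$pathways["denitrification", ]
  dnra <- pa$pathways["DNRA", ]
  out <- vapply(split(seq_along(grouping), grouping), function(idx) {
    md <- mean(dnra[idx])
    if (md == 0) Inf else mean(denit[idx]) / md
  }, 0)
  if (any(is.infinite(out)))
    warning("zero mean DNRA abundance in group(s) ",
            paste(names(out)[is.infinite(out)], collapse = ", "),
            "; ratio is +Inf")
  attr(out, "per_sample") <- ifelse(dnra > 0, denit / dnra, Inf)
  out
}

#' Nitrogen-cycle flux scheme
#'
#' Weighted description of the conceptual N-cycle diagram: directed
#' arrows NO3- -> NO2- (nitrate reduction), NO2- -> N gases
#' (denitrification), NO2- -> NH4+ (DNRA), NH4+ -> NO3- (ammonia
#' oxidation, via NO2-) and N2 -> organic N (N2 fixation), each
#' weighted by the group-mean abundance of the corresponding guild.
#'
#' @param pa A [quantify_guilds()] result.
#' @param grouping Optional sample -> group labels (see
#'   [denit_dnra_ratio()]).
#' @return Data.frame with columns `group`, `pathway`, `from`, `to`,
#'   `weight`; serializable as TSV.
#' @export
flux_scheme <- function(pa, grouping = NULL) {
  stopifnot(inherits(pa, "pathway_abundance"))
  if (is.null(grouping)) grouping <- pa$group
  if (is.null(grouping))
    grouping <- setNames(rep("all", ncol(pa$pathways)),
                         colnames(pa$pathways))
  grouping <- grouping[colnames(pa$pathways)]
  arrows <- data.frame(
    pathway = c("nitrate_reduction", "denitrification", "DNRA",
                "ammonia_oxidation", "n_fixation"),
    from = c("NO3-", "NO2-", "NO2-", "NH4+", "N2"),
    to = c("NO2-", "N gases", "NH4+", "NO3-", "organic N"),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(unique(grouping), function(g) {
    idx <- which(grouping == g)
    w <- rowMeans(pa$pathways[arrows$pathway, idx, drop = FALSE])
    cbind(data.frame(group = g, stringsAsFactors = FALSE), arrows,
          weight = unname(w))
  }))
  rownames(out) <- NULL
  out
}

# Human-readable N-cycle role labels (Table-4 style) for a pathway set.
n_function_label <- function(pathways) {
  lab <- c(denitrification = "denitrifier", DNRA = "DNRA",
           nitrate_reduction = "nitrate reducer", n_fixation = "N2 fixer",
           ammonia_oxidation = "ammonia oxidizer")
  if (length(pathways) == 0) return(NA_character_)
  paste(unname(lab[intersect(names(lab), pathways)]), collapse = ", ")
}
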