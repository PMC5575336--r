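# One-shot orchestration of the whole pipeline: simulate (or read) ->
# prep -> guilds -> network -> keystones -> biogeochem, with a plain
# text config, structured stage logging and a run manifest that
# records everything needed to reproduce the run byte-for-byte.

#' Read a plain-text pipeline configuration
#'
#' `key: value` lines (DCF syntax); values that parse as numbers
#' become numeric.  See [pipeline_config()] for the recognized keys
#' and defaults.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  m <- read.dcf(path)
  cfg <- as.list(m[1, ])
  lapply(cfg, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
}

#' Default pipeline configuration
#'
#' @param ... Overrides of the defaults.
#' @return Named list of pipeline parameters: simulation settings
#'   (`n_otus`, `n_samples`, `block_sizes`, `block_rho`,
#'   `guild_denitrification`, `guild_dnra`, `depth`), prep settings
#'   (`drop_singletons`, `min_prevalence`), network settings (`top_n`,
#'   `bottom_n`, `n_perm`, `n_boot`, `alpha`, `q_threshold`),
#'   `keystone_k`, incubation settings (`incubation_n`, `noise_sd`)
#'   and the master `seed`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_otus = 60, n_samples = 30, block_sizes = "5,5,5",
              block_rho = 0.9, guild_denitrification = 0.3,
              guild_dnra = 0.1, depth = 10000, drop_singletons = 1,
              min_prevalence = 10, top_n = 1000, bottom_n = 1000,
              n_perm = 100, n_boot = 100, alpha = 0.05,
              q_threshold = 0.05, keystone_k = 7, incubation_n = 16,
              noise_sd = 0.05, seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full pipeline on simulated data
#'
#' Simulates a community and incubation set from the config, preps the
#' tables (singleton removal, prevalence filter, qPCR scaling to
#' absolute abundances), quantifies guilds and the flux scheme, infers
#' the co-occurrence network, extracts keystones and computes the
#' stoichiometry table; writes every artifact plus a manifest and a
#' log into `out_dir`.  Identical config and seed reproduce identical
#' outputs.
#'
#' @param config A [pipeline_config()] list or a config file path.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("nitroguild %s run, seed %d\n",
              as.character(packageVersion("nitroguild")), cfg$seed),
      file = log_path)
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  counts <- list()

  sim <- stage("simulate", {
    guild_spec <- c(denitrification = cfg$guild_denitrification,
                    DNRA = cfg$guild_dnra)
    blocks <- as.integer(strsplit(as.character(cfg$block_sizes),
                                  ",")[[1]])
    generate_community(cfg$n_otus, cfg$n_samples, blocks = blocks,
                       block_rho = cfg$block_rho,
                       guild_spec = guild_spec[guild_spec > 0],
                       depth = cfg$depth, seed = cfg$seed)
  })
  logline("simulate: %d OTUs x %d samples, depth %d", cfg$n_otus,
          cfg$n_samples, cfg$depth)

  prepped <- stage("prep", {
    tab <- sim$counts
    if (cfg$drop_singletons) tab <- remove_singletons(tab)
    tab <- prevalence_filter(tab, cfg$min_prevalence)
    to_absolute(to_relative(tab), sim$taxonomy, sim$qpcr)
  })
  counts$prep_otus <- nrow(prepped$values)
  logline("prep: %d OTUs retained after filters", counts$prep_otus)
  write_otu_table(prepped, file.path(out_dir, "absolute.tsv"),
                  taxonomy = sim$taxonomy)

  pa <- stage("guilds", {
    gm <- suppressMessages(assign_guilds(sim$taxonomy, sim$annotation))
    quantify_guilds(prepped, gm, annotation = sim$annotation,
                    taxonomy = sim$taxonomy)
  })
  ratios <- denit_dnra_ratio(pa)
  logline("guilds: denitrification:DNRA ratio %s",
          paste(sprintf("%s=%.3f", names(ratios), ratios), collapse = " "))
  write.table(data.frame(pathway = rownames(pa$pathways), pa$pathways,
                         check.names = FALSE),
              file.path(out_dir, "pathway_abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(flux_scheme(pa), file.path(out_dir, "flux_scheme.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  net <- stage("network", {
    n <- suppressWarnings(infer_network(
      prepped, top_n = cfg$top_n, bottom_n = cfg$bottom_n,
      n_perm = cfg$n_perm, n_boot = cfg$n_boot, alpha = cfg$alpha,
      q_threshold = cfg$q_threshold, seed = cfg$seed))
    gm <- suppressMessages(assign_guilds(sim$taxonomy, sim$annotation))
    annotate_network(n, table = prepped, taxonomy = sim$taxonomy,
                     guild_map = gm)
  })
  counts$candidates <- unname(net$counts["candidates"])
  counts$stable_edges <- unname(net$counts["stable"])
  counts$retained_edges <- unname(net$counts["retained"])
  logline("network: %d candidates, %d stable, %d retained",
          counts$candidates, counts$stable_edges, counts$retained_edges)
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  write_network(net, file.path(out_dir, "edges.tsv"), "edge_tsv")

  keyst <- stage("keystones", {
    if (igraph::vcount(net$graph) == 0) {
      data.frame(otu_id = character(0), degree = integer(0),
                 betweenness = numeric(0), closeness = numeric(0))
    } else {
      cent <- centralities(net)
      identify_keystones(cent, k = min(cfg$keystone_k, nrow(cent)))
    }
  })
  counts$keystones <- nrow(keyst)
  logline("keystones: %d reported", counts$keystones)
  write_keystones(keyst, file.path(out_dir, "keystones.tsv"))

  stoich <- stage("biogeochem", {
    rec <- generate_incubation(cfg$incubation_n, noise_sd = cfg$noise_sd,
                               seed = cfg$seed)
    stoichiometry(rec)
  })
  logline("biogeochem: %d samples, mean Cmic %.1f", nrow(stoich),
          mean(stoich$cmic))
  write.table(stoich, file.path(out_dir, "stoichiometry.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  artifacts <- c("absolute.tsv", "pathway_abundance.tsv",
                 "flux_scheme.tsv", "network.graphml", "edges.tsv",
                 "keystones.tsv", "stoichiometry.tsv")
  manifest <- list(
    version = as.character(packageVersion("nitroguild")),
    seed = cfg$seed, config = cfg, counts = counts,
    checksums = tools::md5sum(file.path(out_dir, artifacts)))
  dcf <- cbind(
    version = manifest$version, seed = cfg$seed,
    do.call(cbind, lapply(cfg, as.character)),
    do.call(cbind, lapply(counts, as.character)),
    do.call(cbind, setNames(as.list(unname(manifest$checksums)),
                            paste0("md5_", artifacts))))
  write.dcf(dcf, file.path(out_dir, "manifest.dcf"))
  logline("done: %d artifacts", length(artifacts))
  invisible(manifest)
}
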