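# Synthetic community and incubation generators with known ground
# truth, so every downstream stage has a recovery test without any
# external data.  Absolute abundances have log-normal marginals
# coupled by a Gaussian copula with equicorrelated planted blocks;
# counts are multinomial subsamples at fixed depth; guild genes are
# planted on the highest-abundance OTUs until target abundance
# fractions are met.

#' Generate a synthetic community with planted structure
#'
#' Per sample, OTU abundances are drawn as `qlnorm(pnorm(Z))` where
#' `Z` is standard normal with within-block correlation `rho`
#' (equicorrelated factor construction, zero correlation between
#' blocks) — so planted blocks co-occur while everything else is
#' independent.  Sequencing counts are multinomial draws of size
#' `depth` from the per-sample relative abundances.  Each OTU gets a
#' unique genus; N-cycle genes are planted genus-wise on the
#' highest-abundance OTUs (descending, pathways disjoint) until each
#' pathway's target fraction of total absolute abundance is reached;
#' the overshoot is at most one OTU's share and the realized fraction
#' is recorded in the ground truth.
#'
#' @param n_otus Number of OTUs (>= largest block).
#' @param n_samples Number of samples.
#' @param blocks Planted co-occurring blocks: a list of integer
#'   vectors (explicit OTU indices, disjoint) or an integer vector of
#'   block sizes (assigned to consecutive OTUs from the first).
#' @param block_rho Within-block correlation(s) in (0, 1], recycled
#'   over blocks.
#' @param guild_spec Named numeric: target fraction of total absolute
#'   abundance per pathway (names from [gene_pathways()]), each in
#'   `[0, 1]`.
#' @param depth Sequencing depth per sample (>= 100).
#' @param seed Integer seed (single RNG stream; output is
#'   reproducible bit-for-bit).
#' @param meanlog,sdlog Log-normal marginal parameters (heavy-tailed
#'   abundance distribution; defaults 0 and 1).
#' @param archaeal_fraction Fraction of OTUs labelled Archaea (the
#'   rest are Bacteria), to exercise per-domain qPCR scaling.
#' @return List with `counts` and `absolute` ([sample_table()]s),
#'   `taxonomy`, `annotation`, `qpcr` (per-sample per-domain copy
#'   totals consistent with the absolute table) and `truth`
#'   (`block_members`, `block_rho`, `guild_fraction` targets,
#'   `realized_fraction`, `guild_otus`, `qpcr_totals`, `seed`).
#' @export
generate_community <- function(n_otus, n_samples, blocks = list(),
                               block_rho = 0.9, guild_spec = numeric(0),
                               depth = 10000, seed = 1, meanlog = 0,
                               sdlog = 1, archaeal_fraction = 0) {
  if (depth < 100) stop("depth must be >= 100")
  if (is.numeric(blocks) && !is.list(blocks)) {
    sizes <- as.integer(blocks)
    ends <- cumsum(sizes)
    blocks <- lapply(seq_along(sizes),
                     function(b) (c(0, ends)[b] + 1):ends[b])
  }
  if (length(blocks) > 0) {
    all_members <- unlist(blocks)
    if (anyDuplicated(all_members)) stop("block member sets must be disjoint")
    if (max(all_members) > n_otus)
      stop("n_otus must be >= the largest block index")
  }
  rho <- rep_len(block_rho, max(1, length(blocks)))
  if (any(rho <= 0 | rho > 1))
    stop("block_rho must be in (0, 1] (implied correlation not valid)")
  if (length(guild_spec) > 0) {
    if (is.null(names(guild_spec)) ||
        !all(names(guild_spec) %in% names(NG_PATHWAYS)))
      stop("guild_spec must be named by pathway: ",
           paste(names(NG_PATHWAYS), collapse = ", "))
    if (any(guild_spec < 0 | guild_spec > 1))
      stop("infeasible guild_spec: fractions must be in [0, 1]")
    if (sum(guild_spec) > 1)
      stop("infeasible guild_spec: disjoint pathway fractions sum above 1")
  }

  set.seed(seed)
  otu <- sprintf("OTU_%04d", seq_len(n_otus))
  smp <- sprintf("S%02d", seq_len(n_samples))

  # Gaussian copula: shared block factor + independent residual
  Z <- matrix(rnorm(n_otus * n_samples), n_otus, n_samples)
  for (b in seq_along(blocks)) {
    W <- rnorm(n_samples)
    idx <- blocks[[b]]
    Z[idx, ] <- sqrt(rho[b]) * matrix(W, length(idx), n_samples,
                                      byrow = TRUE) +
      sqrt(1 - rho[b]) * Z[idx, , drop = FALSE]
  }
  abs_mat <- stats::qlnorm(stats::pnorm(Z), meanlog = meanlog,
                           sdlog = sdlog)
  dimnames(abs_mat) <- list(otu, smp)

  counts <- vapply(seq_len(n_samples), function(j)
    rmultinom(1, depth, abs_mat[, j])[, 1], numeric(n_otus))
  dimnames(counts) <- list(otu, smp)

  domain <- rep("Bacteria", n_otus)
  if (archaeal_fraction > 0) {
    n_arc <- round(archaeal_fraction * n_otus)
    if (n_arc > 0) domain[sample.int(n_otus, n_arc)] <- "Archaea"
  }
  taxonomy <- taxonomy_map(data.frame(
    otu_id = otu, domain = domain,
    phylum = ifelse(domain == "Archaea", "Thaumarchaeota", "Acidobacteria"),
    genus = sprintf("Genus_%04d", seq_len(n_otus)),
    stringsAsFactors = FALSE))

  # plant guild genes on the highest-abundance OTUs, pathways disjoint
  share <- rowSums(abs_mat) / sum(abs_mat)
  ord <- order(share, decreasing = TRUE)
  assigned <- character(0)
  guild_otus <- list()
  realized <- numeric(0)
  ann_genus <- character(0)
  ann_genes <- character(0)
  for (p in names(guild_spec)) {
    target <- guild_spec[[p]]
    members <- character(0)
    acc <- 0
    gene_pool <- NG_PATHWAYS[[p]]
    gi <- 0L
    for (i in ord) {
      if (acc >= target) break
      id <- otu[i]
      if (id %in% assigned) next
      members <- c(members, id)
      acc <- acc + share[i]
      gi <- gi + 1L
      ann_genus <- c(ann_genus, taxonomy[id, "genus"])
      ann_genes <- c(ann_genes,
                     gene_pool[(gi - 1L) %% length(gene_pool) + 1L])
    }
    if (acc < target)
      stop("infeasible guild_spec: cannot reach fraction for ", p)
    assigned <- c(assigned, members)
    guild_otus[[p]] <- members
    realized[p] <- acc
  }
  annotation <- if (length(ann_genus) > 0)
    guild_annotation(ann_genus, ann_genes)
  else structure(list(), class = "guild_annotation")

  qpcr <- qpcr_table(
    smp,
    bacterial = colSums(abs_mat[domain == "Bacteria", , drop = FALSE]),
    archaeal = if (any(domain == "Archaea"))
      colSums(abs_mat[domain == "Archaea", , drop = FALSE]) else 0)

  truth <- list(block_members = lapply(blocks, function(b) otu[b]),
                block_rho = rho[seq_along(blocks)],
                guild_fraction = guild_spec,
                realized_fraction = realized,
                guild_otus = guild_otus,
                qpcr_totals = qpcr, seed = seed)
  list(counts = sample_table(counts, scale = "counts"),
       absolute = sample_table(abs_mat, scale = "absolute"),
       taxonomy = taxonomy, annotation = annotation, qpcr = qpcr,
       truth = truth)
}

#' Generate synthetic fumigation-extraction incubation data
#'
#' Inverse of the biomass and net-rate formulas: fumigated extract =
#' non-fumigated + true biomass times the extraction-efficiency factor
#' (0.38 for C, 0.54 for N), day-21 mineral N = day-7 + rate x 336 h,
#' with multiplicative Gaussian noise of relative SD `noise_sd` on
#' every measured quantity (noise-free fields are exact at
#' `noise_sd = 0`).
#'
#' @param n_samples Number of samples.
#' @param true_cmic,true_nmic True microbial biomass C and N
#'   (umol g-1, >= 0).
#' @param amm_rate,nit_rate True net ammonification / nitrification
#'   rates (nmol g-1 h-1).
#' @param noise_sd Relative measurement noise (>= 0).
#' @param seed Integer seed.
#' @param doc_nonfum,tn_nonfum Baseline extract concentrations
#'   (umol g-1).
#' @param nh4_d7,no3_d7 Initial mineral N concentrations (nmol g-1).
#' @param respiration Basal respiration (umol CO2-C g-1 d-1).
#' @param doc_leachate,dn_leachate,nh4_leachate,no3_leachate Leachate
#'   concentrations (umol L-1).
#' @return An [incubation_record()] with the generator parameters in
#'   `attr(, "truth")`.
#' @export
generate_incubation <- function(n_samples, true_cmic = 300,
                                true_nmic = 40, amm_rate = 0.25,
                                nit_rate = 0.05, noise_sd = 0.05,
                                seed = 1, doc_nonfum = 50, tn_nonfum = 10,
                                nh4_d7 = 100, no3_d7 = 50,
                                respiration = 3.1, doc_leachate = 764,
                                dn_leachate = 25.2, nh4_leachate = 1.0,
                                no3_leachate = 4.5) {
  if (true_cmic < 0 || true_nmic < 0) stop("true biomass must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  noisy <- function(x) {
    if (noise_sd == 0) return(rep_len(x, n_samples))
    pmax(0, rep_len(x, n_samples) * (1 + rnorm(n_samples, 0, noise_sd)))
  }
  hours <- 14 * 24
  rec <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    doc_nonfum = noisy(doc_nonfum),
    doc_fum = noisy(doc_nonfum + true_cmic * 0.38),
    tn_nonfum = noisy(tn_nonfum),
    tn_fum = noisy(tn_nonfum + true_nmic * 0.54),
    nh4_d7 = noisy(nh4_d7),
    nh4_d21 = noisy(nh4_d7 + amm_rate * hours),
    no3_d7 = noisy(no3_d7),
    no3_d21 = noisy(no3_d7 + nit_rate * hours),
    respiration = noisy(respiration),
    doc_leachate = noisy(doc_leachate),
    dn_leachate = noisy(dn_leachate),
    nh4_leachate = noisy(nh4_leachate),
    no3_leachate = noisy(no3_leachate),
    stringsAsFactors = FALSE)
  out <- incubation_record(rec)
  attr(out, "truth") <- list(true_cmic = true_cmic, true_nmic = true_nmic,
                             amm_rate = amm_rate, nit_rate = nit_rate,
                             noise_sd = noise_sd, seed = seed)
  out
}
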