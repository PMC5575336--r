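# Ensemble co-occurrence network inference: five association measures
# scored over all OTU pairs, candidate selection by top/bottom score
# thresholds, per-edge permutation nulls and bootstrap stability,
# Brown's dependent p-value merging over the measure ensemble,
# Benjamini-Hochberg correction, and signed network construction.
#
# Inputs are expected on the absolute-abundance scale: permutation
# shuffles one row's sample order without any compositional
# renormalization, because absolute abundances do not carry the
# closure constraint that creates spurious correlations in relative
# data.

MEASURE_KIND <- c(spearman = "correlation", pearson = "correlation",
                  mi = "information", braycurtis = "dissimilarity",
                  kl = "dissimilarity")

measure_index <- function(measure) {
  i <- match(measure, ng_measures())
  if (is.na(i)) stop("unknown measure: ", measure)
  i
}

#' Score all OTU pairs under one association measure
#'
#' Spearman/Pearson are computed on the raw rows; Bray-Curtis as
#' `sum|x-y| / sum(x+y)`; symmetrized Kullback-Leibler divergence on
#' Laplace-smoothed row profiles; mutual information on
#' equal-frequency-discretized rows with `floor(sqrt(n_samples))` bins.
#'
#' @param table A [sample_table()] (absolute scale recommended) with
#'   at least 4 samples; rows should be prevalence-filtered first.
#' @param measure One of [ng_measures()].
#' @return Symmetric numeric matrix of pair scores (diagonal `NA`);
#'   pairs involving a constant row under a correlation measure are
#'   `NA` and their count is reported via a message.
#' @export
score_all_pairs <- function(table, measure) {
  stopifnot(inherits(table, "sample_table"))
  if (ncol(table$values) < 4) stop("need >= 4 samples to score pairs")
  m <- cpp_score_matrix(table$values, measure_index(measure) - 1L)
  dimnames(m) <- list(otu_ids(table), otu_ids(table))
  n_na <- sum(is.na(m[upper.tri(m)]))
  if (n_na > 0)
    message(sprintf("%d pair(s) skipped under measure '%s' (undefined score)",
                    n_na, measure))
  m
}

#' Select candidate edges from per-measure score matrices
#'
#' For each measure the `top_n` highest- and `bottom_n` lowest-scoring
#' pairs are proposed (all pairs tied with the cutoff score are
#' included, so the selection is deterministic and order-independent);
#' the candidate set is the union across measures, each candidate
#' tagged with the measures that proposed it.
#'
#' @param scores Named list of symmetric score matrices, one per
#'   measure (from [score_all_pairs()]).
#' @param top_n,bottom_n Number of pairs to take from each end of each
#'   measure's score distribution (the reference configuration uses
#'   1000 and 1000).
#' @return Data.frame with columns `otu_a`, `otu_b` (canonical order
#'   `otu_a < otu_b`) and `proposed_by` (comma-separated measures).
#' @export
candidate_edges <- function(scores, top_n = 1000, bottom_n = 1000) {
  stopifnot(is.list(scores), length(scores) >= 1, top_n >= 0, bottom_n >= 0)
  ids <- rownames(scores[[1]])
  ut <- which(upper.tri(scores[[1]]), arr.ind = TRUE)
  pair_key <- paste(ids[ut[, 1]], ids[ut[, 2]], sep = "\r")
  proposed <- list()
  for (meas in names(scores)) {
    s <- scores[[meas]][ut]
    ok <- which(!is.na(s))
    if (length(ok) <= top_n + bottom_n) {
      message(sprintf(
        "measure '%s': %d scored pairs <= top_n + bottom_n; all become candidates",
        meas, length(ok)))
      sel <- ok
    } else {
      sorted <- sort(s[ok])
      hi <- if (top_n > 0)
        s[ok] >= sorted[length(sorted) - top_n + 1]
      else rep(FALSE, length(ok))
      lo <- if (bottom_n > 0) s[ok] <= sorted[bottom_n]
      else rep(FALSE, length(ok))
      sel <- ok[hi | lo]
    }
    for (i in sel) proposed[[pair_key[i]]] <- c(proposed[[pair_key[i]]], meas)
  }
  if (length(proposed) == 0)
    return(data.frame(otu_a = character(0), otu_b = character(0),
                      proposed_by = character(0), stringsAsFactors = FALSE))
  keys <- sort(names(proposed))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(otu_a = ab[, 1], otu_b = ab[, 2],
             proposed_by = vapply(proposed[keys], paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

# Permutation p-value, add-one estimator (1 + k) / (n + 1) with k the
# number of null scores as or more extreme than the observed one.
# Extremeness is the absolute deviation from the null median, i.e. the
# test looks in the direction the observed score deviates while
# remaining calibrated (uniform under the null) for both signed
# correlations and one-sided dissimilarity/information measures.
perm_pvalue <- function(obs, null, measure) {
  null <- null[is.finite(null)]
  n <- length(null)
  if (!is.finite(obs) || n == 0) return(NA_real_)
  med <- median(null)
  k <- sum(abs(null - med) >= abs(obs - med))
  (1 + k) / (n + 1)
}

# Convert a permutation score series into a p-series with the same
# extremeness rule (for Brown covariance estimation).
null_p_series <- function(obs, null, measure) {
  n <- length(null)
  dev <- abs(null - median(null))
  # k_j = #{|null - med| >= dev_j} = n - #{< dev_j}
  (1 + (n - rank(dev, ties.method = "min") + 1)) / (n + 1)
}

#' Permutation null and bootstrap stability for one edge
#'
#' The permutation null shuffles one row's sample order (`n_perm`
#' iterations); the p-value is the add-one estimator
#' `(1 + k)/(n_perm + 1)` with `k` the number of null scores as or
#' more extreme than the observed one (absolute deviation from the
#' null median, so the minimum attainable p at 100 permutations is
#' 1/101 and a score equal to every null score gives p = 1).  The bootstrap resamples samples
#' with replacement (`n_boot` iterations; draws with fewer than 3
#' distinct samples are redrawn, with capped retries) and the edge is
#' stable when the permutation-null median lies outside the central
#' bootstrap interval `[100*alpha/2, 100*(1-alpha/2)]` percentiles.
#'
#' @param table A [sample_table()].
#' @param pair Character vector of two OTU ids.
#' @param measure One of [ng_measures()].
#' @param n_perm,n_boot Iteration counts (default 100 each).
#' @param alpha Stability level (default 0.05).
#' @param stability_test `"disjoint"` (default): the edge is stable
#'   when the central bootstrap and permutation-null intervals are
#'   disjoint — the operational reading of filtering edges whose
#'   bootstrap distribution overlaps the null; `"median"`: stable when
#'   the null median lies outside the bootstrap interval (weaker).
#' @param seed Integer seed.
#' @return List with `score`, `p_perm`, `boot_interval` (lo, hi),
#'   `null_interval`, `stable`, and the raw `null` and `boot` score
#'   vectors.
#' @export
edge_null_and_stability <- function(table, pair, measure, n_perm = 100,
                                    n_boot = 100, alpha = 0.05,
                                    stability_test = c("disjoint", "median"),
                                    seed = 1) {
  stopifnot(inherits(table, "sample_table"), length(pair) == 2)
  stability_test <- match.arg(stability_test)
  mi <- measure_index(measure)
  set.seed(seed)
  st <- cpp_edge_stats(table$values[pair[1], ], table$values[pair[2], ],
                       n_perm, n_boot)
  obs <- st$obs[mi]
  null <- st$null[, mi]
  boot <- st$boot[, mi]
  probs <- c(alpha / 2, 1 - alpha / 2)
  ival <- unname(quantile(boot, probs, na.rm = TRUE))
  nival <- unname(quantile(null, probs, na.rm = TRUE))
  stable <- if (stability_test == "disjoint") {
    all(is.finite(c(ival, nival))) &&
      (ival[1] > nival[2] || ival[2] < nival[1])
  } else {
    nm <- median(null, na.rm = TRUE)
    is.finite(nm) && (nm < ival[1] || nm > ival[2])
  }
  list(score = obs,
       p_perm = perm_pvalue(obs, null, measure),
       boot_interval = ival, null_interval = nival, stable = stable,
       null = null, boot = boot)
}

#' Brown's method for merging dependent p-values
#'
#' Extends Fisher's combination `X = sum(-2 log p)` to dependent tests
#' by moment matching: with `E[X] = 2k` and
#' `Var(X) = 4k + 2 sum_{i<j} cov_ij` (covariances of the `-2 log p`
#' terms), `X` is treated as `c * chisq(f)` with `c = Var/(2E)` and
#' `f = 2 E^2 / Var`; the merged p-value is the upper tail at `X/c`.
#' With a zero covariance matrix this is exactly Fisher's method.
#'
#' @param p Numeric vector of >= 2 p-values in (0, 1].
#' @param cov_mat Covariance matrix of the `-2 log p` terms across
#'   tests (e.g. estimated from permutation p-series); `NULL` for
#'   independence (Fisher).
#' @return Merged p-value.
#' @export
merge_brown <- function(p, cov_mat = NULL) {
  if (length(p) < 2) stop("merge_brown needs >= 2 p-values")
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clamped to machine minimum")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (any(p > 1)) stop("p-values must be in (0, 1]")
  k <- length(p)
  X <- sum(-2 * log(p))
  EX <- 2 * k
  VX <- 4 * k
  if (!is.null(cov_mat)) {
    stopifnot(nrow(cov_mat) == k, ncol(cov_mat) == k)
    VX <- VX + 2 * sum(cov_mat[upper.tri(cov_mat)])
  }
  if (!is.finite(VX) || VX <= 0) VX <- 4 * k
  cc <- VX / (2 * EX)
  f <- 2 * EX^2 / VX
  pchisq(X / cc, df = f, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment,
#' `q_i = min_{j: p_(j) >= p_(i)} min(1, p_(j) * m / j)`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in the input order (empty input gives an empty
#'   vector).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

# Majority vote over signed evidence: correlation measures vote by the
# sign of their observed score, dissimilarity measures vote co-presence
# when the observed score is below the permutation-null median
# (closer than expected by chance); MI is unsigned and abstains.
# Ties default to co-presence.
edge_sign <- function(obs, null_medians, measures) {
  votes <- integer(0)
  for (m in measures) {
    kind <- MEASURE_KIND[[m]]
    if (kind == "correlation" && is.finite(obs[m])) {
      votes <- c(votes, if (obs[m] >= 0) 1L else -1L)
    } else if (kind == "dissimilarity" && is.finite(obs[m]) &&
               is.finite(null_medians[m])) {
      votes <- c(votes, if (obs[m] < null_medians[m]) 1L else -1L)
    }
  }
  if (sum(votes) >= 0) "co-presence" else "exclusion"
}

#' Infer an ensemble co-occurrence network
#'
#' Full inference chain: per-measure all-pair scoring, top/bottom
#' candidate selection, shared permutation nulls and bootstrap
#' stability per candidate edge, stability filtering (per measure the
#' bootstrap interval must be disjoint from the permutation-null
#' interval, aggregated over measures by `stable_rule`), merging of
#' the per-measure permutation evidence across the ensemble,
#' Benjamini-Hochberg correction over the stable edges, and signed
#' network construction at `q <= q_threshold`.
#'
#' Two merge methods are available.  The default `"empirical"` method
#' evaluates Fisher's statistic `X = sum(-2 log p)` against the
#' edge's own joint permutation null: because one shared shuffle per
#' iteration scores all measures simultaneously, the per-iteration
#' p-vectors carry the exact cross-measure dependence, and ranking
#' the observed `X` within the pooled set of 101 candidates gives a
#' merged p-value that is exactly uniform under the null.  The
#' `"brown"` method applies Brown's scaled chi-square approximation
#' ([merge_brown()]) with the covariance estimated from the edge's
#' permutation p-series (Fisher fallback when estimation is
#' degenerate); it is the textbook form but inherits the chi-square
#' approximation error at 100 permutations.
#'
#' @param table A [sample_table()], prevalence-filtered, ideally on
#'   `absolute` scale (a warning is issued otherwise).
#' @param measures Subset of [ng_measures()] (default: all five).
#' @param top_n,bottom_n Candidate selection thresholds per measure.
#' @param n_perm,n_boot Permutation and bootstrap iteration counts.
#' @param alpha Bootstrap stability level.
#' @param q_threshold BH-adjusted significance threshold for retained
#'   edges.
#' @param stable_rule How per-measure stability aggregates to the edge
#'   level: `"majority"` (strict majority of measures stable; default)
#'   or `"all"` (every measure stable; strictest).
#' @param stability_test Per-measure stability criterion, see
#'   [edge_null_and_stability()].
#' @param merge_method `"empirical"` (default) or `"brown"`, see
#'   Details.
#' @param seed Integer seed governing all randomization.
#' @return An `ng_network`: list with `graph` (igraph), `edges` (the
#'   full candidate edge table with per-measure scores, p-values,
#'   bootstrap intervals, stability, merged p, q, sign, retained flag),
#'   `params` and `counts`.
#' @export
infer_network <- function(table, measures = ng_measures(), top_n = 1000,
                          bottom_n = 1000, n_perm = 100, n_boot = 100,
                          alpha = 0.05, q_threshold = 0.05,
                          stable_rule = c("majority", "all"),
                          stability_test = c("disjoint", "median"),
                          merge_method = c("empirical", "brown"),
                          seed = 1) {
  stopifnot(inherits(table, "sample_table"))
  stable_rule <- match.arg(stable_rule)
  stability_test <- match.arg(stability_test)
  merge_method <- match.arg(merge_method)
  measures <- match.arg(measures, ng_measures(), several.ok = TRUE)
  if (table$scale != "absolute")
    warning("co-occurrence inference is recommended on absolute abundances; ",
            "input scale is '", table$scale, "'")
  scores <- lapply(setNames(measures, measures),
                   function(m) suppressMessages(score_all_pairs(table, m)))
  cand <- candidate_edges(scores, top_n = top_n, bottom_n = bottom_n)
  n_cand <- nrow(cand)
  midx <- vapply(measures, measure_index, 0L)

  set.seed(seed)
  k <- length(measures)
  score_m <- p_m <- lo_m <- hi_m <- med_m <- stab_m <-
    matrix(NA_real_, n_cand, k, dimnames = list(NULL, measures))
  p_merged <- rep(NA_real_, n_cand)
  fisher_fallback <- 0L
  for (i in seq_len(n_cand)) {
    st <- cpp_edge_stats(table$values[cand$otu_a[i], ],
                         table$values[cand$otu_b[i], ], n_perm, n_boot)
    obs <- st$obs[midx]
    names(obs) <- measures
    nullm <- st$null[, midx, drop = FALSE]
    bootm <- st$boot[, midx, drop = FALSE]
    pser <- matrix(NA_real_, n_perm, k)
    for (j in seq_len(k)) {
      m <- measures[j]
      nj <- nullm[, j]
      score_m[i, j] <- obs[j]
      p_m[i, j] <- perm_pvalue(obs[j], nj, m)
      probs <- c(alpha / 2, 1 - alpha / 2)
      bq <- quantile(bootm[, j], probs, na.rm = TRUE)
      lo_m[i, j] <- bq[1]; hi_m[i, j] <- bq[2]
      med_m[i, j] <- median(nj, na.rm = TRUE)
      stab_m[i, j] <- if (stability_test == "disjoint") {
        nq <- quantile(nj, probs, na.rm = TRUE)
        as.numeric(all(is.finite(c(bq, nq))) &&
                     (bq[1] > nq[2] || bq[2] < nq[1]))
      } else {
        as.numeric(is.finite(med_m[i, j]) &&
                     (med_m[i, j] < bq[1] || med_m[i, j] > bq[2]))
      }
      if (merge_method == "brown" && all(is.finite(nj)))
        pser[, j] <- null_p_series(obs[j], nj, m)
    }
    pv <- p_m[i, ]
    if (k == 1) {
      p_merged[i] <- pv[1]
    } else if (merge_method == "empirical") {
      # pooled exchangeable evaluation of Fisher's statistic: the
      # observed score and its n_perm null scores form 101 candidates,
      # each converted to a p-value against the pooled set; the merged
      # p is the observed X's tail rank among the candidate X's.
      Xc <- numeric(n_perm + 1)
      okm <- 0L
      for (j in seq_len(k)) {
        sc <- c(obs[j], nullm[, j])
        if (!all(is.finite(sc))) next
        dev <- abs(sc - median(sc))
        pc <- (length(sc) - rank(dev, ties.method = "min") + 1) /
          length(sc)
        Xc <- Xc - 2 * log(pc)
        okm <- okm + 1L
      }
      if (okm >= 1) p_merged[i] <- sum(Xc >= Xc[1]) / length(Xc)
    } else if (all(is.finite(pv))) {
      ok <- complete.cases(pser)
      if (sum(ok) >= 10) {
        p_merged[i] <- merge_brown(pv, stats::cov(-2 * log(pser[ok, ,
                                                                drop = FALSE])))
      } else {
        fisher_fallback <- fisher_fallback + 1L
        p_merged[i] <- merge_brown(pv, cov_mat = NULL)
      }
    }
  }
  if (fisher_fallback > 0)
    warning(sprintf(
      "Brown covariance estimation degenerate for %d edge(s); Fisher fallback used",
      fisher_fallback))

  stable <- if (stable_rule == "all") {
    rowSums(stab_m == 1, na.rm = TRUE) == k
  } else {
    rowSums(stab_m == 1, na.rm = TRUE) > k / 2
  }
  q <- rep(NA_real_, n_cand)
  if (any(stable & is.finite(p_merged)))
    q[stable & is.finite(p_merged)] <-
      bh_fdr(p_merged[stable & is.finite(p_merged)])
  sign_lab <- vapply(seq_len(n_cand), function(i)
    edge_sign(score_m[i, ], med_m[i, ], measures), "")
  retained <- stable & !is.na(q) & q <= q_threshold

  edges <- data.frame(cand, stringsAsFactors = FALSE)
  for (j in seq_along(measures)) {
    m <- measures[j]
    edges[[paste0("score_", m)]] <- score_m[, j]
    edges[[paste0("p_", m)]] <- p_m[, j]
    edges[[paste0("boot_lo_", m)]] <- lo_m[, j]
    edges[[paste0("boot_hi_", m)]] <- hi_m[, j]
  }
  edges$stable <- stable
  edges$p_merged <- p_merged
  edges$q <- q
  edges$sign <- sign_lab
  edges$retained <- retained

  net <- build_network(edges, q_threshold = q_threshold)
  net$params <- list(measures = measures, top_n = top_n,
                     bottom_n = bottom_n, n_perm = n_perm, n_boot = n_boot,
                     alpha = alpha, q_threshold = q_threshold,
                     stable_rule = stable_rule,
                     stability_test = stability_test,
                     merge_method = merge_method, seed = seed)
  net$counts <- c(candidates = n_cand, stable = sum(stable),
                  retained = sum(retained))
  net
}

#' Simulate merged p-values under the global null
#'
#' Draws independent log-normal abundance rows (no association), runs
#' the per-edge permutation machinery and merges the five measures'
#' evidence exactly as [infer_network()] does.  Used to check that
#' merged p-values are uniform under the null (calibration of the
#' ensemble test).
#'
#' @param n_edges Number of independent null edges to simulate.
#' @param n_samples Samples per row.
#' @param n_perm Permutation iterations per edge.
#' @param seed Integer seed.
#' @param merge_method `"empirical"` (default) or `"brown"`, as in
#'   [infer_network()].
#' @return Numeric vector of `n_edges` merged p-values.
#' @export
simulate_null_merged_p <- function(n_edges, n_samples = 30, n_perm = 100,
                                   seed = 1,
                                   merge_method = c("empirical", "brown")) {
  merge_method <- match.arg(merge_method)
  set.seed(seed)
  k <- length(ng_measures())
  out <- numeric(n_edges)
  for (r in seq_len(n_edges)) {
    x <- stats::rlnorm(n_samples)
    y <- stats::rlnorm(n_samples)
    st <- cpp_edge_stats(x, y, n_perm, 0)
    if (merge_method == "empirical") {
      Xc <- numeric(n_perm + 1)
      for (j in seq_len(k)) {
        sc <- c(st$obs[j], st$null[, j])
        dev <- abs(sc - median(sc))
        pc <- (length(sc) - rank(dev, ties.method = "min") + 1) /
          length(sc)
        Xc <- Xc - 2 * log(pc)
      }
      out[r] <- sum(Xc >= Xc[1]) / length(Xc)
    } else {
      pv <- pser <- NULL
      pv <- vapply(seq_len(k), function(j)
        perm_pvalue(st$obs[j], st$null[, j], ng_measures()[j]), 0)
      pser <- vapply(seq_len(k), function(j)
        null_p_series(st$obs[j], st$null[, j], ng_measures()[j]),
        numeric(n_perm))
      out[r] <- merge_brown(pv, stats::cov(-2 * log(pser)))
    }
  }
  out
}

#' Build the signed network from merged, corrected edges
#'
#' Keeps stable edges with `q <= q_threshold`; nodes are the endpoints
#' of retained edges (isolated candidates are dropped).
#'
#' @param edges Edge table as produced by [infer_network()] (columns
#'   `otu_a`, `otu_b`, `stable`, `q`, `sign` at minimum).
#' @param q_threshold Significance threshold.
#' @return An `ng_network` list with `graph` (igraph, undirected, edge
#'   attributes `sign`, `p_merged`, `q`) and `edges` (the input table
#'   with a recomputed `retained` column).
#' @export
build_network <- function(edges, q_threshold = 0.05) {
  retained <- edges$stable & !is.na(edges$q) & edges$q <= q_threshold
  edges$retained <- retained
  kept <- edges[retained, , drop = FALSE]
  if (nrow(kept) > 0) {
    g <- igraph::graph_from_data_frame(
      kept[, c("otu_a", "otu_b")], directed = FALSE)
    igraph::E(g)$sign <- kept$sign
    igraph::E(g)$p_merged <- kept$p_merged
    igraph::E(g)$q <- kept$q
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  }
  structure(list(graph = g, edges = edges), class = "ng_network")
}

#' @export
print.ng_network <- function(x, ...) {
  cat(sprintf("ng_network: %d nodes, %d edges (of %d candidates, %d stable)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$edges), sum(x$edges$stable, na.rm = TRUE)))
  invisible(x)
}

#' Attach node annotation to a network
#'
#' Adds phylum, class, genus, mean abundance, N-cycle function and
#' centralities as node attributes, for export and keystone reporting.
#'
#' @param net An `ng_network`.
#' @param table The [sample_table()] the network was inferred from.
#' @param taxonomy Optional `taxonomy_map`.
#' @param guild_map Optional [assign_guilds()] output.
#' @return The annotated `ng_network`.
#' @export
annotate_network <- function(net, table = NULL, taxonomy = NULL,
                             guild_map = NULL) {
  stopifnot(inherits(net, "ng_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) return(net)
  ids <- igraph::V(g)$name
  if (!is.null(taxonomy)) {
    igraph::V(g)$phylum <- taxonomy[ids, "phylum"]
    igraph::V(g)$class <- taxonomy[ids, "class"]
    igraph::V(g)$genus <- taxonomy[ids, "genus"]
  }
  if (!is.null(table))
    igraph::V(g)$mean_abundance <- rowMeans(table$values)[ids]
  if (!is.null(guild_map))
    igraph::V(g)$n_function <- vapply(guild_map[ids], n_function_label, "")
  cent <- centralities(g)
  igraph::V(g)$degree <- cent$degree
  igraph::V(g)$betweenness <- cent$betweenness
  igraph::V(g)$closeness <- cent$closeness
  net$graph <- g
  net
}
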