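# Table transformations applied before any inference: rarefaction,
# singleton and prevalence filters, relative-to-absolute scaling by
# qPCR copy numbers, alpha diversity and standard-curve quantification.

#' Rarefy a count table to even depth
#'
#' Subsamples every sample without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth` reads.
#' Samples whose total is below `depth` are dropped with a warning.
#'
#' @param table A [sample_table()] on `counts` scale.
#' @param depth Target depth (reads per sample), > 0.
#' @param seed Integer seed; rarefaction is random and the seed is
#'   mandatory for reproducibility.
#' @return A rarefied `sample_table` on `counts` scale.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "sample_table"))
  if (table$scale != "counts") stop("rarefy requires a counts-scale table")
  if (depth <= 0) stop("depth must be > 0")
  totals <- colSums(table$values)
  keep <- totals >= depth
  if (!all(keep))
    warning(sprintf("dropping %d sample(s) with fewer than %d reads: %s",
                    sum(!keep), depth,
                    paste(colnames(table$values)[!keep], collapse = ", ")))
  if (!any(keep)) stop("no sample reaches the requested depth")
  set.seed(seed)
  # muffle vegan's count-magnitude heuristic; inputs are validated counts
  sub <- withCallingHandlers(
    t(vegan::rrarefy(t(table$values[, keep, drop = FALSE]), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  grp <- if (is.null(table$group)) NULL else table$group[keep]
  sample_table(sub, scale = "counts", group = grp)
}

#' Remove whole-table singleton OTUs
#'
#' Drops OTUs with exactly one sequence in the entire dataset (total
#' count across all samples equal to 1); these most likely represent
#' sequencing/PCR errors or chimeras.  All-zero OTUs are not singletons
#' and are retained.
#'
#' @param table A [sample_table()] on `counts` scale.
#' @return Filtered `sample_table`.
#' @export
remove_singletons <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (table$scale != "counts")
    stop("singleton removal is defined on counts")
  subset_otus(table, rowSums(table$values) != 1)
}

#' Prevalence filter
#'
#' Keeps OTUs detected (value > 0) in at least `min_samples` samples.
#'
#' @param table A [sample_table()].
#' @param min_samples Minimum number of samples with presence (>= 1).
#' @return Filtered `sample_table`.
#' @export
prevalence_filter <- function(table, min_samples) {
  stopifnot(inherits(table, "sample_table"))
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (min_samples > ncol(table$values))
    stop(sprintf("min_samples (%d) exceeds number of samples (%d)",
                 min_samples, ncol(table$values)))
  subset_otus(table, rowSums(table$values > 0) >= min_samples)
}

#' Scale relative abundances to absolute copy numbers
#'
#' Converts per-sample relative OTU abundances to absolute abundances
#' (SSU gene copies per ng DNA) using per-domain qPCR copy numbers.
#' In the default `domain` mode each OTU's relative abundance is first
#' renormalized within its domain (the bacterial qPCR assay measures
#' bacterial SSU copies only), then multiplied by that domain's copy
#' number: `absolute(i,j) = rel(i,j)/sum(rel over domain d, sample j) *
#' Q_d(j)`.  The `pooled` mode skips the renormalization and scales raw
#' relative abundances by the summed copy number of all domains present.
#'
#' @param table A [sample_table()] on `relative` scale.
#' @param taxonomy A `taxonomy_map` classifying every OTU to a domain.
#' @param qpcr A [qpcr_table()] covering all samples of `table`.
#' @param mode `"domain"` (default) or `"pooled"`.
#' @return A `sample_table` on `absolute` scale.
#' @export
to_absolute <- function(table, taxonomy, qpcr, mode = c("domain", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "sample_table"), inherits(qpcr, "qpcr_table"))
  if (table$scale != "relative")
    stop("to_absolute requires a relative-scale table (run to_relative first)")
  miss_s <- setdiff(sample_ids(table), qpcr$sample_id)
  if (length(miss_s) > 0)
    stop("sample(s) missing from qPCR table: ", paste(miss_s, collapse = ", "))
  dom <- taxonomy[otu_ids(table), "domain"]
  if (any(is.na(dom)))
    stop("OTU(s) without domain classification: ",
         paste(otu_ids(table)[is.na(dom)][1:min(5, sum(is.na(dom)))],
               collapse = ", "))
  qcol <- c(Bacteria = "bacterial", Archaea = "archaeal",
            Eukaryota = "fungal", Fungi = "fungal")[dom]
  Q <- as.matrix(qpcr[sample_ids(table), c("bacterial", "archaeal", "fungal")])
  out <- matrix(0, nrow(table$values), ncol(table$values),
                dimnames = dimnames(table$values))
  if (mode == "pooled") {
    present <- unique(qcol)
    tot <- rowSums(Q[, present, drop = FALSE])
    out <- sweep(table$values, 2, tot, "*")
  } else {
    for (d in unique(qcol)) {
      rows <- which(qcol == d)
      mass <- colSums(table$values[rows, , drop = FALSE])
      qd <- Q[, d]
      zero <- mass == 0 & qd > 0
      if (any(zero))
        warning(sprintf(
          "domain '%s' has zero relative mass but nonzero qPCR copies in %d sample(s); assigning 0",
          d, sum(zero)))
      scalefac <- ifelse(mass > 0, qd / mass, 0)
      out[rows, ] <- sweep(table$values[rows, , drop = FALSE], 2, scalefac, "*")
    }
  }
  sample_table(out, scale = "absolute", group = table$group)
}

#' Alpha diversity of one sample
#'
#' Observed richness, bias-corrected Chao1 and Shannon index (natural
#' log) of a single count vector.  Chao1 uses the bias-corrected form
#' `S_obs + F1(F1-1)/(2(F2+1))` (F1/F2 singleton/doubleton counts
#' within the sample) so it is defined when no doubletons occur.
#'
#' @param x Non-negative integer count vector with at least one
#'   positive entry.
#' @return List with `observed`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  if (any(x < 0) || any(x != round(x)))
    stop("alpha_diversity expects non-negative integer counts")
  if (all(x == 0)) stop("all-zero count vector")
  pos <- x[x > 0]
  f1 <- sum(pos == 1)
  f2 <- sum(pos == 2)
  p <- pos / sum(pos)
  list(observed = length(pos),
       chao1 = length(pos) + f1 * (f1 - 1) / (2 * (f2 + 1)),
       shannon = -sum(p * log(p)))
}

#' Alpha diversity for every sample of a table
#'
#' @param table A [sample_table()] on `counts` scale.
#' @return Data.frame with one row per sample.
#' @export
alpha_diversity_table <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  res <- lapply(seq_len(ncol(table$values)),
                function(j) alpha_diversity(table$values[, j]))
  data.frame(sample_id = sample_ids(table),
             observed = vapply(res, `[[`, 0, "observed"),
             chao1 = vapply(res, `[[`, 0, "chao1"),
             shannon = vapply(res, `[[`, 0, "shannon"),
             stringsAsFactors = FALSE)
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct = slope * log10(copies) + intercept` to a
#' dilution series.  A valid curve has negative slope; slopes near
#' -3.32 correspond to perfect doubling per cycle.
#'
#' @param copies Standard concentrations (copies per microliter),
#'   at least 3 points spanning >= 2 orders of magnitude.
#' @param ct Measured quantification cycles.
#' @return A `standard_curve` with `slope`, `intercept`, `r_squared`.
#' @export
fit_standard_curve <- function(copies, ct) {
  stopifnot(length(copies) == length(ct))
  if (length(copies) < 3) stop("need >= 3 dilution points")
  if (diff(range(log10(copies))) < 2)
    stop("dilution series must span >= 2 orders of magnitude")
  fit <- lm(ct ~ log10(copies))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) stop("invalid qPCR curve")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "standard_curve")
}

#' Quantify copies from a Ct value
#' @param curve A [fit_standard_curve()] result.
#' @param ct Quantification cycle(s).
#' @return Estimated copies per microliter.
#' @export
quantify_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' qPCR amplification efficiency in percent
#'
#' `(10^(-1/slope) - 1) * 100`; 100 percent means exact doubling per
#' cycle (slope -3.3219).
#'
#' @param curve A [fit_standard_curve()] result.
#' @return Efficiency in percent.
#' @export
amplification_efficiency <- function(curve) {
  stopifnot(inherits(curve, "standard_curve"))
  (10^(-1 / curve$slope) - 1) * 100
}
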