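# Soil biogeochemical calculators: chloroform fumigation-extraction
# microbial biomass, net N transformation rates from the 7-to-21-day
# incubation interval, specific respiration, carbon/nitrogen use
# efficiency, critical C:N ratio and extracellular enzyme ratios.
# All quantities are computed per sample; group mean (SD) summaries
# are a separate step so mean-of-ratios is never silently replaced by
# ratio-of-means.

#' Build an incubation record table
#'
#' One row per sample; concentrations in the units of the field
#' convention: fumigated / non-fumigated extract DOC and total N in
#' umol g-1, day-7 / day-21 mineral N in nmol g-1, respiration in
#' umol CO2-C g-1 d-1, leachate concentrations in umol L-1.
#'
#' @param df Data.frame with columns `sample_id`, `doc_fum`,
#'   `doc_nonfum`, `tn_fum`, `tn_nonfum`, `nh4_d7`, `nh4_d21`,
#'   `no3_d7`, `no3_d21` and optionally `respiration`, `doc_leachate`,
#'   `dn_leachate`, `nh4_leachate`, `no3_leachate`, `group`.
#' @return An `incubation_record` data.frame.
#' @export
incubation_record <- function(df) {
  need <- c("sample_id", "doc_fum", "doc_nonfum", "tn_fum", "tn_nonfum",
            "nh4_d7", "nh4_d21", "no3_d7", "no3_d21")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("incubation record missing column(s): ", paste(miss, collapse = ", "))
  num <- setdiff(names(df), c("sample_id", "group"))
  if (any(as.matrix(df[, num]) < 0, na.rm = TRUE))
    stop("concentrations must be >= 0")
  class(df) <- c("incubation_record", "data.frame")
  df
}

#' Read / write incubation TSVs
#' @param path TSV path with the [incubation_record()] columns.
#' @return An `incubation_record`.
#' @export
read_incubation <- function(path) {
  incubation_record(read.delim(path, header = TRUE, sep = "\t",
                               check.names = FALSE,
                               stringsAsFactors = FALSE, quote = ""))
}

#' @rdname read_incubation
#' @param rec An `incubation_record`.
#' @export
write_incubation <- function(rec, path) {
  write.table(as.data.frame(rec), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Microbial biomass from fumigation-extraction
#'
#' `Cmic = (DOC_fumigated - DOC_nonfumigated) / kEC` and
#' `Nmic = (TN_fumigated - TN_nonfumigated) / kEN`, with the
#' extraction-efficiency factors kEC = 0.38 and kEN = 0.54.  Negative
#' extract differences are floored at zero with a warning (expected
#' only as measurement noise).
#'
#' @param rec An [incubation_record()].
#' @param kec,ken Extraction-efficiency factors in (0, 1].
#' @return Data.frame with `sample_id`, `cmic`, `nmic` (umol g-1).
#' @export
microbial_biomass <- function(rec, kec = 0.38, ken = 0.54) {
  stopifnot(inherits(rec, "incubation_record"))
  if (kec <= 0 || ken <= 0 || kec > 1 || ken > 1)
    stop("extraction efficiency factors must be in (0, 1]")
  dc <- rec$doc_fum - rec$doc_nonfum
  dn <- rec$tn_fum - rec$tn_nonfum
  if (any(dc < 0) || any(dn < 0)) {
    warning(sprintf(
      "%d negative fumigation difference(s) floored at zero",
      sum(dc < 0) + sum(dn < 0)))
    dc[dc < 0] <- 0
    dn[dn < 0] <- 0
  }
  data.frame(sample_id = rec$sample_id, cmic = dc / kec, nmic = dn / ken,
             stringsAsFactors = FALSE)
}

#' Net ammonification and nitrification rates
#'
#' Difference between the final (day 21) and initial (day 7) NH4+ and
#' NO3- concentrations divided by the 14-day (336 h) interval; may be
#' negative (net immobilization).
#'
#' @param rec An [incubation_record()].
#' @return Data.frame with `sample_id`, `net_ammonification`,
#'   `net_nitrification` (nmol g-1 h-1).
#' @export
net_rates <- function(rec) {
  stopifnot(inherits(rec, "incubation_record"))
  hours <- 14 * 24
  data.frame(sample_id = rec$sample_id,
             net_ammonification = (rec$nh4_d21 - rec$nh4_d7) / hours,
             net_nitrification = (rec$no3_d21 - rec$no3_d7) / hours,
             stringsAsFactors = FALSE)
}

#' Specific respiration
#'
#' Respiration rate per unit microbial biomass carbon, reported on the
#' nmol C per biomass-C per day scale (respiration in umol CO2-C g-1
#' d-1 over Cmic in umol g-1, times 1000).
#'
#' @param respiration Basal respiration, umol CO2-C g-1 d-1.
#' @param cmic Microbial biomass carbon, umol g-1 (> 0).
#' @return Specific respiration, nmol C per gCmic-equivalent per day.
#' @export
specific_respiration <- function(respiration, cmic) {
  if (any(cmic <= 0)) stop("cmic must be > 0")
  respiration / cmic * 1000
}

#' Carbon use efficiency from stoichiometric ratios
#'
#' Saturating stoichiometric model: with `S = B/L` (microbial biomass
#' C:N over substrate C:N), `cue = cue_max * S / (S + k_cn)`.
#'
#' @param B Microbial biomass molar C:N ratio.
#' @param L Substrate molar C:N ratio (> 0).
#' @param cue_max,k_cn Model constants (defaults 0.6 and 0.5).
#' @return Carbon use efficiency in (0, `cue_max`).
#' @export
cue_from_ratios <- function(B, L, cue_max = 0.6, k_cn = 0.5) {
  if (any(L <= 0)) stop("substrate C:N must be > 0")
  S <- B / L
  cue_max * S / (S + k_cn)
}

#' Critical C:N ratio
#'
#' Substrate C:N above which microbial growth is N-limited and net
#' immobilization is expected: biomass C:N divided by carbon use
#' efficiency.
#'
#' @param B Microbial biomass molar C:N ratio.
#' @param cue Carbon use efficiency in (0, 1].
#' @return Critical C:N ratio.
#' @export
critical_cn <- function(B, cue) {
  if (any(cue <= 0)) stop("cue must be > 0")
  B / cue
}

#' Carbon and nitrogen use efficiency and critical C:N
#'
#' Stoichiometric model: with biomass ratio `B = Cmic/Nmic` and
#' substrate ratio `L` (leachate DOC/DN by default, or
#' DOC/(NO3- + NH4+) with `substrate = "doc_mineral"`), the imbalance
#' `S = B/L` saturates carbon use efficiency as
#' `cue = cue_max * S / (S + k_cn)`; nitrogen use efficiency is
#' `nue = min(1, cue * L / B)` and the critical C:N ratio is
#' `B / cue`.
#'
#' @param rec An [incubation_record()] providing the leachate columns.
#' @param cmic,nmic Microbial biomass C and N (umol g-1, > 0), e.g.
#'   from [microbial_biomass()].
#' @param substrate `"doc_dn"` (default) or `"doc_mineral"`.
#' @param cue_max Maximum CUE of the saturating model (default 0.6).
#' @param k_cn Half-saturation constant of the model (default 0.5).
#' @return Data.frame with `sample_id`, `cue`, `nue`, `critical_cn`.
#' @export
cue_nue_critical <- function(rec, cmic, nmic,
                             substrate = c("doc_dn", "doc_mineral"),
                             cue_max = 0.6, k_cn = 0.5) {
  stopifnot(inherits(rec, "incubation_record"))
  substrate <- match.arg(substrate)
  if (any(cmic <= 0) || any(nmic <= 0)) stop("cmic and nmic must be > 0")
  B <- cmic / nmic
  L <- if (substrate == "doc_dn") {
    rec$doc_leachate / rec$dn_leachate
  } else {
    rec$doc_leachate / (rec$no3_leachate + rec$nh4_leachate)
  }
  if (any(!is.finite(L) | L <= 0)) stop("substrate C:N must be finite and > 0")
  cue <- cue_from_ratios(B, L, cue_max = cue_max, k_cn = k_cn)
  data.frame(sample_id = rec$sample_id, cue = cue,
             nue = pmin(1, cue * L / B), critical_cn = critical_cn(B, cue),
             stringsAsFactors = FALSE)
}

#' Extracellular enzyme activity ratios
#'
#' C-to-nutrient acquisition ratios BG/PME, BG/NAG and BG/LEU from
#' per-sample enzyme activities (umol g-1 h-1); a zero denominator
#' yields `NA`.
#'
#' @param activities Data.frame or named list with columns/elements
#'   `BG`, `PME`, `NAG`, `LEU`.
#' @return Data.frame with `bg_pme`, `bg_nag`, `bg_leu`.
#' @export
enzyme_ratios <- function(activities) {
  need <- c("BG", "PME", "NAG", "LEU")
  miss <- setdiff(need, names(activities))
  if (length(miss) > 0)
    stop("missing enzyme activitie(s): ", paste(miss, collapse = ", "))
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(bg_pme = ratio(activities$BG, activities$PME),
             bg_nag = ratio(activities$BG, activities$NAG),
             bg_leu = ratio(activities$BG, activities$LEU))
}

#' Full per-sample stoichiometry table
#'
#' Convenience wrapper chaining [microbial_biomass()], [net_rates()],
#' [specific_respiration()] and [cue_nue_critical()].
#'
#' @param rec An [incubation_record()] (with `respiration` and
#'   leachate columns for the dependent quantities).
#' @param substrate Passed to [cue_nue_critical()].
#' @param kec,ken Passed to [microbial_biomass()].
#' @return Data.frame, one row per sample.
#' @export
stoichiometry <- function(rec, substrate = "doc_dn", kec = 0.38,
                          ken = 0.54) {
  bm <- microbial_biomass(rec, kec = kec, ken = ken)
  nr <- net_rates(rec)
  out <- merge(bm, nr, by = "sample_id", sort = FALSE)
  out$cmic_nmic <- out$cmic / out$nmic
  if ("respiration" %in% names(rec))
    out$specific_respiration <- specific_respiration(rec$respiration,
                                                     out$cmic)
  if (all(c("doc_leachate", "dn_leachate") %in% names(rec)))
    out <- merge(out,
                 cue_nue_critical(rec, out$cmic, out$nmic,
                                  substrate = substrate),
                 by = "sample_id", sort = FALSE)
  if ("group" %in% names(rec)) out$group <- rec$group
  out
}

#' Group mean (SD) summary of a stoichiometry table
#'
#' @param stoich Output of [stoichiometry()].
#' @param group Optional grouping vector (defaults to the `group`
#'   column, else one pooled group).
#' @return Data.frame of per-group means and SDs for every numeric
#'   quantity.
#' @export
summarize_stoichiometry <- function(stoich, group = NULL) {
  if (is.null(group))
    group <- if ("group" %in% names(stoich)) stoich$group
             else rep("all", nrow(stoich))
  num <- names(stoich)[vapply(stoich, is.numeric, TRUE)]
  do.call(rbind, lapply(split(seq_len(nrow(stoich)), group), function(idx) {
    m <- vapply(num, function(v) mean(stoich[[v]][idx]), 0)
    s <- vapply(num, function(v) stats::sd(stoich[[v]][idx]), 0)
    out <- data.frame(group = group[idx[1]], stringsAsFactors = FALSE)
    for (v in num) {
      out[[paste0(v, "_mean")]] <- m[[v]]
      out[[paste0(v, "_sd")]] <- s[[v]]
    }
    out
  }))
}
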