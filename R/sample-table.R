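#' OTU-by-sample abundance table
#'
#' The central container of the package: a numeric matrix with OTUs in
#' rows and samples in columns, together with a declared measurement
#' scale and an optional sample grouping (e.g. forest stand).
#'
#' @param values Numeric matrix, OTUs in rows (rownames are OTU ids),
#'   samples in columns (colnames are sample ids). No negative entries.
#' @param scale One of `"counts"` (sequence read counts), `"relative"`
#'   (per-sample proportions summing to 1) or `"absolute"` (SSU gene
#'   copies per ng DNA).
#' @param group Optional character vector of group labels, named by
#'   sample id or of length `ncol(values)`.
#'
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(values, scale = c("counts", "relative", "absolute"),
                         group = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("OTU_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at OTU '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (scale == "relative") {
    cs <- colSums(values)
    if (any(cs == 0))
      stop("all-zero sample column on relative scale: ",
           paste(colnames(values)[cs == 0], collapse = ", "))
    if (any(abs(cs - 1) > 1e-9))
      stop("relative-scale columns must sum to 1 (tolerance 1e-9); offending sample: ",
           colnames(values)[which.max(abs(cs - 1))])
  }
  if (!is.null(group)) {
    if (!is.null(names(group))) {
      missing <- setdiff(colnames(values), names(group))
      if (length(missing) > 0)
        stop("group labels missing for samples: ",
             paste(missing, collapse = ", "))
      group <- group[colnames(values)]
    } else if (length(group) != ncol(values)) {
      stop("group must be named by sample or match the number of samples")
    }
    group <- setNames(as.character(group), colnames(values))
  }
  structure(list(values = values, scale = scale, group = group),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d OTUs x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$group))
    cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$group)),
                                 table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$values)

otu_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# subset OTUs (rows) keeping metadata
subset_otus <- function(x, keep) {
  sample_table(x$values[keep, , drop = FALSE], scale = x$scale,
               group = x$group)
}

#' Convert a table to per-sample relative abundances
#'
#' @param table A [sample_table()] on any scale.
#' @return A `sample_table` on `relative` scale; columns sum to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  cs <- colSums(table$values)
  if (any(cs == 0))
    stop("cannot convert all-zero sample column(s) to relative scale: ",
         paste(colnames(table$values)[cs == 0], collapse = ", "))
  sample_table(sweep(table$values, 2, cs, "/"), scale = "relative",
               group = table$group)
}
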