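#' Construct an ExpressionSeries
#'
#' An `expression_series` is the substrate of all DNB statistics: a genes x
#' samples numeric matrix together with per-sample metadata assigning every
#' sample to one ordinal timepoint and a replicate index within it.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). No missing values are allowed.
#' @param timepoint Character or factor of length `ncol(values)` giving the
#'   timepoint label of each sample. The order of `timepoint_levels` defines
#'   the temporal order.
#' @param replicate Integer vector of length `ncol(values)`: replicate index
#'   of each sample within its timepoint.
#' @param timepoint_levels Ordered unique timepoint labels. Defaults to the
#'   order of first appearance in `timepoint`.
#' @param scale Declared scale of the values, `"log"` or `"raw"`. The DNB
#'   statistics use the values as-is; the declaration is carried as metadata
#'   so downstream reports are unambiguous.
#'
#' @return An object of class `expression_series` with fields `values`,
#'   `genes`, `samples`, `timepoint` (ordered factor), `replicate`, `scale`.
#' @export
expression_series <- function(values, timepoint, replicate,
                              timepoint_levels = NULL,
                              scale = c("log", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers")
  }
  if (anyNA(values)) {
    stop("expression values contain missing entries; ",
         "use read_expression_table(missing = \"drop\") or clean upstream")
  }
  n <- ncol(values)
  if (length(timepoint) != n || length(replicate) != n) {
    stop("`timepoint` and `replicate` must have one entry per sample")
  }
  timepoint <- as.character(timepoint)
  if (is.null(timepoint_levels)) timepoint_levels <- unique(timepoint)
  if (!all(timepoint %in% timepoint_levels)) {
    stop("timepoint labels outside `timepoint_levels`: ",
         paste(setdiff(timepoint, timepoint_levels), collapse = ", "))
  }
  tp <- factor(timepoint, levels = timepoint_levels, ordered = TRUE)
  if (any(table(tp) < 1L)) {
    stop("every declared timepoint needs at least one sample")
  }
  structure(
    list(values = values,
         genes = rownames(values),
         samples = colnames(values),
         timepoint = stats::setNames(tp, colnames(values)),
         replicate = stats::setNames(as.integer(replicate), colnames(values)),
         scale = scale),
    class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  tab <- table(x$timepoint)
  cat(sprintf("expression_series: %d genes x %d samples (%s scale)\n",
              length(x$genes), length(x$samples), x$scale))
  cat("timepoints:",
      paste(sprintf("%s(n=%d)", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' Timepoint labels of a series, in temporal order
#' @param series An `expression_series`.
#' @return Character vector of ordered timepoint labels.
#' @export
timepoints <- function(series) levels(series$timepoint)

#' Sample identifiers belonging to one timepoint
#' @param series An `expression_series`.
#' @param t A timepoint label.
#' @return Character vector of sample ids.
#' @export
timepoint_samples <- function(series, t) {
  if (!t %in% levels(series$timepoint)) {
    stop("unknown timepoint: ", t)
  }
  series$samples[series$timepoint == t]
}

#' Extract the genes x replicates submatrix of one timepoint
#' @inheritParams timepoint_samples
#' @param genes Optional gene subset (default: all genes).
#' @return Numeric matrix genes x replicates.
#' @export
timepoint_matrix <- function(series, t, genes = NULL) {
  smp <- timepoint_samples(series, t)
  if (is.null(genes)) genes <- series$genes
  missing <- setdiff(genes, series$genes)
  if (length(missing)) {
    stop("genes absent from series: ", paste(utils::head(missing, 5),
                                             collapse = ", "))
  }
  series$values[genes, smp, drop = FALSE]
}

#' Subset an expression series by genes
#' @inheritParams timepoint_samples
#' @param genes Genes to keep, in the given order.
#' @return A new `expression_series`.
#' @export
subset_genes <- function(series, genes) {
  expression_series(series$values[genes, , drop = FALSE],
                    timepoint = as.character(series$timepoint),
                    replicate = series$replicate,
                    timepoint_levels = levels(series$timepoint),
                    scale = series$scale)
}
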