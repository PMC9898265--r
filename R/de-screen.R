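# Candidate-gene screening: per-gene Welch t tests of each timepoint versus
# all other samples ("one vs rest"), Benjamini-Hochberg adjustment per
# comparison, and the union candidate set. This is a deliberately simple,
# fully self-contained stand-in for a count-model differential-expression
# stage: the pipeline only needs a candidate filter upstream of the DNB
# search, and the screen is optional — the DNB stage accepts any explicit
# candidate list.

welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
  data.frame(diff = ma - mb, t = tt, df = df, p = p)
}

#' One-vs-rest Welch screen across timepoints
#'
#' For each timepoint t, every gene is tested with a two-sided Welch
#' two-sample t test of t's samples against all remaining samples. P values
#' are Benjamini-Hochberg adjusted within each comparison (mirroring
#' per-comparison DEG calling; `bh_scope = "global"` pools all T x n_genes
#' tests instead) and the candidate set is the union over comparisons of
#' genes with q below the threshold.
#'
#' @param series An [expression_series()]; values are used as-is, so supply
#'   (approximately) log-scale data.
#' @param q_threshold FDR threshold for candidacy, default 0.05.
#' @param bh_scope `"per_comparison"` (default) or `"global"`.
#' @return A `de_result`: list with `table` (data.frame gene, comparison,
#'   diff, t, p, q) and `candidates` (character vector).
#' @export
one_vs_rest_screen <- function(series, q_threshold = 0.05,
                               bh_scope = c("per_comparison", "global")) {
  bh_scope <- match.arg(bh_scope)
  tps <- timepoints(series)
  counts <- table(series$timepoint)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop("timepoint(s) with < 2 samples: ", paste(small, collapse = ", "))
  }
  if (length(series$samples) - min(counts) < 2L) {
    stop("the 'rest' class needs >= 2 samples for every comparison")
  }
  parts <- lapply(tps, function(t) {
    in_t <- series$timepoint == t
    res <- welch_rows(series$values[, in_t, drop = FALSE],
                      series$values[, !in_t, drop = FALSE])
    data.frame(gene = series$genes,
               comparison = sprintf("%s_vs_rest", t),
               diff = res$diff, t = res$t, p = res$p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, parts)
  if (bh_scope == "per_comparison") {
    tab$q <- stats::ave(tab$p, tab$comparison,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  } else {
    tab$q <- stats::p.adjust(tab$p, "BH")
  }
  candidates <- sort(unique(tab$gene[tab$q < q_threshold]))
  structure(list(table = tab, candidates = candidates,
                 q_threshold = q_threshold, bh_scope = bh_scope),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d tests, %d candidate gene(s) at q < %g (%s BH)\n",
              nrow(x$table), length(x$candidates), x$q_threshold, x$bh_scope))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes 2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl -
#' ct_ref_ctrl)), the standard qPCR relative fold change of a target gene
#' against a reference (normalization) gene in a case versus a control
#' condition. Vectorized over its arguments.
#'
#' @param ct_target_case,ct_ref_case Ct values of target and reference gene
#'   in the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control condition.
#' @return Fold change(s); 1 means no change, 2 means one cycle earlier in
#'   the case after normalization.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  args <- cbind(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(args))) stop("all Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
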