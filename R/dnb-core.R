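# The central computation: per-timepoint group statistics (SD_in, PCC_in,
# PCC_out), the criticality index CI = sqrt(size) * (PCC_in / PCC_out) *
# SD_in, the dominant-group search, and critical-timepoint detection.
# Correlations are always computed across the replicate samples of a single
# timepoint; sample SD uses the n-1 denominator.

#' Pearson correlation of genes across one timepoint's replicates
#'
#' Zero-variance genes make the correlation undefined; such entries are set
#' to 0 (not dropped — dropping would silently change group size and hence
#' the sqrt(size) term downstream), a warning is emitted and the affected
#' genes are flagged in the `"zero_variance"` attribute.
#'
#' @param series An [expression_series()].
#' @param t Timepoint label.
#' @param genes Gene subset, |genes| >= 2.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `zero_variance` names the flagged genes (possibly empty).
#' @export
timepoint_correlation <- function(series, t, genes) {
  if (length(genes) < 2L) stop("need at least 2 genes")
  x <- timepoint_matrix(series, t, genes)
  if (ncol(x) < 3L) {
    stop(sprintf("timepoint %s has %d replicates; need >= 3 (correlation across 2 points is always +/-1)",
                 t, ncol(x)))
  }
  sds <- apply(x, 1L, stats::sd)
  zv <- rownames(x)[sds == 0]
  cm <- suppressWarnings(stats::cor(t(x)))
  if (length(zv)) {
    warning(sprintf("%d zero-variance gene(s) at %s; correlations set to 0",
                    length(zv), t))
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  attr(cm, "zero_variance") <- zv
  cm
}

#' Group statistics at one timepoint
#'
#' SD_in is the mean across group genes of the sample standard deviation
#' over the timepoint's replicates; PCC_in the mean absolute Pearson
#' correlation over all within-group pairs; PCC_out the mean absolute
#' correlation over all group x background pairs.
#'
#' @param series An [expression_series()].
#' @param group Gene set, size >= 2.
#' @param background Gene set disjoint from `group`, size >= 1.
#' @param t Timepoint label.
#' @return Named numeric vector `c(SD_in, PCC_in, PCC_out)`.
#' @export
group_stats <- function(series, group, background, t) {
  if (length(group) < 2L) stop("group must have >= 2 genes")
  if (!length(background)) stop("background must be non-empty")
  if (length(intersect(group, background))) {
    stop("group and background overlap: ",
         paste(utils::head(intersect(group, background), 5), collapse = ", "))
  }
  xg <- timepoint_matrix(series, t, group)
  xb <- timepoint_matrix(series, t, background)
  if (ncol(xg) < 3L) stop(sprintf("timepoint %s has < 3 replicates", t))

  sd_in <- mean(apply(xg, 1L, stats::sd))
  cin <- suppressWarnings(stats::cor(t(xg)))
  cin[is.na(cin)] <- 0
  pcc_in <- mean(abs(cin[upper.tri(cin)]))
  cout <- suppressWarnings(stats::cor(t(xg), t(xb)))
  cout[is.na(cout)] <- 0
  pcc_out <- mean(abs(cout))
  c(SD_in = sd_in, PCC_in = pcc_in, PCC_out = pcc_out)
}

#' Criticality index
#'
#' CI = sqrt(size) * (PCC_in / max(PCC_out, pcc_out_floor)) * SD_in. The
#' floor prevents division blow-up at near-zero cross-correlation; when it
#' engages, the returned value carries attribute `floored = TRUE`.
#'
#' @param sd_in Average within-group standard deviation (>= 0).
#' @param pcc_in Average absolute within-group correlation, in [0, 1].
#' @param pcc_out Average absolute group-background correlation, in [0, 1].
#' @param size Group size (>= 2).
#' @param pcc_out_floor Denominator floor, default 1e-6.
#' @return Non-negative numeric scalar with attribute `floored`.
#' @export
criticality_index <- function(sd_in, pcc_in, pcc_out, size,
                              pcc_out_floor = 1e-6) {
  if (size < 2) stop("size must be >= 2")
  if (sd_in < 0 || pcc_in < 0 || pcc_in > 1 || pcc_out < 0 || pcc_out > 1) {
    stop("arguments outside their domains")
  }
  floored <- pcc_out < pcc_out_floor
  ci <- sqrt(size) * pcc_in / max(pcc_out, pcc_out_floor) * sd_in
  attr(ci, "floored") <- floored
  ci
}

#' Criticality profile of a gene group across all timepoints
#'
#' @param series An [expression_series()].
#' @param group Gene set (>= 2 genes).
#' @param background Background gene set; default all other genes in the
#'   series.
#' @param pcc_out_floor Passed to [criticality_index()].
#' @return A `criticality_profile` data.frame with columns timepoint, size,
#'   SD_in, PCC_in, PCC_out, CI, floored; attribute `group` holds the gene
#'   set.
#' @export
criticality_profile <- function(series, group, background = NULL,
                                pcc_out_floor = 1e-6) {
  if (is.null(background)) background <- setdiff(series$genes, group)
  tps <- timepoints(series)
  rows <- lapply(tps, function(t) {
    st <- group_stats(series, group, background, t)
    ci <- criticality_index(st["SD_in"], st["PCC_in"], st["PCC_out"],
                            length(group), pcc_out_floor)
    data.frame(timepoint = t, size = length(group),
               SD_in = unname(st["SD_in"]), PCC_in = unname(st["PCC_in"]),
               PCC_out = unname(st["PCC_out"]), CI = as.numeric(ci),
               floored = attr(ci, "floored"))
  })
  out <- do.call(rbind, rows)
  attr(out, "group") <- group
  class(out) <- c("criticality_profile", "data.frame")
  out
}

#' Detect the critical timepoint from a criticality profile
#'
#' Returns the argmax of CI. Ties are broken by the earliest timepoint and
#' flagged. A profile that is identically zero yields a structured
#' "no transition" result rather than an error.
#'
#' @param profile A `criticality_profile` (or any data.frame with columns
#'   `timepoint` and `CI`, ordered temporally).
#' @return List with `found` (logical), `timepoint` (label or NA), `index`,
#'   `tie` (logical), `ci` (the CI at the detected timepoint).
#' @export
detect_transition <- function(profile) {
  if (nrow(profile) < 2L) stop("CI must be defined for >= 2 timepoints")
  ci <- profile$CI
  if (all(ci == 0)) {
    return(list(found = FALSE, timepoint = NA_character_, index = NA_integer_,
                tie = FALSE, ci = 0))
  }
  i <- which(ci == max(ci))
  tie <- length(i) > 1L
  if (tie) message("CI tie across timepoints; reporting the earliest")
  i <- i[1L]
  list(found = TRUE, timepoint = profile$timepoint[i], index = i,
       tie = tie, ci = ci[i])
}

#' Search for the dominant (maximum-CI) gene group
#'
#' The DNB criteria define what the dominant group looks like, not how to
#' find it; this search is the package's explicit design. Per timepoint:
#' (1) absolute Pearson correlation among candidate genes across that
#' timepoint's replicates; (2) average-linkage hierarchical clustering on
#' distance 1 - |PCC|; (3) every dendrogram clade whose merge height is at
#' most `cut_height` and whose size is at least `min_group_size` becomes a
#' candidate group — this includes the clusters of a fixed-height cut and
#' their nested subclades, so the criticality index itself selects the group
#' granularity instead of a single arbitrary cut absorbing weakly attached
#' genes; (4) each candidate group is scored by its CI at that timepoint
#' against the background. Each candidate group's CI is evaluated across
#' every timepoint, and the dominant group is selected by the
#' `selection` rule:
#' \describe{
#'   \item{`"excess"` (default)}{maximizes the group's CI at its formation
#'     timepoint minus the median of its CI over all timepoints. This
#'     operationalizes the defining property of a dynamic biomarker — the
#'     score escalates at the triggering phase — and protects against large
#'     constitutively co-expressed modules whose CI is high at every
#'     timepoint purely through the sqrt(size) term.}
#'   \item{`"max"`}{the plain rule: the (clade, timepoint) pair with the
#'     globally maximal CI.}
#' }
#' The critical timepoint is the selected group's formation timepoint.
#' With few replicates (< 5) sample correlations are very noisy and a
#' warning is issued; recovery guarantees assume larger `n_rep`.
#'
#' @param series An [expression_series()].
#' @param candidates Candidate gene set (e.g. from [one_vs_rest_screen()]);
#'   default all genes.
#' @param min_group_size Smallest admissible cluster, default 5.
#' @param cut_height Dendrogram cut height on the 1 - |PCC| scale,
#'   default 0.5.
#' @param pcc_out_floor Denominator floor for the CI.
#' @param background `"all"` (default) scores clusters against every
#'   non-member gene in the series; `"candidates"` restricts the background
#'   to non-member candidates.
#' @param selection Dominant-group selection rule, `"excess"` (default) or
#'   `"max"`; see Details.
#' @return A `dnb_result`: list with `found`, `group`, `critical_timepoint`,
#'   `profile` (the winning group's [criticality_profile()] across all
#'   timepoints), `diagnostics` (per-timepoint data.frame of every evaluated
#'   cluster: timepoint, cluster id, size, SD_in, PCC_in, PCC_out, CI at the
#'   formation timepoint, and the selection score) and `params`. When no
#'   cluster meets `min_group_size` anywhere, `found` is FALSE and the other
#'   fields are empty — not an error.
#' @export
find_dominant_group <- function(series, candidates = NULL,
                                min_group_size = 5, cut_height = 0.5,
                                pcc_out_floor = 1e-6,
                                background = c("all", "candidates"),
                                selection = c("excess", "max")) {
  background <- match.arg(background)
  selection <- match.arg(selection)
  if (is.null(candidates)) candidates <- series$genes
  candidates <- intersect(series$genes, candidates)
  if (length(candidates) < min_group_size) {
    stop("fewer candidates than min_group_size")
  }
  n_rep <- min(table(series$timepoint))
  if (n_rep < 3L) stop("every timepoint needs >= 3 replicates")
  if (n_rep < 5L) {
    warning(sprintf("smallest timepoint has %d replicates; sample correlations will be noisy",
                    n_rep))
  }

  universe <- if (background == "all") series$genes else candidates
  tps <- timepoints(series)
  if (length(tps) < 2L && selection == "excess") selection <- "max"

  # pass 1: per-timepoint clustering of the candidates -> candidate clades
  clades <- list()   # each: list(tp_index, genes)
  for (ti in seq_along(tps)) {
    xc <- timepoint_matrix(series, tps[ti], candidates)
    acm <- abs(suppressWarnings(stats::cor(t(xc))))
    acm[is.na(acm)] <- 0
    diag(acm) <- 1
    hc <- stats::hclust(stats::as.dist(1 - acm), method = "average")
    for (m in dendrogram_clades(hc, cut_height, min_group_size)) {
      clades[[length(clades) + 1L]] <- list(ti = ti, genes = candidates[m])
    }
  }

  # pass 2: one correlation computation per timepoint scores every clade's
  # CI profile; memory stays candidates x universe
  n_univ <- length(universe)
  ci_prof <- matrix(NA_real_, length(clades), length(tps))
  stats_at_t <- vector("list", length(clades))
  for (ti in seq_along(tps)) {
    xu <- timepoint_matrix(series, tps[ti], universe)
    sds <- apply(xu, 1L, stats::sd)
    cc <- abs(suppressWarnings(stats::cor(t(xu[candidates, , drop = FALSE]),
                                          t(xu))))
    cc[is.na(cc)] <- 0
    cc[cbind(candidates, candidates)] <- 1
    for (j in seq_along(clades)) {
      grp <- clades[[j]]$genes
      k <- length(grp)
      if (n_univ - k < 1L) next
      sub <- cc[grp, grp, drop = FALSE]
      pcc_in <- (sum(sub) - k) / (k * (k - 1))
      pcc_out <- (sum(cc[grp, , drop = FALSE]) - sum(sub)) /
        (k * (n_univ - k))
      st <- c(SD_in = mean(sds[grp]), PCC_in = pcc_in, PCC_out = pcc_out)
      ci <- criticality_index(st["SD_in"], st["PCC_in"], st["PCC_out"], k,
                              pcc_out_floor)
      ci_prof[j, ti] <- as.numeric(ci)
      if (ti == clades[[j]]$ti) stats_at_t[[j]] <- st
    }
  }

  scores <- vapply(seq_along(clades), function(j) {
    own <- ci_prof[j, clades[[j]]$ti]
    if (is.na(own)) return(-Inf)
    if (selection == "excess") own - stats::median(ci_prof[j, ]) else own
  }, numeric(1))

  diag_rows <- lapply(seq_along(clades), function(j) {
    st <- stats_at_t[[j]]
    if (is.null(st)) return(NULL)
    data.frame(timepoint = tps[clades[[j]]$ti], cluster = j,
               size = length(clades[[j]]$genes),
               SD_in = unname(st["SD_in"]), PCC_in = unname(st["PCC_in"]),
               PCC_out = unname(st["PCC_out"]),
               CI = ci_prof[j, clades[[j]]$ti], score = scores[j])
  })
  diag_rows <- diag_rows[!vapply(diag_rows, is.null, logical(1))]
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(timepoint = character(0), cluster = integer(0),
               size = integer(0), SD_in = numeric(0), PCC_in = numeric(0),
               PCC_out = numeric(0), CI = numeric(0), score = numeric(0))
  params <- list(min_group_size = min_group_size, cut_height = cut_height,
                 pcc_out_floor = pcc_out_floor, background = background,
                 selection = selection, n_candidates = length(candidates))
  best <- if (length(scores) && any(is.finite(scores))) {
    j <- which.max(scores)
    list(ci = ci_prof[j, clades[[j]]$ti], group = clades[[j]]$genes,
         timepoint = tps[clades[[j]]$ti],
         background = setdiff(universe, clades[[j]]$genes))
  } else list(ci = -Inf)

  if (!is.finite(best$ci)) {
    return(structure(list(found = FALSE, group = character(0),
                          critical_timepoint = NA_character_, profile = NULL,
                          diagnostics = diagnostics, params = params),
                     class = "dnb_result"))
  }
  prof <- criticality_profile(series, best$group,
                              background = best$background,
                              pcc_out_floor = pcc_out_floor)
  structure(list(found = TRUE, group = best$group,
                 critical_timepoint = best$timepoint, profile = prof,
                 diagnostics = diagnostics, params = params),
            class = "dnb_result")
}

# Member index sets of all dendrogram clades with merge height <= cut and
# size >= min_size. Leaf-order indices refer to positions in the clustered
# label vector.
dendrogram_clades <- function(hc, cut, min_size) {
  n <- nrow(hc$merge) + 1L
  members <- vector("list", n - 1L)
  out <- list()
  for (i in seq_len(n - 1L)) {
    left <- hc$merge[i, 1L]; right <- hc$merge[i, 2L]
    m <- c(if (left < 0) -left else members[[left]],
           if (right < 0) -right else members[[right]])
    members[[i]] <- m
    if (hc$height[i] <= cut && length(m) >= min_size) {
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' @export
print.dnb_result <- function(x, ...) {
  if (!x$found) {
    cat("dnb_result: no dominant group found\n")
    return(invisible(x))
  }
  cat(sprintf("dnb_result: %d-gene dominant group, critical timepoint %s\n",
              length(x$group), x$critical_timepoint))
  print(as.data.frame(x$profile), row.names = FALSE)
  invisible(x)
}
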