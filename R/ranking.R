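# Integrated ranking of DNB members: a network index (intra-group degree
# normalized to the total number of intra-group links) and a pathway index
# (reference-pathway hits as a percentage), combined by a weighted mean.

#' Network-degree index of DNB members
#'
#' Degrees are counted on the subgraph induced by the group — the
#' normalizer L is "the total number of links among all DNB genes" — so a
#' gene's index_one is its number of links to other group members divided by
#' L. Genes absent from the network get degree 0. When the induced subgraph
#' has no edges every index is 0 and the result carries attribute
#' `no_internal_edges = TRUE`.
#'
#' @param group Non-empty gene set.
#' @param network A `gene_network` (see [read_network_edges()]).
#' @param whole_network If TRUE, count degrees in the full network instead
#'   of the induced subgraph (the normalizer stays the induced-subgraph
#'   link count L, floored at 1).
#' @return data.frame with columns gene, degree, index_one; attribute
#'   `L` (induced link count) and `no_internal_edges`.
#' @export
network_degree_index <- function(group, network, whole_network = FALSE) {
  if (!length(group)) stop("group must be non-empty")
  g <- network$graph
  present <- intersect(group, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, present)
  L <- igraph::ecount(sub)
  deg <- stats::setNames(rep(0L, length(group)), group)
  if (length(present)) {
    d <- if (whole_network) igraph::degree(g, present)
         else igraph::degree(sub, present)
    deg[names(d)] <- as.integer(d)
  }
  idx <- if (L > 0) deg / L else deg * 0
  out <- data.frame(gene = group, degree = unname(deg),
                    index_one = unname(idx), stringsAsFactors = FALSE)
  attr(out, "L") <- L
  attr(out, "no_internal_edges") <- L == 0L
  out
}

#' Pathway-hit index of DNB members
#'
#' h_i is the number of reference pathways whose gene set contains the
#' gene; index_two = 100 * h_i / total_reference_count (a percentage).
#'
#' @param group Non-empty gene set.
#' @param pathways A `pathway_collection` (see [read_gmt()]).
#' @return data.frame with columns gene, pathway_hits, index_two.
#' @export
pathway_hit_index <- function(group, pathways) {
  if (!length(group)) stop("group must be non-empty")
  total <- pathways$total_reference_count
  if (total <= 0) stop("total_reference_count must be positive")
  hits <- vapply(group, function(g) {
    sum(vapply(pathways$pathways, function(s) g %in% s, logical(1)))
  }, integer(1))
  data.frame(gene = group, pathway_hits = unname(hits),
             index_two = unname(100 * hits / total),
             stringsAsFactors = FALSE)
}

#' Integrated ranking of DNB members
#'
#' integrated_index = w1 * index_one + w2 * (index_two / 100); at the
#' default equal weights (0.5, 0.5) it lies in [0, 1]. Members are sorted by
#' descending integrated index; exact ties are broken lexicographically by
#' gene id and flagged in the `tie` column.
#'
#' @param members Non-empty gene set (the DNB group).
#' @param network A `gene_network`.
#' @param pathways A `pathway_collection`.
#' @param weights Non-negative length-2 vector (w1, w2), default
#'   c(0.5, 0.5).
#' @param whole_network Passed to [network_degree_index()].
#' @return data.frame with columns gene, degree, index_one, pathway_hits,
#'   index_two, integrated_index, rank, tie; ordered by rank.
#' @export
integrated_rank <- function(members, network, pathways,
                            weights = c(0.5, 0.5), whole_network = FALSE) {
  if (!length(members)) stop("members must be non-empty")
  if (length(weights) != 2L || any(weights < 0)) {
    stop("weights must be two non-negative numbers")
  }
  ni <- network_degree_index(members, network, whole_network)
  pi_ <- pathway_hit_index(members, pathways)
  stopifnot(identical(ni$gene, pi_$gene))
  out <- data.frame(gene = ni$gene, degree = ni$degree,
                    index_one = ni$index_one,
                    pathway_hits = pi_$pathway_hits,
                    index_two = pi_$index_two,
                    stringsAsFactors = FALSE)
  out$integrated_index <- weights[1L] * out$index_one +
    weights[2L] * out$index_two / 100
  ord <- order(-out$integrated_index, out$gene)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  dup <- duplicated(out$integrated_index) |
    duplicated(out$integrated_index, fromLast = TRUE)
  out$tie <- dup
  rownames(out) <- NULL
  out
}
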