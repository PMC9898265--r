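# Readers and writers for the external formats the pipeline touches:
# delimited expression matrices + sample metadata, GMT gene sets,
# SIF / two-column edge lists, and the result tables.

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is delimited text: first column gene identifiers, header
#' row sample identifiers. The metadata file has columns `sample`,
#' `timepoint`, `replicate`. Timepoint temporal order is the order of first
#' appearance in the metadata (or `timepoint_levels` when given). Gene
#' identifiers are matched exactly and case-sensitively everywhere in the
#' package.
#'
#' @param matrix_path Path to the expression matrix.
#' @param metadata_path Path to the sample metadata table.
#' @param scale Declared value scale, `"log"` or `"raw"`.
#' @param sep Field delimiter; default auto-detects from the extension
#'   (`.csv` is comma, anything else tab).
#' @param missing Policy for missing values: `"error"` (default) or
#'   `"drop"`, which removes genes with any missing value and reports the
#'   count via a message. Values are never imputed: the DNB statistics are
#'   correlation-based and imputation would bias them.
#' @param timepoint_levels Optional explicit timepoint order.
#' @return An [expression_series()].
#' @export
read_expression_table <- function(matrix_path, metadata_path,
                                  scale = c("log", "raw"), sep = NULL,
                                  missing = c("error", "drop"),
                                  timepoint_levels = NULL) {
  scale <- match.arg(scale)
  missing <- match.arg(missing)
  msep <- detect_sep(matrix_path, sep)
  raw <- utils::read.table(matrix_path, sep = msep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  gene_ids <- as.character(raw[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) &
                     !col %in% c("NA", "NaN", "nan", ""))
      if (length(bad)) {
        stop(sprintf("non-numeric value %s at row %d (gene %s), column %s",
                     dQuote(col[bad[1L]]), bad[1L], gene_ids[bad[1L]],
                     colnames(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- gene_ids

  if (anyNA(mat)) {
    if (missing == "error") {
      idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at gene %s, sample %s (policy: error)",
                   gene_ids[idx[1L]], colnames(mat)[idx[2L]]))
    }
    keep <- rowSums(is.na(mat)) == 0L
    message(sprintf("dropped %d gene(s) with missing values", sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }

  meta <- utils::read.table(metadata_path, sep = detect_sep(metadata_path, sep),
                            header = TRUE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  need <- c("sample", "timepoint", "replicate")
  if (!all(need %in% colnames(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  absent <- setdiff(colnames(mat), meta$sample)
  if (length(absent)) {
    stop("samples in matrix but absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  meta <- meta[match(colnames(mat), meta$sample), ]
  expression_series(mat,
                    timepoint = meta$timepoint,
                    replicate = meta$replicate,
                    timepoint_levels = timepoint_levels,
                    scale = scale)
}

#' Write an expression series to matrix + metadata files
#'
#' Inverse of [read_expression_table()]; values round-trip at full precision
#' (written with 17 significant digits).
#'
#' @param series An `expression_series`.
#' @param matrix_path,metadata_path Output paths (delimiter auto-detected
#'   from extension).
#' @return Invisibly, the two paths.
#' @export
write_expression_table <- function(series, matrix_path, metadata_path) {
  sep <- detect_sep(matrix_path)
  df <- data.frame(gene = series$genes,
                   format(series$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = series$samples,
                     timepoint = as.character(series$timepoint),
                     replicate = series$replicate)
  utils::write.table(meta, metadata_path, sep = detect_sep(metadata_path),
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Read a GMT pathway collection
#'
#' MSigDB dialect: one gene set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @param total_reference_count Number of reference pathways used when
#'   normalizing pathway hits to a percentage. Defaults to the number of
#'   lines in the file; set to 185 to mirror the MSigDB KEGG collection the
#'   ranking scheme was designed around.
#' @return A `pathway_collection`: list with `pathways` (named list of
#'   character vectors) and `total_reference_count`.
#' @export
read_gmt <- function(path, total_reference_count = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 non-empty fields", i))
    }
    nms[i] <- f[1L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicate pathway names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  if (is.null(total_reference_count)) total_reference_count <- length(sets)
  if (total_reference_count < length(sets)) {
    stop("total_reference_count smaller than the number of loaded pathways")
  }
  structure(list(pathways = sets,
                 total_reference_count = as.integer(total_reference_count)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d sets, reference count %d\n",
              length(x$pathways), x$total_reference_count))
  invisible(x)
}

#' Read an undirected gene network from an edge list
#'
#' Accepts two-column TSV (`a<TAB>b`) or three-column SIF
#' (`a<TAB>type<TAB>b`). Duplicate edges (in either orientation) are merged
#' and self-loops dropped; a message reports how many of each.
#'
#' @param path Path to the edge list.
#' @param sep Field delimiter (default any whitespace/tab).
#' @return A `gene_network`: an igraph-backed undirected simple graph.
#' @export
read_network_edges <- function(path, sep = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(gene_network(matrix(character(0), ncol = 2)))
  }
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  bad <- which(!nf %in% c(2L, 3L))
  if (length(bad)) {
    stop(sprintf("malformed edge line %d: expected 2 (TSV) or 3 (SIF) fields, got %d",
                 bad[1L], nf[bad[1L]]))
  }
  edges <- t(vapply(parts, function(f) {
    if (length(f) == 3L) c(f[1L], f[3L]) else f
  }, character(2)))
  gene_network(edges)
}

#' Construct a gene network from an edge matrix
#'
#' @param edges Two-column character matrix of endpoints.
#' @return A `gene_network` (undirected, simple).
#' @export
gene_network <- function(edges) {
  edges <- matrix(as.character(edges), ncol = 2)
  nodes <- unique(as.vector(edges))
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # endpoints of dropped loops stay as isolated nodes
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  ndup <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) < ndup) {
    message(sprintf("merged %d duplicate edge(s)", ndup - igraph::ecount(g)))
  }
  structure(list(graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Write DNB result tables
#'
#' Writes `criticality_profile.tsv` (columns timepoint, size, SD_in,
#' PCC_in, PCC_out, CI), `dnb_members.tsv` (gene, index_one, index_two,
#' integrated_index, rank; rank ascending) and `run_config.yaml` echoing the
#' parameters recorded on the result. Output is deterministic: identical
#' results yield byte-identical files.
#'
#' @param result A `dnb_result` (see [find_dominant_group()]), optionally
#'   carrying a `ranking` element from [integrated_rank()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_results <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  prof_path <- file.path(out_dir, "criticality_profile.tsv")
  mem_path <- file.path(out_dir, "dnb_members.tsv")
  cfg_path <- file.path(out_dir, "run_config.yaml")

  prof <- result$profile
  if (is.null(prof)) {
    prof <- data.frame(timepoint = character(0), size = integer(0),
                       SD_in = numeric(0), PCC_in = numeric(0),
                       PCC_out = numeric(0), CI = numeric(0))
  }
  prof <- prof[, c("timepoint", "size", "SD_in", "PCC_in", "PCC_out", "CI")]
  num <- vapply(prof, is.numeric, logical(1))
  prof[num] <- lapply(prof[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(prof, prof_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  memcols <- c("gene", "index_one", "index_two", "integrated_index", "rank")
  if (!is.null(result$ranking)) {
    mem <- result$ranking[order(result$ranking$rank), memcols]
  } else if (length(result$group)) {
    mem <- data.frame(gene = sort(result$group), index_one = NA_real_,
                      index_two = NA_real_, integrated_index = NA_real_,
                      rank = NA_integer_)
  } else {
    mem <- data.frame(gene = character(0), index_one = numeric(0),
                      index_two = numeric(0), integrated_index = numeric(0),
                      rank = integer(0))
  }
  num <- vapply(mem, is.numeric, logical(1))
  mem[num] <- lapply(mem[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(mem, mem_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  params <- result$params
  if (is.null(params)) params <- list()
  params$critical_timepoint <- result$critical_timepoint
  writeLines(yaml::as.yaml(params), cfg_path)
  invisible(c(profile = prof_path, members = mem_path, config = cfg_path))
}
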