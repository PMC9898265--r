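# In-code fixtures: tiny expression series, files written to tempdir().

# genes x samples series with 2 timepoints x 3 replicates by default
toy_series <- function(values = NULL, n_genes = 4, tp = c("T1", "T2"),
                       n_rep = 3, seed = 42) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(n_genes * length(tp) * n_rep),
                     nrow = n_genes,
                     dimnames = list(paste0("g", seq_len(n_genes)),
                                     paste0("s", seq_len(length(tp) * n_rep))))
  }
  expression_series(values,
                    timepoint = rep(tp, each = n_rep),
                    replicate = rep(seq_len(n_rep), times = length(tp)),
                    timepoint_levels = tp)
}

write_toy_expression_files <- function(series,
                                       dir = withr::local_tempdir(
                                         .local_envir = parent.frame())) {
  m <- file.path(dir, "expr.tsv")
  md <- file.path(dir, "meta.tsv")
  write_expression_table(series, m, md)
  list(matrix = m, metadata = md, dir = dir)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

triangle_net <- function() gene_network(cbind(c("a", "b", "c"),
                                              c("b", "c", "a")))
star_net <- function() gene_network(cbind(rep("hub", 3),
                                          c("l1", "l2", "l3")))

toy_gmt_lines <- c(
  "pwA\tdescA\tg1\tg2\tg3",
  "pwB\tdescB\tg2\tg4",
  "pwC\tdescC\tg5\tg1")
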