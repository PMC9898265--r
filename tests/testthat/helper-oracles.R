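# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and stats::cor / stats::p.adjust) so that agreement is a real
# cross-check, not a tautology.

# Pearson correlation of two vectors from the raw sum formula
naive_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(0)
  sxy / sqrt(sxx * syy)
}

naive_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))

# full correlation matrix by double loop
naive_cor_matrix <- function(mat) {
  g <- nrow(mat)
  out <- diag(1, g)
  dimnames(out) <- list(rownames(mat), rownames(mat))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i != j) out[i, j] <- naive_pcc(mat[i, ], mat[j, ])
    }
  }
  out
}

# (SD_in, PCC_in, PCC_out) by explicit loops over pairs
naive_group_stats <- function(series, group, background, t) {
  xg <- timepoint_matrix(series, t, group)
  xb <- timepoint_matrix(series, t, background)
  sd_in <- mean(vapply(seq_len(nrow(xg)), function(i) naive_sd(xg[i, ]),
                       numeric(1)))
  acc <- c()
  for (i in seq_len(nrow(xg) - 1L)) {
    for (j in seq((i + 1L), nrow(xg))) {
      acc <- c(acc, abs(naive_pcc(xg[i, ], xg[j, ])))
    }
  }
  pcc_in <- mean(acc)
  acc <- c()
  for (i in seq_len(nrow(xg))) {
    for (j in seq_len(nrow(xb))) {
      acc <- c(acc, abs(naive_pcc(xg[i, ], xb[j, ])))
    }
  }
  c(SD_in = sd_in, PCC_in = pcc_in, PCC_out = mean(acc))
}

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j >= i}
# min(1, p_(j) * m / j), mapped back to the input order
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, ps * m / seq_len(m))
  for (i in rev(seq_len(m - 1L))) q[i] <- min(q[i], q[i + 1L])
  out <- numeric(m)
  out[o] <- q
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
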