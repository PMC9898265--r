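test_that("screen output contracts hold on a toy series", {
  s <- toy_series(n_genes = 6, tp = c("T1", "T2", "T3"), n_rep = 4)
  res <- one_vs_rest_screen(s)
  expect_s3_class(res, "de_result")
  expect_identical(nrow(res$table), 6L * 3L)
  expect_true(all(res$table$q >= res$table$p - 1e-15))
  expect_true(all(res$candidates %in% s$genes))

  # a constant gene: zero variance in both classes, equal means
  vals <- s$values
  vals["g1", ] <- 5
  s2 <- toy_series(values = vals, tp = c("T1", "T2", "T3"), n_rep = 4)
  res2 <- one_vs_rest_screen(s2)
  g1 <- res2$table[res2$table$gene == "g1", ]
  expect_true(all(g1$t == 0))
  expect_true(all(g1$p == 1))
  expect_false("g1" %in% res2$candidates)
})

test_that("welch statistics match stats::t.test gene by gene", {
  s <- toy_series(n_genes = 8, tp = c("T1", "T2"), n_rep = 5, seed = 99)
  res <- one_vs_rest_screen(s)
  for (g in c("g1", "g4", "g8")) {
    a <- s$values[g, s$timepoint == "T1"]
    b <- s$values[g, s$timepoint != "T1"]
    tt <- t.test(a, b)  # Welch by default
    row <- res$table[res$table$gene == g &
                       res$table$comparison == "T1_vs_rest", ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up oracle, per scope", {
  set.seed(1)
  s <- toy_series(n_genes = 30, tp = c("T1", "T2", "T3"), n_rep = 4, seed = 3)
  for (scope in c("per_comparison", "global")) {
    res <- one_vs_rest_screen(s, bh_scope = scope)
    tab <- res$table
    if (scope == "per_comparison") {
      for (cmp in unique(tab$comparison)) {
        sel <- tab$comparison == cmp
        expect_equal(tab$q[sel], naive_bh(tab$p[sel]), tolerance = 1e-12)
      }
    } else {
      expect_equal(tab$q, naive_bh(tab$p), tolerance = 1e-12)
    }
  }
  # and on a fixed printed toy list
  p <- c(0.01, 0.04, 0.03, 0.005, 0.2, 0.9)
  expect_equal(p.adjust(p, "BH"), naive_bh(p), tolerance = 1e-15)
})

test_that("screen is invariant to gene and sample order", {
  s <- toy_series(n_genes = 10, tp = c("T1", "T2"), n_rep = 5, seed = 12)
  res <- one_vs_rest_screen(s)
  perm_g <- sample(s$genes)
  perm_s <- sample(s$samples)
  s2 <- expression_series(s$values[perm_g, perm_s],
                          timepoint = as.character(s$timepoint[perm_s]),
                          replicate = s$replicate[perm_s],
                          timepoint_levels = timepoints(s))
  res2 <- one_vs_rest_screen(s2)
  key <- function(r) r$table[order(r$table$gene, r$table$comparison),
                             c("diff", "t", "p", "q")]
  expect_equal(unname(as.matrix(key(res))), unname(as.matrix(key(res2))),
               tolerance = 1e-12)
  expect_identical(res$candidates, res2$candidates)
})

test_that("planted shifts are recovered and label permutation destroys them", {
  sim <- simulate_series(simulation_config(n_genes = 300, k = 2, n_rep = 10,
                                           sd_boost = 1, rho_in = 0,
                                           rho_out = 0, de_fraction = 0.1,
                                           seed = 77))
  res <- one_vs_rest_screen(sim$series)
  expect_gte(mean(sim$truth$de_genes %in% res$candidates), 0.9)

  # permute sample labels: planted candidates collapse to null levels
  set.seed(7)
  counts <- vapply(1:5, function(i) {
    perm <- sample(length(sim$series$samples))
    sp <- expression_series(sim$series$values,
                            timepoint = as.character(sim$series$timepoint)[perm],
                            replicate = sim$series$replicate[perm],
                            timepoint_levels = timepoints(sim$series))
    length(one_vs_rest_screen(sp)$candidates)
  }, numeric(1))
  expect_lt(mean(counts), length(sim$truth$de_genes) / 2)
})

test_that("screen preconditions", {
  s <- toy_series(n_genes = 4, tp = c("T1", "T2"), n_rep = 3)
  s$timepoint[1:5] <- factor("T1", levels = c("T1", "T2"), ordered = TRUE)
  expect_error(one_vs_rest_screen(s), "T2")
})

test_that("2^-ddCt fold change", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(19, 15, 20, 15), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(22, 15, 20, 15), 0.25)  # ddCt = +2
  expect_equal(ddct_fold_change(c(20, 19), 15, 20, 15), c(1, 2))
  expect_error(ddct_fold_change(NA, 15, 20, 15), "finite")
  expect_error(ddct_fold_change(Inf, 15, 20, 15), "finite")
})
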