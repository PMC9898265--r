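test_that("timepoint correlation: exact cases and contracts", {
  vals <- rbind(gA = c(1, 2, 3, 9, 9, 9),
                gB = c(2, 4, 6, 9, 9, 9),
                gC = c(3, 2, 1, 9, 9, 9),
                gD = c(5, 5, 5, 9, 9, 9))
  colnames(vals) <- paste0("s", 1:6)
  s <- toy_series(values = vals)
  cm <- suppressWarnings(timepoint_correlation(s, "T1", c("gA", "gB", "gC")))
  expect_equal(cm["gA", "gB"], 1)
  expect_equal(cm["gA", "gC"], -1)
  expect_equal(diag(cm), c(gA = 1, gB = 1, gC = 1))
  expect_equal(cm, t(cm))

  # zero-variance gene: correlations 0, warning, flag
  expect_warning(cmz <- timepoint_correlation(s, "T1", c("gA", "gD")),
                 "zero-variance")
  expect_equal(cmz["gA", "gD"], 0)
  expect_identical(attr(cmz, "zero_variance"), "gD")

  expect_error(timepoint_correlation(s, "T1", "gA"), "2 genes")
  s2 <- toy_series(n_genes = 3, n_rep = 2)
  expect_error(timepoint_correlation(s2, "T1", c("g1", "g2")), ">= 3")
})

test_that("correlation and group stats match brute force to 1e-12", {
  set.seed(31)
  s <- toy_series(n_genes = 6, tp = "T1", n_rep = 5)
  cm <- timepoint_correlation(s, "T1", s$genes)
  expect_identical(dimnames(cm), dimnames(naive_cor_matrix(s$values)))
  expect_equal(cm, naive_cor_matrix(s$values), tolerance = 1e-12,
               ignore_attr = TRUE)

  s25 <- toy_series(n_genes = 25, tp = c("T1", "T2"), n_rep = 6, seed = 8)
  grp <- paste0("g", 1:5)
  bg <- paste0("g", 6:25)
  st <- group_stats(s25, grp, bg, "T2")
  expect_equal(st, naive_group_stats(s25, grp, bg, "T2"), tolerance = 1e-12)
})

test_that("group stats degenerate and contract cases", {
  vals <- rbind(gA = c(1, 2, 3), gB = c(1, 2, 3), gC = c(0, 1, 0))
  colnames(vals) <- paste0("s", 1:3)
  s <- toy_series(values = vals, tp = "T1", n_rep = 3)
  st <- group_stats(s, c("gA", "gB"), "gC", "T1")
  expect_equal(unname(st["PCC_in"]), 1)  # duplicated rows

  vals2 <- matrix(4, 3, 3, dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:3)))
  s2 <- toy_series(values = vals2, tp = "T1", n_rep = 3)
  st2 <- group_stats(s2, c("gA", "gB"), "gC", "T1")
  expect_equal(unname(st2["SD_in"]), 0)
  ci <- criticality_index(st2["SD_in"], st2["PCC_in"], st2["PCC_out"], 2)
  expect_equal(as.numeric(ci), 0)

  expect_error(group_stats(s, c("gA", "gB"), c("gB", "gC"), "T1"), "overlap")
})

test_that("criticality index formula, floor and domain", {
  ci <- criticality_index(2, 0.8, 0.1, 16)
  expect_equal(as.numeric(ci), 64)
  expect_false(attr(ci, "floored"))

  expect_equal(as.numeric(criticality_index(0, 0.9, 0.2, 10)), 0)

  cif <- criticality_index(2, 0.8, 0, 16, pcc_out_floor = 1e-6)
  expect_true(attr(cif, "floored"))
  expect_equal(as.numeric(cif), 1e6 * sqrt(16) * 0.8 * 2)

  expect_error(criticality_index(1, 0.5, 0.5, 1), "size")
  expect_error(criticality_index(1, 1.5, 0.5, 4), "domain")
})

test_that("scale equivariance and permutation invariance", {
  s <- toy_series(n_genes = 12, tp = c("T1", "T2"), n_rep = 5, seed = 4)
  grp <- paste0("g", 1:4)
  bg <- paste0("g", 5:12)
  st <- group_stats(s, grp, bg, "T1")
  c_ <- 3.7
  s_sc <- toy_series(values = s$values * c_, tp = c("T1", "T2"), n_rep = 5)
  st_sc <- group_stats(s_sc, grp, bg, "T1")
  expect_equal(st_sc["PCC_in"], st["PCC_in"], tolerance = 1e-12)
  expect_equal(st_sc["PCC_out"], st["PCC_out"], tolerance = 1e-12)
  expect_equal(st_sc["SD_in"], c_ * st["SD_in"], tolerance = 1e-12)
  ci <- criticality_index(st["SD_in"], st["PCC_in"], st["PCC_out"], 4)
  ci_sc <- criticality_index(st_sc["SD_in"], st_sc["PCC_in"], st_sc["PCC_out"], 4)
  expect_equal(as.numeric(ci_sc), c_ * as.numeric(ci), tolerance = 1e-12)

  # gene and sample permutations change nothing
  set.seed(2)
  pg <- sample(s$genes); ps <- sample(s$samples)
  s_p <- expression_series(s$values[pg, ps],
                           timepoint = as.character(s$timepoint[ps]),
                           replicate = s$replicate[ps],
                           timepoint_levels = timepoints(s))
  expect_equal(group_stats(s_p, grp, bg, "T1"), st, tolerance = 1e-12)
})

test_that("CI is monotone in its arguments", {
  base <- as.numeric(criticality_index(1, 0.5, 0.3, 9))
  expect_gt(as.numeric(criticality_index(1.2, 0.5, 0.3, 9)), base)
  expect_gt(as.numeric(criticality_index(1, 0.6, 0.3, 9)), base)
  expect_lt(as.numeric(criticality_index(1, 0.5, 0.4, 9)), base)
})

test_that("detect_transition: argmax, ties, degenerate profile", {
  prof <- data.frame(timepoint = paste0("D", 3:7), CI = c(1, 2, 9, 3, 2))
  tr <- detect_transition(prof)
  expect_true(tr$found)
  expect_identical(tr$timepoint, "D5")
  expect_false(tr$tie)

  flat <- data.frame(timepoint = paste0("D", 3:7), CI = rep(2, 5))
  trf <- suppressMessages(detect_transition(flat))
  expect_identical(trf$timepoint, "D3")
  expect_true(trf$tie)

  zero <- data.frame(timepoint = paste0("D", 3:7), CI = rep(0, 5))
  trz <- detect_transition(zero)
  expect_false(trz$found)
  expect_true(is.na(trz$timepoint))

  expect_error(detect_transition(zero[1, , drop = FALSE]), ">= 2")
})

test_that("expected_ci profile hands detect_transition the planted t_star", {
  cfg <- simulation_config()
  prof <- data.frame(timepoint = cfg$timepoint_labels,
                     CI = vapply(1:5, function(t) expected_ci(cfg, t),
                                 numeric(1)))
  expect_identical(detect_transition(prof)$timepoint, "D6")
})

test_that("find_dominant_group recovers a strongly planted group", {
  sim <- simulate_series(simulation_config(n_rep = 10, seed = 1))
  res <- suppressWarnings(find_dominant_group(sim$series))
  expect_true(res$found)
  expect_identical(res$critical_timepoint, sim$truth$t_star)
  expect_gte(jaccard(res$group, sim$truth$dnb_genes), 0.6)
  expect_s3_class(res$profile, "criticality_profile")
  expect_identical(nrow(res$profile), 5L)
  expect_true(all(c("timepoint", "cluster", "size", "CI") %in%
                    colnames(res$diagnostics)))

  # the winner's search-path statistics agree with an independent
  # group_stats call (fast path vs the exported operation)
  st <- group_stats(sim$series, res$group,
                    setdiff(sim$series$genes, res$group),
                    res$critical_timepoint)
  ci <- criticality_index(st["SD_in"], st["PCC_in"], st["PCC_out"],
                          length(res$group))
  win <- res$diagnostics[which.max(res$diagnostics$score), ]
  expect_equal(win$CI, as.numeric(ci), tolerance = 1e-12)
  expect_equal(win[, c("SD_in", "PCC_in", "PCC_out")],
               as.data.frame(as.list(st)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$profile$CI[res$profile$timepoint == res$critical_timepoint],
               as.numeric(ci), tolerance = 1e-12)
})

test_that("find_dominant_group is invariant to gene and sample order", {
  sim <- simulate_series(simulation_config(n_genes = 60, k = 10, n_rep = 8,
                                           seed = 6))
  s <- sim$series
  res <- suppressWarnings(find_dominant_group(s))
  set.seed(3)
  pg <- sample(s$genes); ps <- sample(s$samples)
  s_p <- expression_series(s$values[pg, ps],
                           timepoint = as.character(s$timepoint[ps]),
                           replicate = s$replicate[ps],
                           timepoint_levels = timepoints(s))
  res_p <- suppressWarnings(find_dominant_group(s_p))
  expect_setequal(res$group, res_p$group)
  expect_identical(res$critical_timepoint, res_p$critical_timepoint)
})

test_that("no admissible cluster yields a structured empty result", {
  sim <- simulate_series(simulation_config(n_genes = 30, k = 5, n_rep = 10,
                                           sd_boost = 1, rho_in = 0,
                                           rho_out = 0, de_fraction = 0,
                                           seed = 2))
  res <- find_dominant_group(sim$series, min_group_size = 5,
                             cut_height = 0.01)
  expect_false(res$found)
  expect_length(res$group, 0)
  expect_true(is.na(res$critical_timepoint))
  expect_identical(nrow(res$diagnostics), 0L)
})

test_that("background = 'candidates' restricts the scoring universe", {
  sim <- simulate_series(simulation_config(n_genes = 80, k = 10, n_rep = 8,
                                           seed = 13))
  cand <- c(sim$truth$dnb_genes, paste0("g00", 60:79))
  cand <- intersect(cand, sim$series$genes)
  res_all <- suppressWarnings(
    find_dominant_group(sim$series, cand, background = "all"))
  res_cand <- suppressWarnings(
    find_dominant_group(sim$series, cand, background = "candidates"))
  expect_true(res_all$found && res_cand$found)
  # same planted group found either way, scored against different universes
  expect_setequal(res_all$group, res_cand$group)
  ci_all <- res_all$profile$CI[res_all$profile$timepoint ==
                                 res_all$critical_timepoint]
  ci_cand <- res_cand$profile$CI[res_cand$profile$timepoint ==
                                   res_cand$critical_timepoint]
  expect_false(isTRUE(all.equal(ci_all, ci_cand)))
})
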