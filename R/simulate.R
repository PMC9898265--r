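# One-factor Gaussian simulator with a planted DNB group and a planted
# critical timepoint. A single latent factor z per (timepoint, replicate)
# induces both the within-group correlation (loading sqrt(rho_in)) and the
# group-to-background correlation (background loading sqrt(rho_out)), so the
# large-replicate limits of PCC_in / PCC_out are known in closed form and
# expected_ci() is an exact oracle for the empirical criticality index.

#' Simulation configuration
#'
#' Defaults state the strong-effect world the recovery guarantees are tested
#' under: five timepoints (labels D3-D7 mirroring a days-post-fertilization
#' design), planted transition at the fourth (D6), within-group correlation
#' jumping 0.1 -> 0.8 and group-background coupling dropping 0.3 -> 0.05 at
#' the transition, and a 3x standard-deviation boost of the planted genes
#' there. `n_rep` defaults to 3, the replicated design the statistics were
#' built for; tests needing tight tolerances raise it explicitly.
#'
#' @param n_genes Total number of genes.
#' @param k Planted DNB group size (2 <= k < n_genes).
#' @param n_timepoints Number of timepoints T.
#' @param n_rep Replicates per timepoint (>= 3).
#' @param t_star Index (1..T) of the planted transition.
#' @param baseline_sd Baseline per-gene standard deviation sigma0 (> 0).
#' @param sd_boost Multiplier beta (>= 1) applied to the DNB genes'
#'   standard deviation at `t_star`.
#' @param rho_in Within-DNB-group target correlation, scalar or length-T
#'   schedule; peaks at `t_star` in the default world.
#' @param rho_out Group-to-background coupling schedule (scalar or
#'   length T). Background genes load on the shared factor with
#'   sqrt(rho_out), so the realized DNB-background correlation is
#'   sqrt(rho_in * rho_out) and background-background pairs correlate at
#'   rho_out.
#' @param coupled_fraction Fraction of background genes carrying the
#'   `rho_out` factor loading; the rest are pure noise. Default 1 keeps the
#'   closed-form PCC_out limit exact.
#' @param de_fraction Fraction of background genes given a mean shift
#'   `de_shift` for t >= t_star, so the differential screen has signal.
#' @param de_shift Mean shift delta applied to the DE genes (in units of
#'   expression; default 3 * baseline_sd).
#' @param dnb_de If TRUE (default) the planted DNB genes also receive the
#'   `de_shift` for t >= t_star, so a differential candidate screen retains
#'   them — mirroring a design where DNB members are sought within the DEG
#'   union. A per-timepoint constant shift leaves every within-timepoint
#'   statistic (SD, correlations, CI) untouched. Set FALSE for strictly
#'   null simulations.
#' @param timepoint_labels Optional labels (default D3, D4, ...).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200, k = 20, n_timepoints = 5,
                              n_rep = 3, t_star = 4, baseline_sd = 1,
                              sd_boost = 3,
                              rho_in = NULL, rho_out = NULL,
                              coupled_fraction = 1,
                              de_fraction = 0.1,
                              de_shift = 3 * baseline_sd,
                              dnb_de = TRUE,
                              timepoint_labels = NULL,
                              seed = 1L) {
  T <- as.integer(n_timepoints)
  if (is.null(rho_in)) rho_in <- ifelse(seq_len(T) == t_star, 0.8, 0.1)
  if (is.null(rho_out)) rho_out <- ifelse(seq_len(T) == t_star, 0.05, 0.3)
  if (length(rho_in) == 1L) rho_in <- rep(rho_in, T)
  if (length(rho_out) == 1L) rho_out <- rep(rho_out, T)
  if (is.null(timepoint_labels)) {
    timepoint_labels <- paste0("D", seq(3, length.out = T))
  }
  cfg <- list(n_genes = as.integer(n_genes), k = as.integer(k),
              n_timepoints = T, n_rep = as.integer(n_rep),
              t_star = as.integer(t_star),
              baseline_sd = baseline_sd, sd_boost = sd_boost,
              rho_in = rho_in, rho_out = rho_out,
              coupled_fraction = coupled_fraction,
              de_fraction = de_fraction, de_shift = de_shift,
              dnb_de = isTRUE(dnb_de),
              timepoint_labels = timepoint_labels,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (k < 2L || k >= n_genes) stop("need 2 <= k < n_genes")
    if (n_rep < 3L) stop("n_rep must be >= 3 (correlation across 2 points is degenerate)")
    if (t_star < 1L || t_star > n_timepoints) stop("t_star outside 1..T")
    if (length(rho_in) != n_timepoints || length(rho_out) != n_timepoints) {
      stop("rho_in / rho_out must be scalar or length T")
    }
    if (any(rho_in < 0 | rho_in >= 1) || any(rho_out < 0 | rho_out >= 1)) {
      stop("rho schedules must lie in [0, 1)")
    }
    if (baseline_sd <= 0) stop("baseline_sd must be positive")
    if (sd_boost < 1) stop("sd_boost must be >= 1")
    if (coupled_fraction < 0 || coupled_fraction > 1) {
      stop("coupled_fraction must be in [0, 1]")
    }
    if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
    if (length(timepoint_labels) != n_timepoints) {
      stop("timepoint_labels must have length T")
    }
  })
  invisible(cfg)
}

#' Simulate an expression series with a planted DNB group
#'
#' Gene values at timepoint t, replicate r:
#' \itemize{
#'   \item DNB gene i: mu_i + s_i(t) * (sqrt(rho_in(t)) * z_tr +
#'     sqrt(1 - rho_in(t)) * eps), with s_i(t) = sigma0 * beta at t = t_star
#'     and sigma0 otherwise;
#'   \item coupled background gene j: mu_j + sigma0 * (sqrt(rho_out(t)) *
#'     z_tr + sqrt(1 - rho_out(t)) * eps);
#'   \item uncoupled background: mu_j + sigma0 * eps;
#' }
#' with z and eps independent standard normals and one shared z per
#' (timepoint, replicate). DE genes additionally get `de_shift` added for
#' t >= t_star. Baseline means mu are drawn once from N(8, 2^2), a typical
#' log2-expression location. Generation is fully reproducible from
#' `config$seed` (one stream, fixed draw order).
#'
#' @param config A [simulation_config()].
#' @return List with `series` (an [expression_series()]) and `truth`
#'   (list: `dnb_genes`, `t_star` label and index, `de_genes`,
#'   `coupled_genes`, and the config).
#' @export
simulate_series <- function(config) {
  cfg <- validate_simulation_config(config)
  set.seed(cfg$seed)
  G <- cfg$n_genes; Tn <- cfg$n_timepoints; R <- cfg$n_rep
  genes <- sprintf("g%04d", seq_len(G))
  dnb <- genes[seq_len(cfg$k)]
  bg <- genes[-seq_len(cfg$k)]

  mu <- stats::rnorm(G, mean = 8, sd = 2)
  names(mu) <- genes

  n_coupled <- round(cfg$coupled_fraction * length(bg))
  coupled <- if (n_coupled > 0) sample(bg, n_coupled) else character(0)
  n_de <- round(cfg$de_fraction * length(bg))
  de_genes <- if (n_de > 0) sample(bg, n_de) else character(0)
  if (isTRUE(cfg$dnb_de)) de_genes <- union(dnb, de_genes)

  vals <- matrix(NA_real_, G, Tn * R,
                 dimnames = list(genes, NULL))
  tp_of <- character(Tn * R); rep_of <- integer(Tn * R)
  smp <- character(Tn * R)
  is_coupled <- genes %in% coupled
  is_dnb <- genes %in% dnb
  for (t in seq_len(Tn)) {
    s_t <- cfg$baseline_sd * if (t == cfg$t_star) cfg$sd_boost else 1
    a_in <- sqrt(cfg$rho_in[t]); b_in <- sqrt(1 - cfg$rho_in[t])
    a_out <- sqrt(cfg$rho_out[t]); b_out <- sqrt(1 - cfg$rho_out[t])
    z <- stats::rnorm(R)
    eps <- matrix(stats::rnorm(G * R), G, R)
    block <- matrix(NA_real_, G, R, dimnames = list(genes, NULL))
    block[is_dnb, ] <- mu[is_dnb] +
      s_t * (a_in * rep(z, each = sum(is_dnb)) + b_in * eps[is_dnb, , drop = FALSE])
    cb <- is_coupled
    block[cb, ] <- mu[cb] + cfg$baseline_sd *
      (a_out * rep(z, each = sum(cb)) + b_out * eps[cb, , drop = FALSE])
    un <- !is_dnb & !is_coupled
    block[un, ] <- mu[un] + cfg$baseline_sd * eps[un, , drop = FALSE]
    if (t >= cfg$t_star && length(de_genes)) {
      block[de_genes, ] <- block[de_genes, ] + cfg$de_shift
    }
    idx <- (t - 1L) * R + seq_len(R)
    vals[, idx] <- block
    tp_of[idx] <- cfg$timepoint_labels[t]
    rep_of[idx] <- seq_len(R)
    smp[idx] <- sprintf("%s_r%d", cfg$timepoint_labels[t], seq_len(R))
  }
  colnames(vals) <- smp
  series <- expression_series(vals, timepoint = tp_of, replicate = rep_of,
                              timepoint_levels = cfg$timepoint_labels,
                              scale = "log")
  truth <- list(dnb_genes = dnb,
                t_star = cfg$timepoint_labels[cfg$t_star],
                t_star_index = cfg$t_star,
                de_genes = de_genes,
                coupled_genes = coupled,
                config = cfg)
  list(series = series, truth = truth)
}

#' Closed-form large-replicate limit of the planted group's CI
#'
#' Substitutes the generative parameters into the criticality index:
#' sqrt(k) * rho_in(t) / max(pcc_out_limit(t), floor) * s(t), where s(t) is
#' the planted standard deviation schedule and pcc_out_limit(t) is the
#' realized group-to-background correlation
#' coupled_fraction * sqrt(rho_in(t) * rho_out(t)) implied by the one-factor
#' construction. Used as the independent oracle for the empirical CI as
#' `n_rep` grows.
#'
#' @param config A [simulation_config()].
#' @param t Timepoint index (1..T) or label.
#' @param pcc_out_floor Floor applied to the denominator, as in
#'   [criticality_index()].
#' @return The limiting CI value (numeric scalar).
#' @export
expected_ci <- function(config, t, pcc_out_floor = 1e-6) {
  cfg <- validate_simulation_config(config)
  if (is.character(t)) t <- match(t, cfg$timepoint_labels)
  if (is.na(t) || t < 1 || t > cfg$n_timepoints) stop("unknown timepoint")
  s_t <- cfg$baseline_sd * if (t == cfg$t_star) cfg$sd_boost else 1
  pcc_out_lim <- cfg$coupled_fraction * sqrt(cfg$rho_in[t] * cfg$rho_out[t])
  sqrt(cfg$k) * cfg$rho_in[t] / max(pcc_out_lim, pcc_out_floor) * s_t
}
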