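#' Quantile-based BIC from category probabilities
#'
#' `BIC = -2 * sum_i N * p_i * ln(pi_i) + M * ln(N)`, where `p_i` are
#' empirical category probabilities, `pi_i` simulated category
#' probabilities (floored at `floor` before the log to keep empty
#' simulated cells finite), `N` the observed trial count and `M` the free
#' parameter count.
#'
#' @param p empirical probabilities (summing to 1).
#' @param pi_sim simulated probabilities (summing to 1).
#' @param N observed sample size.
#' @param M number of free parameters.
#' @param floor lower floor applied to `pi_sim` before the log.
#' @return BIC value, with attribute `n_floored` (simulated cells at or
#'   below the floor that carried empirical mass).
#' @export
quantile_bic_from_probs <- function(p, pi_sim, N, M, floor = 0) {
  stopifnot(length(p) == length(pi_sim), N > 0, M >= 0)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(pi_sim) - 1) > 1e-6) {
    stop("p and pi_sim must each sum to 1")
  }
  pif <- pmax(pi_sim, floor)
  used <- p > 0
  if (any(pif[used] == 0)) {
    stop("simulated probability 0 in a non-empty empirical category; set a positive floor")
  }
  bic <- -2 * sum(N * p[used] * log(pif[used])) + M * log(N)
  structure(bic, n_floored = sum(used & pi_sim <= floor))
}

#' Quantile-based BIC of a simulated dataset against empirical data
#'
#' Categorises both tables under the binning scheme derived from the
#' empirical table (default: RT deciles for correct/error trials in easy
#' vs hard value-difference conditions, plus omission categories) and
#' evaluates the quantile BIC.
#'
#' @param empirical observed trial table.
#' @param simulated simulated trial table.
#' @param strata `"vd"` (easy/hard, default) or `"ov"`.
#' @param M free-parameter count of the simulating model.
#' @param floor probability floor; default `1 / (2 * nrow(simulated))`.
#' @param n_quantiles RT bins per cell.
#' @return BIC value (attribute `n_floored`).
#' @export
quantile_bic <- function(empirical, simulated, strata = "vd", M,
                         floor = NULL, n_quantiles = 10) {
  if (nrow(empirical) == 0 || nrow(simulated) == 0) stop("empty trial table")
  scheme <- build_bins(empirical, strata = strata, n_quantiles = n_quantiles)
  ec <- categorize_table(scheme, empirical)
  sc <- categorize_table(scheme, simulated)
  K <- scheme$n_categories
  p  <- tabulate(ec, nbins = K) / length(ec)
  pi_sim <- tabulate(sc, nbins = K) / length(sc)
  quantile_bic_from_probs(p, pi_sim, N = length(ec), M = M,
                          floor = floor %||% 1 / (2 * length(sc)))
}

.model_M <- function(model_name) {
  if (identical(model_name, "lca")) 8L else count_free_params(model_name)
}

#' Compare fitted models by quantile BIC over simulated datasets
#'
#' Simulates `n_sim` datasets from each fitted model (matched to the
#' empirical design), computes the quantile BIC of each against the
#' empirical data, and reports per-model BIC distributions, pairwise mean
#' BIC differences with percentile bootstrap confidence intervals, the
#' fraction of simulation pairs in which each model beats each other, the
#' conservative best-single-simulation comparison, and verdict labels on
#' the conventional meaningful/strong/very strong BIC-difference scale
#' (2 / 6 / 10).
#'
#' @param empirical observed trial table.
#' @param fits named list of `accumimic_fit` objects.
#' @param n_sim simulated datasets per model (>= 2).
#' @param seed integer seed.
#' @param strata BIC stratification (default easy/hard `"vd"`).
#' @param n_boot bootstrap resamples for the CI (default 10000).
#' @param n_quantiles RT bins per cell.
#' @return an `accumimic_comparison` list: `bics` (long data.frame),
#'   `mean_bic`, `pairwise` (data.frame with mean differences, CIs,
#'   win fractions, best-simulation difference, verdicts).
#' @export
compare_models <- function(empirical, fits, n_sim, seed, strata = "vd",
                           n_boot = 10000, n_quantiles = 10) {
  if (n_sim < 2) stop("n_sim must be >= 2")
  stopifnot(length(names(fits)) == length(fits))
  scheme <- build_bins(empirical, strata = strata, n_quantiles = n_quantiles)
  ec <- tabulate(categorize_table(scheme, empirical),
                 nbins = scheme$n_categories)
  p <- ec / sum(ec)
  N <- sum(ec)

  # per-model seeds keyed to the sorted names so reordering `fits` cannot
  # change any model's simulations
  ord <- match(names(fits), sort(names(fits)))
  bics <- do.call(rbind, lapply(seq_along(fits), function(fi) {
    fit <- fits[[fi]]
    M <- .model_M(fit$model)
    vals <- vapply(seq_len(n_sim), function(s) {
      simt <- simulate_from_fit(fit, empirical,
                                seed = as.integer(seed) + ord[fi] * 100003L + s)
      sc <- tabulate(categorize_table(scheme, simt), nbins = scheme$n_categories)
      pi_sim <- sc / sum(sc)
      as.numeric(quantile_bic_from_probs(p, pi_sim, N, M,
                                         floor = 1 / (2 * sum(sc))))
    }, numeric(1))
    data.frame(model = names(fits)[fi], sim = seq_len(n_sim), bic = vals)
  }))

  mean_bic <- tapply(bics$bic, bics$model, mean)[names(fits)]
  pairs <- utils::combn(names(fits), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    ba <- bics$bic[bics$model == pr[1]]
    bb <- bics$bic[bics$model == pr[2]]
    diff_mean <- mean(ba) - mean(bb)
    boot <- withr::with_seed(as.integer(seed) + 7L, {
      vapply(seq_len(n_boot), function(i) {
        mean(sample(ba, replace = TRUE)) - mean(sample(bb, replace = TRUE))
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975)))
    adiff <- abs(diff_mean)
    verdict <- if (adiff <= 2) "negligible" else if (adiff <= 6) "meaningful"
               else if (adiff <= 10) "strong" else "very strong"
    data.frame(model_a = pr[1], model_b = pr[2],
               mean_diff = diff_mean, ci_lo = ci[1], ci_hi = ci[2],
               frac_a_better = mean(outer(ba, bb, `<`)),
               best_sim_diff = min(ba) - min(bb),
               verdict = verdict)
  }))
  structure(list(bics = bics, mean_bic = mean_bic, pairwise = pairwise,
                 seed = as.integer(seed)),
            class = "accumimic_comparison")
}

.skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

#' Per-condition RT quantile summary
#'
#' Deterministic summary for posterior-predictive overlays: per condition
#' cell (easy/hard by median split on the chosen covariate, crossed with
#' correct/error) the RT deciles, trial counts, mean RT and skewness, plus
#' per-difficulty accuracy and omission rates. Empty cells are flagged
#' missing rather than reported as zeros.
#'
#' @param trials a trial table.
#' @param strata `"vd"` (default) or `"ov"`.
#' @param probs quantile probabilities (default deciles).
#' @return list with `cells` (data.frame of per-cell summaries) and
#'   `conditions` (per-difficulty accuracy/omission rates).
#' @export
rt_quantile_summary <- function(trials, strata = "vd",
                                probs = seq(0.1, 0.9, by = 0.1)) {
  x <- .split_covariate(trials, strata)
  hard <- x <= median(x)
  omitted <- trials$response == "omitted"
  correct <- !is.na(trials$correct) & trials$correct
  cells <- do.call(rbind, lapply(c(FALSE, TRUE), function(h) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(ci) {
      sel <- hard == h & correct == ci & !omitted
      n <- sum(sel)
      q <- if (n >= 3) quantile(trials$rt[sel], probs, names = FALSE)
           else rep(NA_real_, length(probs))
      out <- data.frame(difficulty = if (h) "hard" else "easy",
                        outcome = if (ci) "correct" else "error",
                        n = n, missing = n == 0,
                        mean_rt = if (n) mean(trials$rt[sel]) else NA_real_,
                        skewness = .skewness(trials$rt[sel]))
      qd <- as.data.frame(as.list(setNames(q, paste0("q", round(100 * probs)))))
      cbind(out, qd)
    }))
  }))
  conditions <- do.call(rbind, lapply(c(FALSE, TRUE), function(h) {
    sel <- hard == h
    data.frame(difficulty = if (h) "hard" else "easy",
               n = sum(sel),
               accuracy = mean(correct[sel & !omitted]),
               omission_rate = mean(omitted[sel]))
  }))
  list(cells = cells, conditions = conditions)
}
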