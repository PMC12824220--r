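test_that("between-subject RT normalisation matches hand arithmetic", {
  tab <- data.frame(subject_id = c(1, 1, 2, 2),
                    response = "left",
                    rt = c(0.4, 0.6, 0.2, 0.4))
  out <- normalize_rt(tab)
  expect_equal(out$rt, c(0.3, 0.5, 0.3, 0.5))  # grand mean 0.4 preserved
  expect_equal(mean(out$rt), mean(tab$rt))
  # idempotent, and identity for a single subject
  expect_equal(normalize_rt(out)$rt, out$rt)
  single <- tab[tab$subject_id == 1, ]
  expect_equal(normalize_rt(single)$rt, single$rt)
})

test_that("normalisation preserves the grand mean and flags empty subjects", {
  tab <- fix_lca_table()
  out <- normalize_rt(tab)
  expect_equal(mean(out$rt, na.rm = TRUE), mean(tab$rt, na.rm = TRUE))
  sm <- tapply(out$rt, out$subject_id, mean, na.rm = TRUE)
  expect_lt(max(abs(sm - mean(tab$rt, na.rm = TRUE))), 1e-10)
  bad <- tab
  bad$rt[bad$subject_id == 3] <- NA
  bad$response[bad$subject_id == 3] <- "omitted"
  expect_error(normalize_rt(bad), "3")
})

test_that("binning schemes cover every outcome exactly once", {
  tab <- normalize_rt(fix_lca_table())
  scheme <- build_bins(tab, strata = "ov", n_quantiles = 10)
  expect_equal(scheme$n_categories, 42L)
  cats <- categorize_table(scheme, tab)
  expect_true(all(cats >= 1 & cats <= 42))
  expect_equal(length(cats), nrow(tab))
  # omissions land in the per-split omission category
  om <- tab$response == "omitted"
  expect_true(all(cats[om] %in% c(21L, 42L)))
  expect_false(any(cats[!om] %in% c(21L, 42L)))
  # per-cell decile counts are near-equal
  g1c <- cats[cats <= 10]
  expect_true(max(abs(tabulate(g1c, 10) - length(g1c) / 10)) <=
                length(g1c) / 10 * 0.5 + 2)
  # deterministic
  expect_identical(scheme, build_bins(tab, strata = "ov", n_quantiles = 10))
  tiny <- tab[1:30, ]
  expect_error(build_bins(tiny, "ov", 10), "stratum")
})

test_that("category edges are right-closed with boundary tie-breaks", {
  scheme <- structure(list(strata = "ov", split_value = 1,
                           n_quantiles = 3,
                           edges = list(g1_correct = c(0.3, 0.5),
                                        g1_error = c(0.3, 0.5),
                                        g2_correct = c(0.3, 0.5),
                                        g2_error = c(0.3, 0.5)),
                           n_categories = 14L),
                      class = "accumimic_bins")
  # rt below first edge -> bin 1; rt equal to an edge -> lower bin
  ids <- categorize_trials(scheme, split_x = c(0.5, 0.5, 0.5, 0.5),
                           correct = c(TRUE, TRUE, TRUE, TRUE),
                           rt = c(0.1, 0.3, 0.31, 0.7),
                           omitted = rep(FALSE, 4))
  expect_equal(ids, c(1L, 1L, 2L, 3L))
  # omission and the upper split level
  ids2 <- categorize_trials(scheme, split_x = c(2, 2), correct = c(NA, FALSE),
                            rt = c(NA, 0.4), omitted = c(TRUE, FALSE))
  expect_equal(ids2, c(14L, 7L + 3L + 2L))
})

test_that("IBS contributions follow the harmonic-sum formula", {
  # scripted simulator: trial matches on its 3rd draw
  draws <- 0L
  sim <- function(idx) { draws <<- draws + 1L; if (draws == 3L) 1L else 2L }
  r <- ibs_loglik(1L, sim, K_max = 100, repeats = 1)
  expect_equal(r$loglik, -(1 + 1 / 2))
  draws <- 0L
  sim1 <- function(idx) 1L  # immediate match
  expect_equal(ibs_loglik(1L, sim1, K_max = 100, repeats = 1)$loglik, 0)
  # cap flooring
  sim_never <- function(idx) rep(2L, length(idx))
  r2 <- ibs_loglik(1L, sim_never, K_max = 10, repeats = 1)
  expect_equal(r2$loglik, -sum(1 / (1:9)))
  expect_equal(r2$n_capped, 1L)
  expect_error(ibs_loglik(1L, sim1, K_max = 1), "K_max")
})

test_that("IBS is unbiased for Bernoulli categories and scales as 1/repeats", {
  for (p in c(0.3, 0.7)) {
    sim <- function(idx) ifelse(stats::runif(length(idx)) < p, 1L, 2L)
    r <- ibs_loglik(rep(1L, 200), sim, K_max = 5000, repeats = 20, seed = 31)
    est <- mean(r$per_trial)
    se <- r$se / 200
    expect_lt(abs(est - log(p)), 3 * se)
  }
  # variance halves when repeats double (log-log slope near -1)
  sim5 <- function(idx) ifelse(stats::runif(length(idx)) < 0.5, 1L, 2L)
  v <- vapply(c(1, 4, 16), function(R) {
    ests <- vapply(1:200, function(i)
      ibs_loglik(1L, sim5, K_max = 1000, repeats = R, seed = 1000 + i)$loglik,
      numeric(1))
    stats::var(ests)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(v) ~ log(c(1, 4, 16))))[2]
  expect_lt(abs(slope + 1), 0.35)
})

test_that("fitting validates bounds and recovers a likelihood ordering", {
  tab <- normalize_rt(generate_behavior(fix_design_small(),
                                        default_ddm_coefficients("Original*"),
                                        "Original*", seed = 21))
  expect_error(fit_model(tab, "Original*",
                         bounds = list(v_signVD = c(2, -2)), seed = 1),
               "lower bound")
  expect_error(fit_model(tab[0, ], "Original*", seed = 1), "empty")

  # truth scores better than a gross perturbation under the IBS objective
  scheme <- build_bins(tab, "ov", 10)
  obs <- categorize_table(scheme, tab)
  ctx <- accumimic:::.ibs_context(tab, scheme)
  cfg <- list(K_max = 100, dt = 0.005, deadline = 0.75)
  truth <- default_ddm_coefficients("Original*")
  bad <- truth; bad$v_signVD <- -truth$v_signVD
  nll_t <- vapply(1:5, function(r)
    accumimic:::.ibs_nll("Original*", truth, tab, scheme, obs, ctx, cfg,
                         NULL, seed = 40 + r, repeats = 1)$nll, numeric(1))
  nll_b <- vapply(1:5, function(r)
    accumimic:::.ibs_nll("Original*", bad, tab, scheme, obs, ctx, cfg,
                         NULL, seed = 40 + r, repeats = 1)$nll, numeric(1))
  expect_lt(mean(nll_t), mean(nll_b))
})

test_that("the fast IBS path agrees with the generic estimator", {
  tab <- normalize_rt(generate_behavior(fix_design_small(),
                                        default_ddm_coefficients("Original*"),
                                        "Original*", seed = 23))
  scheme <- build_bins(tab, "ov", 10)
  obs <- categorize_table(scheme, tab)
  ctx <- accumimic:::.ibs_context(tab, scheme)
  cfg <- list(K_max = 100, dt = 0.005, deadline = 0.75)
  par <- default_ddm_coefficients("Original*")
  fast <- vapply(1:6, function(r)
    accumimic:::.ibs_nll("Original*", par, tab, scheme, obs, ctx, cfg,
                         NULL, seed = 60 + r, repeats = 1)$nll, numeric(1))
  slow <- vapply(1:6, function(r) {
    sim <- accumimic:::.make_category_simulator("Original*", par, tab, scheme,
                                                cfg$dt, cfg$deadline)
    -ibs_loglik(obs, sim, K_max = 100, repeats = 1, seed = 160 + r)$loglik
  }, numeric(1))
  se <- sqrt(stats::var(fast) / 6 + stats::var(slow) / 6)
  expect_lt(abs(mean(fast) - mean(slow)), 4 * se)
})

test_that("a small fit runs end to end, within bounds, reproducibly", {
  tab <- normalize_rt(generate_behavior(fix_design_small(),
                                        default_ddm_coefficients("Original*"),
                                        "Original*", seed = 22))
  cfg <- list(maxit = 25, restarts = 1, K_max = 50)
  fit <- fit_model(tab, "Original*", config = cfg, seed = 5)
  expect_s3_class(fit, "accumimic_fit")
  for (nm in names(fit$bounds)) {
    expect_gte(fit$par[[nm]], fit$bounds[[nm]][1])
    expect_lte(fit$par[[nm]], fit$bounds[[nm]][2])
  }
  expect_true(all(diff(fit$trace$best) <= 0))
  fit2 <- fit_model(tab, "Original*", config = cfg, seed = 5)
  expect_equal(fit$par, fit2$par)
  expect_gt(fit$par_natural$v_signVD, 0)  # drift sign identified
})
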