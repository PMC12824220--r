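test_that("build_design produces balanced, grid-valid, reproducible tables", {
  d <- fix_design_std()
  expect_equal(nrow(d), 22 * 160)
  vals <- unlist(d[, c("v_left_high", "v_left_low", "v_right_high", "v_right_low")])
  expect_true(all(abs(vals * 10 - round(vals * 10)) < 1e-9))
  expect_true(all(vals >= 0.1 - 1e-9 & vals <= 0.8 + 1e-9))
  expect_true(all(d$v_left_high >= d$v_left_low))
  expect_true(all(d$v_right_high >= d$v_right_low))
  expect_equal(unname(table(d$subject_id)), rep(160L, 22), ignore_attr = TRUE)
  expect_identical(d, build_design(22, 160, seed = 7))
})

test_that("build_design rejects bad inputs and handles the empty case", {
  expect_error(build_design(2, 160, value_grid = numeric(0), seed = 1),
               "non-empty")
  expect_error(build_design(2, 150, seed = 1), "divisible.*16")
  d0 <- build_design(1, 0, seed = 1)
  expect_equal(nrow(d0), 0)
  expect_named(d0, c("subject_id", "trial", "v_left_high", "v_left_low",
                     "v_right_high", "v_right_low"))
})

test_that("regressors match their definitions on the worked example", {
  # left fractals worth 0.70 and 0.90, right 0.30 and 0.40 (euros)
  d <- data.frame(subject_id = 1, trial = 1,
                  v_left_high = 0.9, v_left_low = 0.7,
                  v_right_high = 0.4, v_right_low = 0.3)
  r <- compute_regressors(d)
  expect_equal(r$maxVD, 0.5)
  expect_equal(r$minVD, 0.4)
  expect_equal(r$maxOV, 1.3)
  expect_equal(r$minOV, 1.0)
  expect_equal(r$signVD, 0.45)
  expect_equal(r$OV, 2.3)
})

test_that("regressor identities and swap symmetry hold on random designs", {
  set.seed(99)
  n <- 10000
  g <- seq(0.1, 0.8, by = 0.1)
  lows <- sample(g, 2 * n, replace = TRUE)
  h <- pmin(lows + sample(seq(0, 0.7, 0.1), 2 * n, replace = TRUE), 0.8)
  d <- data.frame(subject_id = 1, trial = seq_len(n),
                  v_left_high = h[1:n], v_left_low = lows[1:n],
                  v_right_high = h[(n + 1):(2 * n)], v_right_low = lows[(n + 1):(2 * n)])
  r <- compute_regressors(d)
  expect_equal(r$absVD, abs(r$signVD))
  expect_equal(r$absMaxVD, abs(r$maxVD))
  expect_equal(r$absMinVD, abs(r$minVD))
  expect_equal(r$OV, r$maxOV + r$minOV)
  expect_equal(r$signVD, (r$maxVD + r$minVD) / 2)
  # swap sides
  ds <- d
  ds$v_left_high <- d$v_right_high; ds$v_left_low <- d$v_right_low
  ds$v_right_high <- d$v_left_high; ds$v_right_low <- d$v_left_low
  rs <- compute_regressors(ds)
  expect_equal(rs$signVD, -r$signVD)
  expect_equal(rs$maxVD, -r$maxVD)
  expect_equal(rs$minVD, -r$minVD)
  expect_equal(rs$absVD, r$absVD)
  expect_equal(rs$maxOV, r$maxOV)
  expect_equal(rs$minOV, r$minOV)
})

test_that("identical bundles give zero value-difference regressors", {
  d <- data.frame(subject_id = 1, trial = 1,
                  v_left_high = 0.6, v_left_low = 0.2,
                  v_right_high = 0.6, v_right_low = 0.2)
  r <- compute_regressors(d)
  expect_equal(r$signVD, 0)
  expect_equal(r$maxVD, 0)
  expect_equal(r$minVD, 0)
})

test_that("unequal weighting de-orthogonalises value difference and overall value", {
  d <- fix_design_std()
  r_eq <- design_correlations(d, weighting(1))$r_wabsVD_wOV
  r_un <- design_correlations(d, weighting(5))$r_wabsVD_wOV
  expect_lt(abs(r_eq), 0.1)
  expect_gt(abs(r_un), abs(r_eq))
})

test_that("design_correlations flags degenerate inputs", {
  d <- fix_design_std()[1:10, ]
  d$v_left_high <- 0.5; d$v_left_low <- 0.5
  d$v_right_high <- 0.5; d$v_right_low <- 0.5
  res <- design_correlations(d, weighting(1))
  expect_true(length(res$undefined) > 0)
  expect_true(is.na(res$r_wabsVD_wOV))
  expect_error(design_correlations(fix_design_std()[1:2, ]), "3 rows")
})

test_that("subject parameter sampling respects constraints and scales", {
  sp <- sample_subject_params("lca", n_subjects = 22, seed = 1)
  expect_length(sp, 22)
  draws <- sample_subject_params("lca", n_subjects = 1000, seed = 2)
  for (nm in c("t0", "b", "k", "w", "a0", "c", "sigma")) {
    expect_true(all(vapply(draws, function(p) p[[nm]] > 0, logical(1))), info = nm)
  }
  expect_true(all(vapply(draws, function(p) p$m >= 0 && p$m <= 1, logical(1))))
  # zero scales collapse to the group location
  cfg <- default_group_config("lca")
  cfg <- lapply(cfg, function(p) { p$scale <- 0; p })
  sp0 <- sample_subject_params("lca", cfg, n_subjects = 3, seed = 3)
  expect_equal(unlist(sp0[[1]]), unlist(sp0[[3]]))
  expect_equal(sp0[[1]]$b, default_lca_params()$b)
  expect_error(sample_subject_params("nonsense", n_subjects = 2, seed = 1))
  cfg_bad <- default_group_config("lca"); cfg_bad$b$scale <- -1
  expect_error(sample_subject_params("lca", cfg_bad, n_subjects = 2, seed = 1),
               "scale")
})

test_that("generated behaviour respects the deadline and is reproducible", {
  tab <- fix_lca_table()
  expect_true(all(is.na(tab$rt) | tab$rt <= 0.75 + 1e-9))
  expect_true(all(tab$response %in% c("left", "right", "omitted")))
  expect_true(all(is.na(tab$rt) == (tab$response == "omitted")))
  tab2 <- generate_behavior(fix_design_std(), default_lca_params(), "lca", seed = 11)
  expect_identical(tab, tab2)
  expect_error(generate_behavior(fix_design_small(), default_lca_params(), "lca",
                                 deadline = -1, seed = 1), "deadline")
  expect_error(generate_behavior(fix_design_small(), default_lca_params(), "lca",
                                 dt = 0, seed = 1), "dt")
})

test_that("extreme drift with no lapses drives accuracy to one", {
  coefs <- default_ddm_coefficients("Original*")
  coefs$v_signVD <- 400
  coefs$p_outlier <- 0
  tab <- generate_behavior(fix_design_small(), coefs, "Original*", seed = 4)
  acc <- mean(tab$correct[!is.na(tab$correct)])
  expect_gt(acc, 0.99)
})
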