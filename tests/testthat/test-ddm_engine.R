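test_that("the model registry matches the published model table", {
  s <- model_registry("Original*")
  expect_equal(s$bound_type, "static")
  expect_equal(s$formulas$v$terms, "signVD")
  expect_false(s$formulas$v$intercept)
  expect_equal(s$formulas$a$terms, "absVD")
  expect_true(s$formulas$a$intercept)
  expect_setequal(s$extra_params, c("z", "p_outlier"))

  s2 <- model_registry("VDOV both")
  expect_equal(s2$bound_type, "angle")
  expect_equal(s2$formulas$a$terms, c("absMaxVD", "absMinVD", "maxOV", "minOV"))
  expect_equal(s2$formulas$theta$terms, s2$formulas$a$terms)
  expect_length(model_names(), 14)
  expect_error(model_registry("nonsense"), "valid names")
})

test_that("free-parameter counts follow the published convention", {
  expect_equal(count_free_params("Original*"), 5L)
  expect_equal(count_free_params("VDOV both"), 14L)
  expect_equal(count_free_params("VD"), 7L)
  # non-decision time is excluded but always fitted
  expect_true("t0" %in% coef_names("Original*"))
})

test_that("trial-level parameter mapping is linear with positivity links", {
  spec <- model_registry("VDOV both")
  coefs <- default_ddm_coefficients("VDOV both")
  tr <- compute_regressors(fix_design_small())[1:50, ]

  # null slopes: parameters equal link-transformed intercepts
  c0 <- coefs
  for (nm in grep("^(a|theta)_(?!int)", names(c0), perl = TRUE, value = TRUE))
    c0[[nm]] <- 0
  for (nm in grep("^v_", names(c0), value = TRUE)) c0[[nm]] <- 0
  tp0 <- trial_params(spec, c0, tr)
  expect_equal(tp0$v, rep(0, nrow(tr)))
  expect_equal(tp0$a, rep(log1p(exp(c0$a_int)), nrow(tr)))
  expect_equal(tp0$theta, rep(log1p(exp(c0$theta_int)), nrow(tr)))

  # hand dot-product: a_int 1.0, a_absMaxVD -0.2, rest 0, absMaxVD 0.5
  ch <- c0
  ch$a_int <- 1.0; ch$a_absMaxVD <- -0.2
  trh <- tr[1, ]
  trh$absMaxVD <- 0.5
  expect_equal(trial_params(spec, ch, trh)$a, log1p(exp(0.9)))

  # doubling a regressor doubles its pre-link contribution
  c1 <- c0; c1$v_maxVD <- 2
  tr2 <- tr; tr2$maxVD <- 2 * tr$maxVD
  expect_equal(trial_params(spec, c1, tr2)$v,
               2 * trial_params(spec, c1, tr)$v)

  expect_error(trial_params(spec, c0[-1], tr), "missing coefficient")
})

test_that("zero-drift diffusion splits responses evenly", {
  tp <- data.frame(v = 0, a = 0.8, theta = 0, z = 0.5, t0 = 0,
                   p_outlier = 0)[rep(1, 1e5), ]
  sim <- simulate_ddm(tp, dt = 0.001, deadline = 50, seed = 8)
  p <- mean(sim$response == "upper")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("the simulator reproduces the two-barrier closed form", {
  # barriers 0 and 2 with start 1 (a = 1, z = 0.5), drift 1:
  # P(upper) = (1 - exp(-2)) / (1 - exp(-4)) = 0.8808
  o <- static_ddm_oracle(1, 1, 0.5)
  expect_equal(o$p_upper, (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-10)
  tp <- data.frame(v = 1, a = 1, theta = 0, z = 0.5, t0 = 0,
                   p_outlier = 0)[rep(1, 1e5), ]
  sim <- simulate_ddm(tp, dt = 0.001, deadline = 50, seed = 9)
  se <- sqrt(o$p_upper * o$p_lower / 1e5)
  expect_lt(abs(mean(sim$response == "upper") - o$p_upper), 3 * se)
})

test_that("the static oracle is a proper defective density pair", {
  expect_equal(static_ddm_oracle(0, 1, 0.3)$p_upper, 0.3)
  o <- static_ddm_oracle(0.8, 0.9, 0.45, t_grid = seq(5e-4, 20, by = 5e-4))
  mass <- sum(o$density$upper + o$density$lower) * 5e-4
  expect_lt(abs(mass - 1), 1e-3)
  up_mass <- sum(o$density$upper) * 5e-4
  expect_lt(abs(up_mass - o$p_upper), 1e-3)
  expect_error(static_ddm_oracle(1, -1, 0.5), "positive")
  expect_error(static_ddm_oracle(1, 1, 1.2), "z")
})

test_that("accuracy is nondecreasing in drift magnitude", {
  acc <- vapply(c(0.5, 1.5, 3), function(v) {
    tp <- data.frame(v = v, a = 0.8, theta = 0, z = 0.5, t0 = 0,
                     p_outlier = 0)[rep(1, 2e4), ]
    mean(simulate_ddm(tp, dt = 0.001, deadline = 50, seed = 10)$response == "upper")
  }, numeric(1))
  expect_true(all(diff(acc) > -2 * sqrt(0.25 / 2e4)))
  expect_gt(acc[3], acc[1])
})

test_that("pure lapses give uniform RTs and even responses", {
  tp <- data.frame(v = 2, a = 0.8, theta = 0, z = 0.5, t0 = 0.2,
                   p_outlier = 1)[rep(1, 1e4), ]
  sim <- simulate_ddm(tp, dt = 0.001, deadline = 0.75, seed = 11)
  expect_lt(abs(mean(sim$response == "upper") - 0.5), 3 * sqrt(0.25 / 1e4))
  ks <- suppressWarnings(stats::ks.test(sim$rt, "punif", 0, 0.75))
  expect_gt(ks$p.value, 0.01)
})

test_that("collapsing bounds reduce RT skew relative to static bounds", {
  n <- 2e4
  tps <- data.frame(v = 1, a = 0.6, theta = 0, z = 0.5, t0 = 0.2,
                    p_outlier = 0)[rep(1, n), ]
  tpa <- transform(tps, theta = 1.0)
  s_static <- simulate_ddm(tps, dt = 0.001, deadline = 5, seed = 12)
  s_angle <- simulate_ddm(tpa, dt = 0.001, deadline = 5, seed = 12)
  sk <- function(x) { x <- x[!is.na(x)]; m <- mean(x)
    mean((x - m)^3) / mean((x - m)^2)^1.5 }
  expect_gt(sk(s_static$rt), sk(s_angle$rt))
})

test_that("choice probabilities are stable under time-step halving", {
  p <- vapply(c(0.002, 0.001), function(dt) {
    tp <- data.frame(v = 1.5, a = 0.7, theta = 0.8, z = 0.5, t0 = 0.2,
                     p_outlier = 0)[rep(1, 4e4), ]
    mean(simulate_ddm(tp, dt = dt, deadline = 0.75, seed = 13)$response == "upper")
  }, numeric(1))
  se <- sqrt(p[2] * (1 - p[2]) / 4e4)
  expect_lt(abs(p[1] - p[2]), 3 * sqrt(2) * se)
})
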