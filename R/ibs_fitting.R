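#' Remove between-subject RT variance
#'
#' Subtracts each subject's mean RT and re-adds the grand (pooled) mean, so
#' that every subject's mean RT equals the grand mean while the grand mean
#' itself is unchanged. Omitted trials are untouched. Idempotent.
#'
#' @param trials a trial table with `subject_id` and `rt` columns.
#' @return the trial table with normalised `rt`.
#' @export
normalize_rt <- function(trials) {
  ok <- !is.na(trials$rt)
  n_by_subj <- tapply(ok, trials$subject_id, sum)
  empty <- names(n_by_subj)[n_by_subj == 0]
  if (length(empty)) {
    stop("subject(s) with no non-omitted trials: ", paste(empty, collapse = ", "))
  }
  grand <- mean(trials$rt[ok])
  subj_mean <- tapply(trials$rt[ok], trials$subject_id[ok], mean)
  shift <- grand - subj_mean[as.character(trials$subject_id)]
  trials$rt <- ifelse(ok, trials$rt + shift, trials$rt)
  trials
}

#' Build a stratified RT-decile binning scheme
#'
#' Outcome categories for simulation-based likelihoods and quantile BIC:
#' trials are stratified by a median split on a design covariate
#' (`"ov"` = overall set value, `"vd"` = absolute equal-weight value
#' difference, i.e. easy/hard), crossed with correct/error, with empirical
#' RT quantile edges (`n_quantiles` bins) in each cell and one omission
#' category per split level.
#'
#' @param trials a trial table with regressor and outcome columns.
#' @param strata `"ov"` or `"vd"`.
#' @param n_quantiles number of RT bins per cell (default 10: deciles).
#' @return an `accumimic_bins` object: split variable and value, per-cell
#'   edge vectors, and the total category count
#'   `2 * (2 * n_quantiles + 1)`.
#' @export
build_bins <- function(trials, strata = c("ov", "vd"), n_quantiles = 10) {
  strata <- match.arg(strata)
  x <- .split_covariate(trials, strata)
  split_value <- median(x)
  g <- 1L + as.integer(x > split_value)
  correct <- !is.na(trials$correct) & trials$correct
  omitted <- trials$response == "omitted"

  edges <- list()
  probs <- seq_len(n_quantiles - 1) / n_quantiles
  for (gi in 1:2) {
    for (ci in c(TRUE, FALSE)) {
      sel <- g == gi & correct == ci & !omitted
      if (sum(sel) < n_quantiles) {
        stop(sprintf("stratum (split=%d, %s) has %d non-omitted trials; need >= %d",
                     gi, if (ci) "correct" else "error", sum(sel), n_quantiles))
      }
      edges[[.cell_key(gi, ci)]] <- unname(quantile(trials$rt[sel], probs))
    }
  }
  structure(list(strata = strata, split_value = split_value,
                 n_quantiles = n_quantiles, edges = edges,
                 n_categories = 2L * (2L * n_quantiles + 1L)),
            class = "accumimic_bins")
}

.cell_key <- function(g, correct) paste0("g", g, if (correct) "_correct" else "_error")

.split_covariate <- function(trials, strata) {
  col <- switch(strata, ov = "OV", vd = "absVD")
  if (!col %in% names(trials)) trials <- compute_regressors(trials)
  trials[[col]]
}

#' Map outcomes to categories of a binning scheme
#'
#' Each outcome maps to exactly one category id: within its split level,
#' correct and error outcomes fall into the RT bin given by the cell's
#' quantile edges (right-closed: an RT equal to an edge falls in the lower
#' bin), and omissions take the split level's omission category. Outcomes
#' on value-tied trials (correct undefined) are categorised with the error
#' cell, consistently for observed and simulated data.
#'
#' @param scheme an `accumimic_bins` scheme.
#' @param split_x the split covariate per trial (design property).
#' @param correct logical per trial (NA allowed).
#' @param rt RT per trial (NA for omissions).
#' @param omitted logical per trial.
#' @return integer category ids in `1:scheme$n_categories`.
#' @export
categorize_trials <- function(scheme, split_x, correct, rt, omitted) {
  Q <- scheme$n_quantiles
  per_level <- 2L * Q + 1L
  g <- 1L + as.integer(split_x > scheme$split_value)
  correct <- !is.na(correct) & correct
  cat_id <- integer(length(g))
  for (gi in 1:2) {
    for (ci in c(TRUE, FALSE)) {
      sel <- which(g == gi & correct == ci & !omitted)
      if (!length(sel)) next
      e <- scheme$edges[[.cell_key(gi, ci)]]
      bin <- 1L + findInterval(rt[sel], e, left.open = TRUE)
      cat_id[sel] <- (gi - 1L) * per_level + (if (ci) 0L else Q) + bin
    }
  }
  om <- which(omitted)
  cat_id[om] <- (g[om] - 1L) * per_level + per_level
  cat_id
}

#' @rdname categorize_trials
#' @param trials a trial table (observed or simulated) with outcome columns.
#' @export
categorize_table <- function(scheme, trials) {
  categorize_trials(scheme,
                    split_x = .split_covariate(trials, scheme$strata),
                    correct = trials$correct,
                    rt = trials$rt,
                    omitted = trials$response == "omitted")
}

#' Inverse binomial sampling log-likelihood estimate
#'
#' For each observed trial, simulates outcomes from the model until the
#' first draw whose category matches the observed category; if the match
#' occurs at draw K the trial's log-likelihood contribution is
#' `-sum(1/j, j = 1..K-1)`. This is an unbiased estimator of `ln p` when
#' the draw cap never binds. Contributions are summed over trials and
#' averaged over `repeats` independent passes. Trials hitting `K_max` are
#' floored at `-sum(1/j, j = 1..K_max-1)` and counted in `n_capped`.
#'
#' @param obs_categories integer category id per observed trial.
#' @param simulator function(active_idx) returning one simulated category
#'   id per requested trial.
#' @param K_max draw cap per trial (>= 2).
#' @param repeats number of independent IBS passes (>= 1).
#' @param seed optional integer seed (pass r uses `seed + r - 1`).
#' @return list with `loglik` (estimate), `se` (analytic standard error of
#'   the estimate), `per_trial` (mean contribution per trial), `n_capped`.
#' @export
ibs_loglik <- function(obs_categories, simulator, K_max = 10000, repeats = 1,
                       seed = NULL) {
  if (K_max < 2) stop("K_max must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  n <- length(obs_categories)
  inv <- 1 / seq_len(K_max)
  H <- c(0, cumsum(inv))        # H[k] = sum_{j=1}^{k-1} 1/j at index k
  V <- c(0, cumsum(inv^2))      # variance estimate companion

  one_pass <- function() {
    K <- integer(n)
    active <- seq_len(n)
    k <- 0L
    while (length(active) && k < K_max) {
      k <- k + 1L
      sims <- simulator(active)
      hit <- sims == obs_categories[active]
      K[active[hit]] <- k
      active <- active[!hit]
    }
    capped <- active
    K[capped] <- K_max
    list(contrib = -H[K], var = V[K], n_capped = length(capped))
  }

  run <- function() {
    passes <- lapply(seq_len(repeats), function(r) {
      if (!is.null(seed)) set.seed(as.integer(seed) + r - 1L)
      one_pass()
    })
    contrib <- Reduce(`+`, lapply(passes, `[[`, "contrib")) / repeats
    varsum <- sum(Reduce(`+`, lapply(passes, `[[`, "var"))) / repeats^2
    list(loglik = sum(contrib), se = sqrt(varsum), per_trial = contrib,
         n_capped = sum(vapply(passes, `[[`, integer(1), "n_capped")))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Default parameter boxes for fitting
#'
#' Plausible box constraints per free parameter, on the natural scale
#' (regression coefficients unconstrained within wide boxes; probabilities
#' and positive scalars within their ranges).
#'
#' @param model_name `"lca"` or a registered DDM name.
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function(model_name) {
  if (identical(model_name, "lca")) {
    return(list(t0 = c(0.05, 0.4), b = c(1, 40), m = c(0, 1), k = c(0.5, 20),
                w = c(0.5, 20), a0 = c(0.2, 3), c = c(0.1, 5),
                sigma = c(0.2, 3)))
  }
  nm <- coef_names(model_registry(model_name))
  setNames(lapply(nm, function(p) {
    if (p %in% c("z")) c(0.2, 0.8)
    else if (p == "p_outlier") c(0.001, 0.2)
    else if (p == "t0") c(0.05, 0.4)
    else if (p == "theta_const") c(0.01, 5)
    else if (p == "sv") c(0, 2)
    else if (grepl("^v_", p)) c(-30, 30)
    else if (grepl("^(a|theta)_int$", p)) c(-3, 3)
    else c(-5, 5)
  }), nm)
}

# z-score the regressor columns a DDM spec uses (indicators left alone);
# returns list(trials, scaling)
.standardize_regressors <- function(trials, spec) {
  cols <- unique(unlist(lapply(spec$formulas, `[[`, "terms")))
  cols <- setdiff(cols, c("hard", "easy"))
  scaling <- list()
  for (col in cols) {
    mu <- mean(trials[[col]]); sdev <- sd(trials[[col]])
    if (sdev == 0) sdev <- 1
    trials[[col]] <- (trials[[col]] - mu) / sdev
    scaling[[col]] <- c(center = mu, scale = sdev)
  }
  list(trials = trials, scaling = scaling)
}

.apply_scaling <- function(trials, scaling) {
  for (col in names(scaling)) {
    trials[[col]] <- (trials[[col]] - scaling[[col]]["center"]) / scaling[[col]]["scale"]
  }
  trials
}

# Static per-trial context for the C++ IBS drivers: split level, edge
# matrix (columns g1/correct, g1/error, g2/correct, g2/error), side info.
.ibs_context <- function(trials, scheme) {
  split_x <- .split_covariate(trials, scheme$strata)
  g <- 1L + as.integer(split_x > scheme$split_value)
  edges <- cbind(scheme$edges[["g1_correct"]], scheme$edges[["g1_error"]],
                 scheme$edges[["g2_correct"]], scheme$edges[["g2_error"]])
  side <- .correct_side(trials)
  list(g = g, edges = edges, Q = scheme$n_quantiles, side = side,
       correct_left = ifelse(is.na(side), -1L, as.integer(side == "left")),
       tie = is.na(side))
}

# Fast IBS negative log-likelihood via the C++ drivers (common random
# numbers: the same seed stream every call makes the objective
# deterministic in the parameters).
.ibs_nll <- function(model_name, par, trials, scheme, obs, ctx, cfg,
                     scaling, seed, repeats, stop_sum = -1) {
  K_max <- cfg$K_max
  inv <- 1 / seq_len(K_max - 1)
  # 0-based in C++: H[k] = sum_{j=1}^{k-1} 1/j, k = 0..K_max
  H <- c(0, 0, cumsum(inv))
  V <- c(0, 0, cumsum(inv^2))
  if (identical(model_name, "lca")) {
    I_left  <- input_drive(par$b, par$m, trials$v_left_high, trials$v_left_low)
    I_right <- input_drive(par$b, par$m, trials$v_right_high, trials$v_right_low)
    if (isTRUE(par$constant_drive)) {
      const <- mean(c(I_left, I_right)); I_left[] <- const; I_right[] <- const
    }
    u1_left <- ctx$tie | ctx$side == "left"
    I1 <- ifelse(u1_left, I_left, I_right)
    I2 <- ifelse(u1_left, I_right, I_left)
    draw <- function() ibs_lca_cpp(obs, I1, I2, par$k, par$w, par$a0, par$c,
                                   par$sigma, par$t0, ctx$tie, ctx$g,
                                   ctx$edges, ctx$Q, K_max, cfg$dt,
                                   cfg$deadline, H, V, stop_sum)
  } else {
    tr <- if (is.null(scaling)) trials else .apply_scaling(trials, scaling)
    tp <- trial_params(model_registry(model_name), par, tr)
    upper_left <- attr(tp, "upper_side") == "left"
    draw <- function() ibs_ddm_cpp(obs, tp$v, tp$a, tp$theta, tp$z, tp$t0,
                                   tp$p_outlier, ctx$correct_left,
                                   upper_left, ctx$g, ctx$edges, ctx$Q,
                                   K_max, cfg$dt, cfg$deadline, H, V, stop_sum)
  }
  withr::with_seed(as.integer(seed), {
    nll <- 0; varsum <- 0; n_capped <- 0L; complete <- TRUE
    for (r in seq_len(repeats)) {
      set.seed(as.integer(seed) + r - 1L)
      res <- draw()
      nll <- nll + res$nll
      varsum <- varsum + res$varsum
      n_capped <- n_capped + res$n_capped
      complete <- complete && res$complete
    }
    list(nll = nll / repeats, se = sqrt(varsum) / repeats,
         n_capped = n_capped, complete = complete)
  })
}

# Build a category simulator for observed trials under a model.
# Returns function(active_idx) -> simulated category ids.
.make_category_simulator <- function(model_name, params, trials, scheme,
                                     dt, deadline, scaling = NULL) {
  split_x <- .split_covariate(trials, scheme$strata)
  if (identical(model_name, "lca")) {
    side <- .correct_side(trials)
    u1_left <- is.na(side) | side == "left"
    I_left  <- input_drive(params$b, params$m, trials$v_left_high, trials$v_left_low)
    I_right <- input_drive(params$b, params$m, trials$v_right_high, trials$v_right_low)
    if (isTRUE(params$constant_drive)) {
      const <- mean(c(I_left, I_right))
      I_left[] <- const; I_right[] <- const
    }
    I1 <- ifelse(u1_left, I_left, I_right)
    I2 <- ifelse(u1_left, I_right, I_left)
    tie <- is.na(side)
    function(idx) {
      sim <- lca_simulate_cpp(I1[idx], I2[idx], params$k, params$w, params$a0,
                              params$c, params$sigma, params$t0, dt, deadline,
                              isTRUE(params$printed_inhibition))
      omitted <- sim$winner == -1L
      correct <- sim$winner == 1L & !tie[idx]
      categorize_trials(scheme, split_x[idx], correct, sim$rt, omitted)
    }
  } else {
    spec <- model_registry(model_name)
    tr <- if (is.null(scaling)) trials else .apply_scaling(trials, scaling)
    tp <- trial_params(spec, params, tr)
    upper_side <- attr(tp, "upper_side")
    side <- .correct_side(trials)
    function(idx) {
      sim <- ddm_simulate_cpp(tp$v[idx], tp$a[idx], tp$theta[idx], tp$z[idx],
                              tp$t0[idx], tp$p_outlier[idx], dt, deadline)
      omitted <- sim$response == -1L
      resp_side <- ifelse(sim$response == 1L, upper_side[idx],
                          ifelse(upper_side[idx] == "left", "right", "left"))
      correct <- !is.na(side[idx]) & resp_side == side[idx]
      categorize_trials(scheme, split_x[idx], correct, sim$rt, omitted)
    }
  }
}

#' Fit a model by IBS likelihood maximisation
#'
#' Estimates the negative log-likelihood of the observed RT-category data
#' by inverse binomial sampling (with common random numbers across
#' evaluations, making the objective deterministic given the seed) and
#' minimises it with bounded multi-start Nelder--Mead on a logit-transformed
#' parameter scale. Fitting is group-level on the pooled trial table; for
#' DDM specifications the value regressors are z-scored per dataset (the
#' scalings are stored in the result).
#'
#' @param trials observed trial table (typically after [normalize_rt()]).
#' @param model_name `"lca"` or a registered DDM name.
#' @param bounds named list of `c(lower, upper)` boxes; defaults from
#'   [default_fit_bounds()].
#' @param config list of fitting controls: `n_quantiles` (10), `strata`
#'   (`"ov"`), `ibs_repeats` (1), `K_max` (500), `maxit` Nelder--Mead
#'   iterations per start (120), `restarts` (2), `dt` (0.005), `deadline`
#'   (0.75).
#' @param seed integer seed; the whole fit is reproducible given the seed.
#' @return an `accumimic_fit` list: `model`, `par` (named list, natural
#'   scale), `nll`, `nll_se`, `trace` (evaluation index, objective,
#'   best-so-far), `convergence`, `bounds`, `scaling`, `scheme`, `seed`,
#'   `config`.
#' @export
fit_model <- function(trials, model_name, bounds = NULL, config = list(), seed) {
  if (nrow(trials) == 0) stop("trials table is empty")
  cfg <- utils::modifyList(list(n_quantiles = 10, strata = "ov", ibs_repeats = 1,
                                K_max = 100, maxit = 120, restarts = 2,
                                polish_repeats = 0, polish_maxit = 30,
                                dt = 0.005, deadline = 0.75), config)
  bounds <- bounds %||% default_fit_bounds(model_name)
  bad <- names(bounds)[vapply(bounds, function(b) b[1] > b[2], logical(1))]
  if (length(bad)) stop("lower bound exceeds upper bound for: ",
                        paste(bad, collapse = ", "))
  pnames <- names(bounds)
  lb <- vapply(bounds, `[`, numeric(1), 1)
  ub <- vapply(bounds, `[`, numeric(1), 2)

  trials <- compute_regressors(trials[, !(names(trials) %in%
    c("signVD", "absVD", "maxVD", "minVD", "absMaxVD", "absMinVD",
      "maxOV", "minOV", "OV", "hard", "easy")), drop = FALSE])
  scheme <- build_bins(trials, strata = cfg$strata, n_quantiles = cfg$n_quantiles)
  obs <- categorize_table(scheme, trials)

  scaling <- NULL
  if (!identical(model_name, "lca")) {
    std <- .standardize_regressors(trials, model_registry(model_name))
    scaling <- std$scaling
  }

  # Random per-fit reflection of the working scale: Nelder--Mead's initial
  # simplex expands each coordinate in one direction, which would push
  # likelihood-flat parameters systematically to one side of the start;
  # a seeded sign flip per coordinate removes that directional bias.
  sgn <- withr::with_seed(as.integer(seed) + 2L,
                          sample(c(-1, 1), length(pnames), replace = TRUE))
  to_par <- function(u) setNames(as.list(lb + (ub - lb) * stats::plogis(sgn * u)),
                                 pnames)

  ctx <- .ibs_context(trials, scheme)
  trace_val <- numeric(0)
  n_eval <- 0L
  best_val <- Inf
  objective <- function(u) {
    par <- to_par(u)
    # abort evaluations that are clearly worse than the best so far
    stop_sum <- if (is.finite(best_val)) best_val + 0.05 * abs(best_val) else -1
    res <- .ibs_nll(model_name, par, trials, scheme, obs, ctx, cfg,
                    scaling, seed = seed, repeats = cfg$ibs_repeats,
                    stop_sum = stop_sum)
    val <- if (res$complete) res$nll else stop_sum + res$nll
    if (res$complete && val < best_val) best_val <<- val
    n_eval <<- n_eval + 1L
    trace_val[n_eval] <<- val
    val
  }

  starts <- withr::with_seed(as.integer(seed) + 1L, {
    s0 <- rep(0, length(pnames))  # box centre
    extra <- lapply(seq_len(max(0, cfg$restarts - 1)), function(i) {
      stats::qlogis(runif(length(pnames), 0.15, 0.85))
    })
    c(list(s0), extra)
  })

  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit, reltol = 1e-3))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("optimizer budget exhausted without a valid evaluation")
  }

  # optional local polish at reduced objective noise
  if (cfg$polish_repeats > 0) {
    pol_obj <- function(u) {
      val <- .ibs_nll(model_name, to_par(u), trials, scheme, obs, ctx, cfg,
                      scaling, seed = as.integer(seed) + 31L,
                      repeats = cfg$polish_repeats)$nll
      n_eval <<- n_eval + 1L
      trace_val[n_eval] <<- val
      val
    }
    pol <- stats::optim(best$par, pol_obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$polish_maxit,
                                       reltol = 1e-4))
    if (is.finite(pol$value)) best <- pol
  }

  par <- to_par(best$par)
  final_res <- .ibs_nll(model_name, par, trials, scheme, obs, ctx, cfg,
                        scaling, seed = as.integer(seed) + 97L,
                        repeats = max(2, cfg$ibs_repeats))
  final <- list(loglik = -final_res$nll, se = final_res$se,
                n_capped = final_res$n_capped)
  trace <- data.frame(eval = seq_along(trace_val), objective = trace_val,
                      best = cummin(trace_val))
  structure(list(model = model_name, par = par,
                 par_natural = .natural_coefs(model_name, par, scaling),
                 nll = -final$loglik,
                 nll_se = final$se, n_capped = final$n_capped,
                 trace = trace, convergence = best$convergence,
                 bounds = bounds, scaling = scaling, scheme = scheme,
                 seed = as.integer(seed), config = cfg),
            class = "accumimic_fit")
}

# Convert natural-scale coefficients onto the z-scored regressor scale
# (inverse of .natural_coefs): slopes multiply by the column sd; intercepts
# absorb the centering of their formula's terms (pre-link).
.standardized_coefs <- function(model_name, par, scaling) {
  if (is.null(scaling) || !length(scaling)) return(par)
  spec <- model_registry(model_name)
  out <- par
  for (p in names(spec$formulas)) {
    f <- spec$formulas[[p]]
    shift <- 0
    for (term in f$terms) {
      sc <- scaling[[term]]
      if (is.null(sc)) next
      cn <- paste0(p, "_", term)
      shift <- shift + par[[cn]] * sc[["center"]]
      out[[cn]] <- par[[cn]] * sc[["scale"]]
    }
    if (isTRUE(f$intercept)) out[[paste0(p, "_int")]] <- par[[paste0(p, "_int")]] + shift
  }
  out
}

# Convert coefficients estimated on z-scored regressors back to the natural
# (euro) regressor scale: slopes divide by the column sd; intercepts absorb
# the centering shifts of their own formula's terms (pre-link scale).
.natural_coefs <- function(model_name, par, scaling) {
  if (is.null(scaling) || !length(scaling)) return(par)
  spec <- model_registry(model_name)
  out <- par
  for (p in names(spec$formulas)) {
    f <- spec$formulas[[p]]
    shift <- 0
    for (term in f$terms) {
      sc <- scaling[[term]]
      if (is.null(sc)) next
      cn <- paste0(p, "_", term)
      shift <- shift + par[[cn]] * sc[["center"]] / sc[["scale"]]
      out[[cn]] <- par[[cn]] / sc[["scale"]]
    }
    if (isTRUE(f$intercept)) out[[paste0(p, "_int")]] <- par[[paste0(p, "_int")]] - shift
  }
  out
}

#' Simulate a dataset from a fitted model
#'
#' Re-simulates every trial of a design under a fitted model's parameters,
#' applying the stored regressor scalings for DDM fits. Returns a trial
#' table matched to the input design (same schema as
#' [generate_behavior()]).
#'
#' @param fit an `accumimic_fit`.
#' @param trials trial/design table to re-simulate (regressors recomputed).
#' @param seed integer seed.
#' @return simulated trial table.
#' @export
simulate_from_fit <- function(fit, trials, seed) {
  design <- trials[, c("subject_id", "trial", "v_left_high", "v_left_low",
                       "v_right_high", "v_right_low")]
  d <- compute_regressors(design)
  withr::with_seed(as.integer(seed), {
    if (identical(fit$model, "lca")) {
      .lca_behavior(d, fit$par, fit$config$deadline, fit$config$dt)
    } else {
      ds <- if (is.null(fit$scaling)) d else .apply_scaling(d, fit$scaling)
      spec <- model_registry(fit$model)
      tp <- trial_params(spec, fit$par, ds)
      upper_side <- attr(tp, "upper_side")
      sim <- ddm_simulate_cpp(tp$v, tp$a, tp$theta, tp$z, tp$t0, tp$p_outlier,
                              fit$config$dt, fit$config$deadline)
      response <- ifelse(sim$response == -1L, "omitted",
                         ifelse(sim$response == 1L, upper_side,
                                ifelse(upper_side == "left", "right", "left")))
      .finish_trials(d, response, sim$rt)
    }
  })
}
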