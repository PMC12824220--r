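#' @useDynLib accumimic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median cor quantile sd optim setNames
NULL

#' Default fractal value grid
#'
#' Fractal values in euros, 0.10 to 0.80 in 0.10 increments.
#' @export
default_value_grid <- function() seq(0.1, 0.8, by = 0.1)

#' Fractal weighting scheme
#'
#' Weights applied to the higher- and lower-valued fractal within a bundle
#' when forming its subjective value. Equal weighting is `ratio = 1`; the
#' default unequal weighting puts five times more weight on the high-value
#' fractal (`ratio = 5`, i.e. w_high = 5/6).
#'
#' @param ratio nonnegative ratio w_high / w_low.
#' @return list with `w_high`, `w_low` summing to 1.
#' @export
weighting <- function(ratio = 1) {
  stopifnot(is.numeric(ratio), length(ratio) == 1, ratio >= 0, is.finite(ratio))
  w_high <- ratio / (1 + ratio)
  structure(list(w_high = w_high, w_low = 1 - w_high), class = "accumimic_weighting")
}

#' Build a balanced bundle-choice design
#'
#' Generates a trial table of two-bundle choices, each bundle holding a
#' high- and a low-valued fractal drawn from a value grid. Trials are
#' stratified approximately uniformly over cells of (overall-value bin x
#' equal-weight value-difference bin), reproducing the balancing of total
#' value and left-right value difference, with left/right assignment
#' randomised per trial.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject; must be divisible by the number of
#'   balance cells (`n_ov_bins * n_vd_bins`).
#' @param value_grid numeric vector of admissible fractal values (euros).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param n_ov_bins,n_vd_bins number of balance bins for overall value and
#'   absolute equal-weight value difference.
#' @return data.frame with columns `subject_id`, `trial`, `v_left_high`,
#'   `v_left_low`, `v_right_high`, `v_right_low`.
#' @export
build_design <- function(n_subjects, n_trials, value_grid = default_value_grid(),
                         seed, n_ov_bins = 4, n_vd_bins = 4) {
  if (length(value_grid) == 0) stop("value_grid must be non-empty")
  stopifnot(n_subjects >= 1, n_trials >= 0)
  n_cells <- n_ov_bins * n_vd_bins

  if (n_trials == 0) {
    return(data.frame(subject_id = integer(0), trial = integer(0),
                      v_left_high = numeric(0), v_left_low = numeric(0),
                      v_right_high = numeric(0), v_right_low = numeric(0)))
  }
  if (n_trials %% n_cells != 0) {
    stop(sprintf("n_trials (%d) must be divisible by the number of balance cells (%d)",
                 n_trials, n_cells))
  }

  # enumerate all unordered pairs of bundles (high >= low on the grid)
  g <- sort(value_grid)
  bundles <- expand.grid(low = g, high = g)
  bundles <- bundles[bundles$high >= bundles$low, , drop = FALSE]
  nb <- nrow(bundles)
  idx <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  idx <- idx[idx$i <= idx$j, , drop = FALSE]
  pairs <- data.frame(
    a_high = bundles$high[idx$i], a_low = bundles$low[idx$i],
    b_high = bundles$high[idx$j], b_low = bundles$low[idx$j])
  ov   <- (pairs$a_high + pairs$a_low + pairs$b_high + pairs$b_low)
  vd   <- abs((pairs$a_high + pairs$a_low) - (pairs$b_high + pairs$b_low)) / 2

  ov_bin <- .quantile_bin(ov, n_ov_bins)
  vd_bin <- .quantile_bin(vd, n_vd_bins)
  cell <- interaction(ov_bin, vd_bin, drop = FALSE)
  if (any(table(cell) == 0)) {
    stop("some balance cells are empty under this grid; reduce n_ov_bins/n_vd_bins")
  }
  per_cell <- n_trials %/% n_cells

  withr::with_seed(as.integer(seed), {
    out <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      rows <- unlist(lapply(split(seq_len(nrow(pairs)), cell), function(ix) {
        sample(ix, per_cell, replace = length(ix) < per_cell)
      }), use.names = FALSE)
      rows <- sample(rows)  # shuffle trial order
      p <- pairs[rows, , drop = FALSE]
      flip <- runif(n_trials) < 0.5  # randomise side assignment
      out[[s]] <- data.frame(
        subject_id = s,
        trial = seq_len(n_trials),
        v_left_high  = ifelse(flip, p$b_high, p$a_high),
        v_left_low   = ifelse(flip, p$b_low,  p$a_low),
        v_right_high = ifelse(flip, p$a_high, p$b_high),
        v_right_low  = ifelse(flip, p$a_low,  p$b_low))
    }
    design <- do.call(rbind, out)
    rownames(design) <- NULL
    design
  })
}

# quantile-based binning into k groups, robust to heavy ties
.quantile_bin <- function(x, k) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1), names = FALSE))
  if (length(br) < k + 1) {
    # fall back to equally spaced breaks over the range
    br <- seq(min(x), max(x), length.out = k + 1)
  }
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Compute value regressors for a design
#'
#' Adds the trial-level value regressors used by the model registry:
#' `signVD`/`absVD` (signed/absolute equal-weight bundle value difference,
#' left minus right), `maxVD`/`minVD` (differences between the two
#' high-valued and between the two low-valued fractals), their absolute
#' versions, `maxOV`/`minOV` (sums of the high-valued and of the low-valued
#' fractals), `OV` (total set value), and `hard`/`easy` indicators from a
#' median split on `absVD`.
#'
#' @param design a design table from [build_design()].
#' @return the design with regressor columns appended.
#' @export
compute_regressors <- function(design) {
  stopifnot(all(c("v_left_high", "v_left_low", "v_right_high", "v_right_low")
                %in% names(design)))
  d <- design
  d$maxVD <- d$v_left_high - d$v_right_high
  d$minVD <- d$v_left_low - d$v_right_low
  d$signVD <- (d$maxVD + d$minVD) / 2
  d$absVD <- abs(d$signVD)
  d$absMaxVD <- abs(d$maxVD)
  d$absMinVD <- abs(d$minVD)
  d$maxOV <- d$v_left_high + d$v_right_high
  d$minOV <- d$v_left_low + d$v_right_low
  d$OV <- d$maxOV + d$minOV
  med <- median(d$absVD)
  d$hard <- as.numeric(d$absVD <= med)
  d$easy <- 1 - d$hard
  d
}

#' Correlation between weighted value difference and weighted overall value
#'
#' Under a fractal weighting, a bundle's subjective value is
#' `w_high * high + w_low * low`. This reports the correlation structure of
#' the weighted absolute value difference and the weighted overall value
#' (and the equal-weight regressors), showing how unequal weighting
#' de-orthogonalises a design balanced under equal weights.
#'
#' @param design a design table (regressors recomputed internally).
#' @param weighting a [weighting()] object.
#' @return list with `cor` (correlation matrix over `wabsVD`, `wOV`,
#'   `absVD`, `OV`), `undefined` (names of constant columns, excluded), and
#'   `r_wabsVD_wOV` (the headline scalar, NA if undefined).
#' @export
design_correlations <- function(design, weighting = weighting(1)) {
  if (nrow(design) < 3) stop("need at least 3 rows to estimate correlations")
  wh <- weighting$w_high; wl <- weighting$w_low
  vl <- wh * design$v_left_high + wl * design$v_left_low
  vr <- wh * design$v_right_high + wl * design$v_right_low
  x <- data.frame(wabsVD = abs(vl - vr), wOV = vl + vr)
  r <- compute_regressors(design)
  x$absVD <- r$absVD
  x$OV <- r$OV
  sds <- vapply(x, sd, numeric(1))
  undefined <- names(x)[sds == 0]
  keep <- x[, sds > 0, drop = FALSE]
  cm <- if (ncol(keep) >= 2) cor(keep) else matrix(numeric(0), 0, 0)
  scalar <- if (all(c("wabsVD", "wOV") %in% colnames(cm))) cm["wabsVD", "wOV"] else NA_real_
  list(cor = cm, undefined = undefined, r_wabsVD_wOV = scalar)
}

#' Sample subject-level parameter sets
#'
#' Draws per-subject parameters around group-level locations:
#' positivity-constrained parameters are sampled on the log scale
#' (log-normal around the location), unconstrained ones from a normal.
#' Parameters constrained to (0, 1) (`z`, `p_outlier`, `m`) are sampled on
#' the logit scale.
#'
#' @param model_name `"lca"` or a registered DDM model name (see
#'   [model_registry()]).
#' @param group_config named list: for each parameter a list with `location`
#'   and `scale` (scale 0 gives the location for every subject). Defaults
#'   from [default_group_config()].
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return list of per-subject named parameter lists (class
#'   `accumimic_subject_params`), with attributes `model_name`.
#' @export
sample_subject_params <- function(model_name, group_config = NULL, n_subjects, seed) {
  cfg <- group_config %||% default_group_config(model_name)
  kinds <- .param_kinds(model_name, names(cfg))
  bad <- vapply(cfg, function(p) !is.finite(p$scale) || p$scale < 0, logical(1))
  if (any(bad)) stop("negative or non-finite scale for: ",
                     paste(names(cfg)[bad], collapse = ", "))
  withr::with_seed(as.integer(seed), {
    draws <- lapply(seq_len(n_subjects), function(s) {
      p <- lapply(names(cfg), function(nm) {
        loc <- cfg[[nm]]$location; sc <- cfg[[nm]]$scale
        switch(kinds[[nm]],
               positive = exp(rnorm(1, log(loc), sc)),
               unit     = stats::plogis(rnorm(1, stats::qlogis(loc), sc)),
               free     = rnorm(1, loc, sc))
      })
      names(p) <- names(cfg)
      p
    })
    structure(draws, class = "accumimic_subject_params", model_name = model_name)
  })
}

# constraint kind per parameter name
.param_kinds <- function(model_name, nms) {
  if (identical(model_name, "lca")) {
    kinds <- c(t0 = "positive", b = "positive", m = "unit", k = "positive",
               w = "positive", a0 = "positive", c = "positive", sigma = "positive")
    if (!all(nms %in% names(kinds)))
      stop("unknown LCA parameter(s): ",
           paste(setdiff(nms, names(kinds)), collapse = ", "))
    kinds[nms]
  } else {
    spec <- model_registry(model_name)  # errors for unknown models
    setNames(vapply(nms, function(nm) {
      if (nm %in% c("z", "p_outlier")) "unit"
      else if (nm %in% c("t0", "theta_const", "sv")) "positive"
      else "free"  # regression coefficients
    }, character(1)), nms)
  }
}

#' Default group-level parameter configuration
#'
#' Locations and between-subject scales for the generative models used by
#' the synthetic-data pipelines. These define the simulated study
#' conditions: choice accuracy well above chance, right-skewed RTs, and a
#' nonzero omission rate under the 750 ms deadline.
#'
#' @param model_name `"lca"` or a registered DDM name.
#' @return named list of `list(location=, scale=)` records.
#' @export
default_group_config <- function(model_name) {
  if (identical(model_name, "lca")) {
    loc <- default_lca_params()
    sc <- c(t0 = 0.1, b = 0.15, m = 0.3, k = 0.15, w = 0.15,
            a0 = 0.1, c = 0.15, sigma = 0.1)
    return(lapply(setNames(names(loc), names(loc)),
                  function(nm) list(location = loc[[nm]], scale = sc[[nm]])))
  }
  spec <- model_registry(model_name)
  coefs <- default_ddm_coefficients(model_name)
  # coefficient spread proportional to its magnitude (several-fold
  # participant heterogeneity is typical for drift/threshold regressions)
  sc <- lapply(coefs, function(x) 0.3 * abs(x) + 0.05)
  sc$z <- 0.2; sc$p_outlier <- 0.3; sc$t0 <- 0.1
  lapply(setNames(names(coefs), names(coefs)),
         function(nm) list(location = coefs[[nm]], scale = sc[[nm]]))
}

#' Generate synthetic choice behaviour
#'
#' Simulates responses and RTs for every trial of a design from a named
#' generative model with per-subject parameters, under a response deadline.
#' DDM models are response-coded (upper bound = left); the LCA is
#' accuracy-coded internally and mapped back to sides. `correct` compares
#' the response to the higher equal-weight bundle value (NA on exact ties).
#'
#' @param design design table from [build_design()].
#' @param subject_params list from [sample_subject_params()] (or a single
#'   parameter record applied to all subjects).
#' @param model_name `"lca"` or a registered DDM name; defaults to the
#'   `model_name` attribute of `subject_params`.
#' @param deadline response deadline in seconds.
#' @param dt Euler step in seconds.
#' @param seed integer seed.
#' @return a trial table: the design plus regressors, `response`
#'   (`"left"`, `"right"`, `"omitted"`), `rt` (seconds, NA when omitted),
#'   `correct` (logical, NA when omitted or tied).
#' @export
generate_behavior <- function(design, subject_params, model_name = NULL,
                              deadline = 0.75, dt = 0.001, seed) {
  if (deadline <= 0) stop("deadline must be positive")
  if (dt <= 0) stop("dt must be positive")
  model_name <- model_name %||% attr(subject_params, "model_name")
  stopifnot(!is.null(model_name))
  d <- compute_regressors(design)
  subjects <- unique(d$subject_id)
  if (!is.list(subject_params[[1]])) subject_params <- rep(list(subject_params), length(subjects))
  stopifnot(length(subject_params) >= length(subjects))

  withr::with_seed(as.integer(seed), {
    parts <- lapply(seq_along(subjects), function(si) {
      ds <- d[d$subject_id == subjects[si], , drop = FALSE]
      pars <- subject_params[[si]]
      if (identical(model_name, "lca")) {
        .lca_behavior(ds, pars, deadline, dt)
      } else {
        .ddm_behavior(ds, pars, model_name, deadline, dt)
      }
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

# equal-weight correct side: "left", "right", or NA on (numerically) tied
# bundle sums
.correct_side <- function(d) {
  diff <- (d$v_left_high + d$v_left_low) - (d$v_right_high + d$v_right_low)
  ifelse(diff > 1e-9, "left", ifelse(diff < -1e-9, "right", NA_character_))
}

.ddm_behavior <- function(ds, pars, model_name, deadline, dt) {
  spec <- model_registry(model_name)
  tp <- trial_params(spec, pars, ds)
  sim <- ddm_simulate_cpp(tp$v, tp$a, tp$theta, tp$z, tp$t0, tp$p_outlier,
                          dt, deadline)
  upper_side <- attr(tp, "upper_side")
  lower_side <- ifelse(upper_side == "left", "right", "left")
  response <- ifelse(sim$response == 1L, upper_side,
                     ifelse(sim$response == 0L, lower_side, "omitted"))
  .finish_trials(ds, response, sim$rt)
}

.lca_behavior <- function(ds, pars, deadline, dt) {
  side <- .correct_side(ds)
  # accumulator 1 = correct option; ties arbitrarily assign left to unit 1
  u1_left <- is.na(side) | side == "left"
  I_left  <- input_drive(pars$b, pars$m, ds$v_left_high, ds$v_left_low)
  I_right <- input_drive(pars$b, pars$m, ds$v_right_high, ds$v_right_low)
  if (isTRUE(pars$constant_drive)) {
    # value-free negative control: both options share the mean drive
    const <- mean(c(I_left, I_right))
    I_left[] <- const
    I_right[] <- const
  }
  I1 <- ifelse(u1_left, I_left, I_right)
  I2 <- ifelse(u1_left, I_right, I_left)
  sim <- lca_simulate_cpp(I1, I2, pars$k, pars$w, pars$a0, pars$c,
                          pars$sigma, pars$t0, dt, deadline,
                          isTRUE(pars$printed_inhibition))
  u1_side <- ifelse(u1_left, "left", "right")
  u2_side <- ifelse(u1_left, "right", "left")
  response <- ifelse(sim$winner == 1L, u1_side,
                     ifelse(sim$winner == 2L, u2_side, "omitted"))
  .finish_trials(ds, response, sim$rt)
}

.finish_trials <- function(ds, response, rt) {
  side <- .correct_side(ds)
  ds$response <- response
  ds$rt <- ifelse(response == "omitted", NA_real_, rt)
  ds$correct <- ifelse(response == "omitted", NA, response == side)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
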