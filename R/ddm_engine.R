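#' The model zoo: value-regression drift diffusion specifications
#'
#' Returns the specification of one of the 14 registered DDM variants. Each
#' spec maps value regressors onto DDM parameters through linear formulas:
#' drift `v` (identity link), initial threshold `a` and collapse rate
#' `theta` (softplus link, keeping them positive). `bound_type` is
#' `"static"` (fixed threshold) or `"angle"` (linearly collapsing bound).
#' "init"-type collapsing models carry a constant free collapse rate
#' (`theta_const`); "rate"-type models regress the collapse rate and keep a
#' free constant initial threshold.
#'
#' @param name one of `model_names()`.
#' @return list of class `accumimic_model_spec` with elements `name`,
#'   `bound_type`, `formulas` (per-parameter list of `intercept` flag and
#'   regressor `terms`), `extra_params`, `coding`.
#' @export
model_registry <- function(name) {
  reg <- .model_table()
  if (!name %in% names(reg)) {
    stop("unknown model '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  }
  structure(c(list(name = name), reg[[name]]), class = "accumimic_model_spec")
}

#' @rdname model_registry
#' @export
model_names <- function() names(.model_table())

.f <- function(terms, intercept = TRUE) list(intercept = intercept, terms = terms)

.model_table <- function() {
  vd   <- c("absMaxVD", "absMinVD")
  ov   <- c("maxOV", "minOV")
  vdov <- c(vd, ov)
  angle_row <- function(a_terms, kind) {
    switch(kind,
      both = list(bound_type = "angle",
                  formulas = list(v = .f(c("maxVD", "minVD"), FALSE),
                                  a = .f(a_terms), theta = .f(a_terms)),
                  extra_params = c("z", "p_outlier"), coding = "response"),
      init = list(bound_type = "angle",
                  formulas = list(v = .f(c("maxVD", "minVD"), FALSE),
                                  a = .f(a_terms)),
                  extra_params = c("z", "p_outlier", "theta_const"),
                  coding = "response"),
      rate = list(bound_type = "angle",
                  formulas = list(v = .f(c("maxVD", "minVD"), FALSE),
                                  a = .f(character(0)), theta = .f(a_terms)),
                  extra_params = c("z", "p_outlier"), coding = "response"))
  }
  list(
    "Original" = list(
      bound_type = "static",
      formulas = list(v = .f(c("hard", "easy"), FALSE),
                      a = .f(c("hard", "easy"), FALSE),
                      z = .f(c("hard", "easy"), FALSE)),
      extra_params = character(0), coding = "accuracy"),
    "Original*" = list(
      bound_type = "static",
      formulas = list(v = .f("signVD", FALSE), a = .f("absVD")),
      extra_params = c("z", "p_outlier"), coding = "response"),
    "VD" = list(
      bound_type = "static",
      formulas = list(v = .f(c("maxVD", "minVD"), FALSE), a = .f(vd)),
      extra_params = c("z", "p_outlier"), coding = "response"),
    "OV" = list(
      bound_type = "static",
      formulas = list(v = .f(c("maxVD", "minVD"), FALSE), a = .f(ov)),
      extra_params = c("z", "p_outlier"), coding = "response"),
    "VDOV" = list(
      bound_type = "static",
      formulas = list(v = .f(c("maxVD", "minVD"), FALSE), a = .f(vdov)),
      extra_params = c("z", "p_outlier"), coding = "response"),
    "VD both"   = angle_row(vd, "both"),
    "VD init"   = angle_row(vd, "init"),
    "VD rate"   = angle_row(vd, "rate"),
    "OV both"   = angle_row(ov, "both"),
    "OV init"   = angle_row(ov, "init"),
    "OV rate"   = angle_row(ov, "rate"),
    "VDOV both" = angle_row(vdov, "both"),
    "VDOV init" = angle_row(vdov, "init"),
    "VDOV rate" = angle_row(vdov, "rate"))
}

#' Number of free parameters of a model specification
#'
#' Counts every regression coefficient (intercepts included) plus the free
#' scalar parameters among starting point `z`, lapse rate `p_outlier`,
#' drift variability `sv` and a constant collapse rate `theta_const`.
#' Non-decision time is excluded from the count.
#'
#' @param spec an `accumimic_model_spec`, or a model name.
#' @return integer count.
#' @export
count_free_params <- function(spec) {
  if (is.character(spec)) spec <- model_registry(spec)
  n_formula <- sum(vapply(spec$formulas, function(f) {
    length(f$terms) + as.integer(isTRUE(f$intercept))
  }, integer(1)))
  n_extra <- length(intersect(spec$extra_params,
                              c("z", "p_outlier", "sv", "theta_const")))
  as.integer(n_formula + n_extra)
}

#' Names of the free coefficients of a model specification
#'
#' Regression coefficients are named `<param>_int` for intercepts and
#' `<param>_<regressor>` for slopes; the scalar extras keep their own names.
#' `t0` is always present (fitted but excluded from complexity counts).
#'
#' @param spec an `accumimic_model_spec` or a model name.
#' @return character vector of coefficient names.
#' @export
coef_names <- function(spec) {
  if (is.character(spec)) spec <- model_registry(spec)
  nm <- unlist(lapply(names(spec$formulas), function(p) {
    f <- spec$formulas[[p]]
    c(if (isTRUE(f$intercept)) paste0(p, "_int"),
      if (length(f$terms)) paste0(p, "_", f$terms))
  }))
  c(nm, spec$extra_params, "t0")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Default generative coefficients for a DDM specification
#'
#' A documented generative parameter regime for synthetic-data pipelines:
#' baseline threshold about 0.5 evidence units, non-decision time 0.25 s,
#' drifts scaled so that accuracy is well above chance for typical value
#' differences, and (for collapsing-bound models) a bound that reaches zero
#' near the response deadline.
#'
#' @param model_name a registered model name.
#' @return named list of coefficients (a valid input to [trial_params()]).
#' @export
default_ddm_coefficients <- function(model_name) {
  spec <- model_registry(model_name)
  defaults <- c(
    v_signVD = 8, v_maxVD = 6.5, v_minVD = 1.3,
    v_hard = 1.2, v_easy = 2.5,
    a_int = inv_softplus(0.5),
    a_absVD = 0.4, a_absMaxVD = 0.3, a_absMinVD = 0.15,
    a_maxOV = -0.25, a_minOV = -0.1,
    a_hard = inv_softplus(0.45), a_easy = inv_softplus(0.55),
    z_hard = 0, z_easy = 0,
    theta_int = inv_softplus(1.0),
    theta_absMaxVD = 0.2, theta_absMinVD = 0.1,
    theta_maxOV = 0.15, theta_minOV = 0.05,
    z = 0.5, p_outlier = 0.02, theta_const = 1.0, sv = 0, t0 = 0.25)
  nm <- coef_names(spec)
  stopifnot(all(nm %in% names(defaults)))
  as.list(defaults[nm])
}

#' Map value regressors to trial-level DDM parameters
#'
#' Evaluates each parameter formula of `spec` as a linear combination of
#' the trial regressors: drift `v` on the identity scale, threshold `a` and
#' collapse rate `theta` through a softplus positivity link, starting point
#' `z` through a logistic link when regressed. Under accuracy coding the
#' signed regressors (`signVD`, `maxVD`, `minVD`) are flipped so that
#' positive drift points at the objectively better bundle (equal-weight
#' sum); ties keep the left-is-upper convention.
#'
#' @param spec an `accumimic_model_spec` or model name.
#' @param coefs named list/vector of coefficients covering [coef_names()].
#' @param trials a trial table carrying the regressor columns (and, for
#'   accuracy coding, the design value columns).
#' @return data.frame with columns `v`, `a`, `theta`, `z`, `t0`,
#'   `p_outlier`, one row per trial, plus attribute `upper_side` (character
#'   per trial: which side the upper bound denotes).
#' @export
trial_params <- function(spec, coefs, trials) {
  if (is.character(spec)) spec <- model_registry(spec)
  coefs <- as.list(coefs)
  needed <- coef_names(spec)
  missing <- setdiff(needed, names(coefs))
  if (length(missing)) stop("missing coefficient(s): ", paste(missing, collapse = ", "))

  n <- nrow(trials)
  tr <- trials
  if (identical(spec$coding, "accuracy")) {
    side <- .correct_side(trials)
    s <- ifelse(is.na(side) | side == "left", 1, -1)
    for (col in intersect(c("signVD", "maxVD", "minVD"), names(tr))) {
      tr[[col]] <- tr[[col]] * s
    }
    upper_side <- ifelse(s == 1, "left", "right")
  } else {
    upper_side <- rep("left", n)
  }

  lin <- function(param) {
    f <- spec$formulas[[param]]
    out <- rep(if (isTRUE(f$intercept)) coefs[[paste0(param, "_int")]] else 0, n)
    for (term in f$terms) {
      if (!term %in% names(tr)) stop("regressor '", term, "' not found in trials")
      out <- out + coefs[[paste0(param, "_", term)]] * tr[[term]]
    }
    out
  }

  v <- lin("v")
  sv <- coefs[["sv"]] %||% 0
  if (is.numeric(sv) && length(sv) == 1 && sv > 0) v <- v + rnorm(n, 0, sv)
  a <- softplus(lin("a"))
  theta <- if (identical(spec$bound_type, "static")) {
    rep(0, n)
  } else if (!is.null(spec$formulas$theta)) {
    softplus(lin("theta"))
  } else {
    rep(coefs[["theta_const"]], n)
  }
  z <- if (!is.null(spec$formulas$z)) stats::plogis(lin("z")) else rep(coefs[["z"]], n)
  p_out <- rep(coefs[["p_outlier"]] %||% 0, n)

  out <- data.frame(v = v, a = a, theta = theta, z = z,
                    t0 = rep(coefs[["t0"]], n), p_outlier = p_out)
  attr(out, "upper_side") <- upper_side
  out
}

#' Simulate drift-diffusion trials
#'
#' Euler--Maruyama simulation of a diffusion with unit noise between
#' symmetric absorbing bounds `+/- max(0, a - theta * t)`, starting at
#' `a * (2z - 1)`. The effective bound is pulled inward by `0.5826 sqrt(dt)`
#' (continuity correction), removing the leading-order absorption bias of
#' discrete-time barrier checks. The walk runs until absorption or
#' `deadline - t0`; unabsorbed trials are omissions. With probability
#' `p_outlier` a trial is a lapse (uniform response, RT uniform on
#' `(0, deadline)`).
#'
#' @param params data.frame with columns `v`, `a`, `theta`, `z`, `t0`,
#'   `p_outlier` (one row per trial), e.g. from [trial_params()].
#' @param dt Euler step (s).
#' @param deadline response deadline (s).
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @return data.frame with `response` (`"upper"`, `"lower"`, `"omitted"`)
#'   and `rt` (seconds; NA when omitted).
#' @export
simulate_ddm <- function(params, dt = 0.001, deadline = 0.75, seed = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (deadline <= 0) stop("deadline must be positive")
  res <- if (is.null(seed)) {
    ddm_simulate_cpp(params$v, params$a, params$theta, params$z,
                     params$t0, params$p_outlier, dt, deadline)
  } else {
    withr::with_seed(as.integer(seed), {
      ddm_simulate_cpp(params$v, params$a, params$theta, params$z,
                       params$t0, params$p_outlier, dt, deadline)
    })
  }
  response <- ifelse(res$response == 1L, "upper",
                     ifelse(res$response == 0L, "lower", "omitted"))
  data.frame(response = response, rt = res$rt, stringsAsFactors = FALSE)
}

#' Closed-form oracle for the static-bound diffusion
#'
#' Absorption probabilities and first-passage densities for a drift
#' diffusion with unit noise between fixed absorbing bounds `+/- a`,
#' starting at `a * (2z - 1)` (classical two-barrier results; the
#' large-time sine series for the densities, truncated adaptively).
#' Decision time only: no non-decision offset, no lapses.
#'
#' @param v drift rate.
#' @param a bound half-separation (> 0).
#' @param z relative start in (0, 1).
#' @param t_grid increasing grid of decision times (s) for the densities.
#' @return list with `p_upper`, `p_lower`, and data.frame `density`
#'   (`t`, `upper`, `lower`: defective first-passage densities).
#' @export
static_ddm_oracle <- function(v, a, z, t_grid = seq(0.001, 10, by = 0.001)) {
  if (a <= 0) stop("a must be positive")
  if (z <= 0 || z >= 1) stop("z must lie strictly in (0, 1)")
  if (any(t_grid <= 0)) stop("t_grid must be positive")
  A <- 2 * a          # barrier separation, barriers at 0 and A
  w <- 2 * a * z      # start position above the lower barrier

  p_upper <- if (abs(v) < 1e-12) {
    z
  } else {
    (1 - exp(-2 * v * w)) / (1 - exp(-2 * v * A))
  }

  # defective density of first passage to the lower barrier at 0 for drift
  # mu, start w in (0, A):
  #   g(t) = (pi / A^2) exp(-mu w - mu^2 t / 2)
  #          * sum_k k exp(-k^2 pi^2 t / (2 A^2)) sin(k pi w / A)
  fp_lower <- function(mu, w0, t) {
    tmin <- min(t)
    lam <- pi^2 / (2 * A^2)
    K <- 1
    while (K < 50000 && (K + 1) * exp(-lam * (K + 1)^2 * tmin) > 1e-14) K <- K + 1
    k <- seq_len(K)
    S <- (k * sin(k * pi * w0 / A)) %*% exp(-lam * outer(k^2, t))
    as.numeric((pi / A^2) * exp(-mu * w0 - mu^2 * t / 2) * S)
  }

  dens_lower <- fp_lower(v, w, t_grid)
  dens_upper <- fp_lower(-v, A - w, t_grid)  # reflection
  list(p_upper = p_upper, p_lower = 1 - p_upper,
       density = data.frame(t = t_grid, upper = dens_upper, lower = dens_lower))
}
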