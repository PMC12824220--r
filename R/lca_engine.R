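#' Default leaky competing accumulator parameters
#'
#' A documented generative regime for the control-free LCA: non-decision
#' time `t0` (s), total input drive `b` (drive units per euro), max/min
#' drive ratio `m` in (0, 1), leak `k` (1/s), mutual inhibition `w` (1/s),
#' initial bound `a0` (evidence units), bound collapse rate `c`
#' (evidence/s) and noise scale `sigma`. Chosen so that simulated behaviour
#' shows accuracy well above chance, right-skewed RTs, a nonzero omission
#' rate under the 750 ms deadline, and overall-value speeding.
#'
#' @return named list of the 8 free parameters.
#' @export
default_lca_params <- function() {
  list(t0 = 0.2, b = 11, m = 5 / 6, k = 6, w = 5,
       a0 = 1.2, c = 1.0, sigma = 0.9)
}

.check_lca_params <- function(p) {
  need <- c("t0", "b", "m", "k", "w", "a0", "c", "sigma")
  missing <- setdiff(need, names(p))
  if (length(missing)) stop("missing LCA parameter(s): ", paste(missing, collapse = ", "))
  pos <- c("t0", "b", "k", "w", "a0", "c", "sigma")
  bad <- pos[vapply(pos, function(nm) !is.finite(p[[nm]]) || p[[nm]] <= 0, logical(1))]
  if (length(bad)) stop("LCA parameter(s) must be positive: ", paste(bad, collapse = ", "))
  if (p$m < 0 || p$m > 1) stop("m must lie in [0, 1]")
  invisible(p)
}

#' Input drive of an accumulator from its option's values
#'
#' `I = b * (m * v_max + (1 - m) * v_min)`: a weighted combination of the
#' option's higher- and lower-valued fractal scaled by the total drive.
#'
#' @param b total input drive (>= 0).
#' @param m max/min drive ratio in \[0, 1\].
#' @param v_max,v_min the option's higher and lower fractal values (euros).
#' @return drive (vectorised over values).
#' @export
input_drive <- function(b, m, v_max, v_min) {
  stopifnot(m >= 0, m <= 1)
  b * (m * v_max + (1 - m) * v_min)
}

#' Simulate single LCA trials
#'
#' Two rectified accumulators race to a shared linearly collapsing bound
#' `B(t) = max(0, a0 - c t)`; unit 1 receives the correct option's drive
#' (accuracy coding). Activations update by Euler steps with leak, cross
#' inhibition and pre-rectification Gaussian noise, and are floored at 0.
#' If the bound floor is reached before any crossing, the unit with the
#' larger activation wins at that moment (tie: fair coin). No crossing
#' before `deadline - t0` is an omission.
#'
#' @param params LCA parameter list (see [default_lca_params()]); set
#'   `printed_inhibition = TRUE` inside `params` to reproduce the
#'   self-inhibition variant in which unit 2's inhibition uses its own
#'   activation.
#' @param v_correct,v_incorrect numeric length-2 vectors `(v_max, v_min)`
#'   for the correct and incorrect option, or matrices/data.frames with one
#'   row per trial and columns `(v_max, v_min)`.
#' @param n number of trials when `v_correct` is a length-2 vector.
#' @param dt Euler step (s).
#' @param deadline response deadline (s).
#' @param seed optional integer seed.
#' @return data.frame with `winner` (1 = correct unit, 2 = incorrect unit,
#'   NA = omission) and `rt` (seconds, NA when omitted).
#' @export
simulate_lca_trial <- function(params, v_correct, v_incorrect, n = 1,
                               dt = 0.001, deadline = 0.75, seed = NULL) {
  .check_lca_params(params)
  if (dt <= 0) stop("dt must be positive")
  if (deadline <= params$t0) stop("deadline must exceed t0")
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(rep(x, each = n), nrow = n, ncol = 2)
    else as.matrix(x)
  }
  vc <- as_mat(v_correct); vi <- as_mat(v_incorrect)
  I1 <- input_drive(params$b, params$m, vc[, 1], vc[, 2])
  I2 <- input_drive(params$b, params$m, vi[, 1], vi[, 2])
  run <- function() lca_simulate_cpp(I1, I2, params$k, params$w, params$a0,
                                     params$c, params$sigma, params$t0,
                                     dt, deadline,
                                     isTRUE(params$printed_inhibition))
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  data.frame(winner = ifelse(res$winner == -1L, NA_integer_, res$winner),
             rt = res$rt)
}

#' Simulate an LCA dataset over a task design
#'
#' Runs `n_concat` independently seeded passes of the LCA over a design
#' (concatenating them into one table), each pass drawing fresh noise.
#' A single parameter record is applied to all subjects, or per-subject
#' records from [sample_subject_params()] can be supplied.
#'
#' @param params an LCA parameter list, or a subject-parameter list.
#' @param design design table from [build_design()].
#' @param dt Euler step (s).
#' @param deadline response deadline (s).
#' @param seed integer seed.
#' @param n_concat number of concatenated passes (>= 1).
#' @return trial table in the common schema (same columns as
#'   [generate_behavior()]), with a `pass` column identifying the pass.
#' @export
simulate_lca_dataset <- function(params, design, dt = 0.001, deadline = 0.75,
                                 seed, n_concat = 1) {
  if (n_concat < 1) stop("n_concat must be >= 1")
  parts <- lapply(seq_len(n_concat), function(i) {
    tab <- generate_behavior(design, subject_params = params,
                             model_name = "lca", deadline = deadline, dt = dt,
                             seed = as.integer(seed) + (i - 1L) * 10007L)
    tab$pass <- i
    tab
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
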