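#' Configuration of an adaptive 2-down/1-up staircase
#'
#' The staircase estimates the just-noticeable difference (JND) in log2
#' ripple velocity: the interval Delta (in log2 units) between two ripple
#' velocities that an observer can just discriminate. A 2-down/1-up rule
#' converges on the 70.7\%-correct point of the psychometric function
#' (Levitt 1971).
#'
#' The step schedule and stop rule default to 8 reversals with the
#' estimate taken from the last 6, and the step size halved after each of
#' the first 2 reversals.
#'
#' @param n_down consecutive correct responses required to decrease Delta.
#' @param n_up incorrect responses required to increase Delta.
#' @param initial_interval starting Delta (log2 units of ripple velocity).
#' @param initial_step starting step size (log2 units).
#' @param n_halvings number of early reversals after each of which the
#'   step is halved.
#' @param n_reversals total reversals before stopping.
#' @param n_estimate number of final reversals averaged for the estimate.
#' @param bounds allowed Delta range (log2 units), positive.
#' @param velocity_bounds ripple-velocity range (cycles/s) the staircase
#'   operates in (bookkeeping only; the task spans 3-48 cycles/s).
#' @param max_trials safety cap on trial count.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(n_down = 2, n_up = 1, initial_interval = 1,
                             initial_step = 0.25, n_halvings = 2,
                             n_reversals = 8, n_estimate = 6,
                             bounds = c(0.01, 2),
                             velocity_bounds = c(3, 48),
                             max_trials = 400) {
  stopifnot(n_down >= 1, n_up >= 1, initial_interval > 0, initial_step > 0,
            n_reversals >= n_estimate, all(bounds > 0), bounds[1] < bounds[2],
            all(velocity_bounds > 0))
  structure(list(n_down = n_down, n_up = n_up,
                 initial_interval = initial_interval,
                 initial_step = initial_step, n_halvings = n_halvings,
                 n_reversals = n_reversals, n_estimate = n_estimate,
                 bounds = bounds, velocity_bounds = velocity_bounds,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' Simulate an adaptive 2-down/1-up staircase
#'
#' Runs the staircase against a simulated observer: a function mapping the
#' current interval Delta (log2 ripple-velocity units) to the probability
#' of a correct response, with chance floor 0.5 (two-alternative task).
#' The JND estimate is the mean Delta at the last `n_estimate` reversals.
#'
#' @param config a [staircase_config()].
#' @param observer function `Delta -> P(correct)` with values in
#'   \[0.5, 1\].
#' @param seed integer seed for the observer's binary responses.
#' @return list with `estimate` (log2 units), `trace` (data.frame with
#'   columns delta, correct, reversal), `reversal_deltas`, and
#'   `at_bound_warning` (TRUE when Delta sat at the upper bound on more
#'   than half of the trials: the observer could not converge).
#' @export
simulate_staircase <- function(config, observer, seed = 1) {
  stopifnot(inherits(config, "staircase_config"), is.function(observer))
  set.seed(seed)
  delta <- config$initial_interval
  step <- config$initial_step
  n_correct_run <- 0L
  n_wrong_run <- 0L
  last_dir <- 0L   # -1 descending, +1 ascending
  reversals <- numeric(0)
  trace <- list()
  trial <- 0L
  while (length(reversals) < config$n_reversals &&
         trial < config$max_trials) {
    trial <- trial + 1L
    p <- observer(delta)
    if (!is.finite(p) || p < 0 || p > 1) stop("observer returned invalid probability")
    correct <- runif(1) < p
    move <- 0L
    if (correct) {
      n_correct_run <- n_correct_run + 1L
      n_wrong_run <- 0L
      if (n_correct_run >= config$n_down) {
        move <- -1L
        n_correct_run <- 0L
      }
    } else {
      n_wrong_run <- n_wrong_run + 1L
      n_correct_run <- 0L
      if (n_wrong_run >= config$n_up) {
        move <- +1L
        n_wrong_run <- 0L
      }
    }
    is_reversal <- FALSE
    if (move != 0L) {
      if (last_dir != 0L && move != last_dir) {
        is_reversal <- TRUE
        reversals <- c(reversals, delta)
        if (length(reversals) <= config$n_halvings) step <- step / 2
      }
      last_dir <- move
    }
    trace[[trial]] <- c(delta = delta, correct = as.numeric(correct),
                        reversal = as.numeric(is_reversal))
    if (move != 0L) {
      delta <- clip(delta + move * step, config$bounds[1], config$bounds[2])
    }
  }
  trace <- as.data.frame(do.call(rbind, trace))
  trace$correct <- trace$correct > 0
  trace$reversal <- trace$reversal > 0
  n_est <- min(config$n_estimate, length(reversals))
  estimate <- if (n_est > 0) {
    mean(utils::tail(reversals, n_est))
  } else {
    trace$delta[nrow(trace)]
  }
  at_bound <- mean(trace$delta >= config$bounds[2]) > 0.5
  list(estimate = estimate, trace = trace, reversal_deltas = reversals,
       at_bound_warning = at_bound)
}

#' Gaussian-psychometric observer for staircase simulations
#'
#' Returns an observer function with
#' `P(correct | Delta) = 0.5 + 0.5 * Phi((Delta - threshold) / slope)`:
#' a cumulative-normal psychometric function scaled to the 0.5 chance
#' floor of a two-alternative task.
#'
#' @param threshold Delta at which Phi crosses 0 (log2 units).
#' @param slope psychometric slope (log2 units).
#' @return function `Delta -> P(correct)`.
#' @export
gaussian_observer <- function(threshold, slope) {
  force(threshold); force(slope)
  function(delta) 0.5 + 0.5 * pnorm((delta - threshold) / slope)
}

#' Invert an observer to its p-percent-correct point
#'
#' Numerically finds the Delta at which the observer's probability of a
#' correct response equals `p`. Used as the independent oracle for
#' staircase convergence (a 2-down/1-up rule targets p = 0.707).
#'
#' @param observer function `Delta -> P(correct)`.
#' @param p target probability.
#' @param interval search interval for Delta.
#' @return Delta at the target point.
#' @export
observer_quantile <- function(observer, p = 2^-0.5,
                              interval = c(1e-6, 10)) {
  stats::uniroot(function(d) observer(d) - p, interval = interval,
                 tol = 1e-8)$root
}
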