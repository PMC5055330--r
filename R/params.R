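#' Simulation parameters for the BC-PF model and its baselines
#'
#' Bundles every model, schedule and tolerance parameter of a run.  The
#' coupled dynamics acts on a complete signed network of `N` agents whose
#' opinions live in `[0,1]^F`.  Each time step one triad (out of the
#' `N(N-1)(N-2)/6`) is drawn uniformly at random and revised; every
#' `opinion_update_period` steps one uniformly drawn agent additionally
#' revises its opinion by bounded-confidence averaging over its friends.
#'
#' @param N Number of agents (integer, at least 3).
#' @param F Number of opinion issues per agent (integer, at least 1).
#' @param p Probability in (0,1) that an unbalanced (-++) triad resolves by
#'   flipping its negative link to positive (the alternative, with
#'   probability `1-p`, breaks a friendship).  `p < 1/2` drives the network
#'   to a bipolar two-clique state, `p > 1/2` to the all-friends state;
#'   `p = 1/2` is the critical point with no guaranteed absorbing class.
#' @param epsilon Confidence level in `[0,1]`: an agent only averages over
#'   friends whose opinion distance is at most `epsilon`.
#' @param rho0 Probability in `[0,1]` that each link is initialized positive
#'   (independently per unordered pair).
#' @param metric Opinion-distance metric for `F > 1`: `"chebyshev"` (maximum
#'   per-issue difference, the model's native choice) or `"euclidean"`.
#'   For `F = 1` both coincide with the absolute difference.
#' @param flip_rule Which link of an unbalanced triad flips:
#'   `"preferential"` (BC-PF: smallest opinion distance becomes friendship,
#'   largest among positives becomes enmity), `"random"` (LTD: uniform), or
#'   `"constrained"` (CTD: random candidate, applied only if the global
#'   unbalanced-triad count does not increase).
#' @param opinion_update_period Steps between opinion revisions, `M`.
#'   Default `max(1, round((N-1)*(N-2)/6))`, so that on average all triads
#'   and all opinions are revised once per round of `N*M` steps.
#' @param max_rounds Cap on the number of rounds before a run is declared
#'   non-absorbed.
#' @param seed RNG seed (integer) making the whole run reproducible, or
#'   `NULL` to continue from the current RNG state.
#' @param tol_fixedpoint Opinion-convergence tolerance: a run is absorbed
#'   when the network is balanced and no agent moves more than this in one
#'   full revision sweep.
#' @param tol_cluster Opinion-equality tolerance used when counting distinct
#'   opinions and snapping converged opinions to their cluster mean.
#' @param schedule `"deterministic"` (opinion revision every `M`-th step) or
#'   `"stochastic"` (after each triad step, revise an opinion with
#'   probability `opinion_rate * 6/((N-1)(N-2))`).
#' @param opinion_rate Rate multiplier for the stochastic schedule; `2`
#'   doubles the average opinion-update speed.
#'
#' @return An object of class `bcpf_params` (a validated list).
#' @examples
#' bcpf_params(N = 40, p = 0.1, epsilon = 0.2, seed = 1)
#' @export
bcpf_params <- function(N = 40L, F = 1L, p = 0.1, epsilon = 0.2, rho0 = 0.5,
                        metric = c("chebyshev", "euclidean"),
                        flip_rule = c("preferential", "random", "constrained"),
                        opinion_update_period = NULL,
                        max_rounds = 1e6, seed = NULL,
                        tol_fixedpoint = 1e-10, tol_cluster = 1e-6,
                        schedule = c("deterministic", "stochastic"),
                        opinion_rate = 1) {
  metric <- match.arg(metric)
  flip_rule <- match.arg(flip_rule)
  schedule <- match.arg(schedule)

  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stop_if(!is.numeric(N) || length(N) != 1L || N != round(N) || N < 3,
          "`N` must be a single integer >= 3")
  stop_if(!is.numeric(F) || length(F) != 1L || F != round(F) || F < 1,
          "`F` must be a single integer >= 1")
  stop_if(!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1,
          "`p` must lie strictly between 0 and 1")
  stop_if(!is.numeric(epsilon) || length(epsilon) != 1L ||
            epsilon < 0 || epsilon > 1,
          "`epsilon` must lie in [0, 1]")
  stop_if(!is.numeric(rho0) || length(rho0) != 1L || rho0 < 0 || rho0 > 1,
          "`rho0` must lie in [0, 1]")
  stop_if(!is.numeric(max_rounds) || length(max_rounds) != 1L || max_rounds < 1,
          "`max_rounds` must be >= 1")
  stop_if(!is.numeric(tol_fixedpoint) || tol_fixedpoint <= 0,
          "`tol_fixedpoint` must be positive")
  stop_if(!is.numeric(tol_cluster) || tol_cluster <= 0,
          "`tol_cluster` must be positive")
  stop_if(!is.numeric(opinion_rate) || opinion_rate <= 0,
          "`opinion_rate` must be positive")
  if (!is.null(seed)) {
    stop_if(!is.numeric(seed) || length(seed) != 1L || seed != round(seed),
            "`seed` must be a single integer or NULL")
    seed <- as.integer(seed)
  }

  N <- as.integer(N)
  F <- as.integer(F)
  if (is.null(opinion_update_period)) {
    opinion_update_period <- default_opinion_period(N)
  }
  stop_if(!is.numeric(opinion_update_period) ||
            opinion_update_period != round(opinion_update_period) ||
            opinion_update_period < 1,
          "`opinion_update_period` must be a positive integer")

  if (p == 0.5) {
    message("p = 0.5 is the critical point: no absorbing class is guaranteed")
  }

  structure(
    list(N = N, F = F, p = p, epsilon = epsilon, rho0 = rho0,
         metric = metric, flip_rule = flip_rule,
         opinion_update_period = as.integer(opinion_update_period),
         max_rounds = max_rounds, seed = seed,
         tol_fixedpoint = tol_fixedpoint, tol_cluster = tol_cluster,
         schedule = schedule, opinion_rate = opinion_rate),
    class = "bcpf_params"
  )
}

#' Default opinion-update period
#'
#' One opinion revision every `(N-1)(N-2)/6` triad revisions, rounded to the
#' nearest integer (floor 1), so that a round of `N * M` steps revises, on
#' average, every triad and every opinion once.
#'
#' @param N Number of agents.
#' @return Integer period `M`.
#' @examples
#' default_opinion_period(40)  # 247
#' @export
default_opinion_period <- function(N) {
  max(1L, as.integer(round((N - 1) * (N - 2) / 6)))
}

#' Total number of triads in a complete network
#'
#' @param N Number of agents.
#' @return `N(N-1)(N-2)/6` as a double (exact for all practical `N`).
#' @export
n_triads <- function(N) N * (N - 1) * (N - 2) / 6

#' @export
print.bcpf_params <- function(x, ...) {
  cat("BC-PF simulation parameters\n")
  cat(sprintf("  agents N = %d, issues F = %d, metric = %s\n",
              x$N, x$F, x$metric))
  cat(sprintf("  p = %g, epsilon = %g, rho0 = %g, flip rule = %s\n",
              x$p, x$epsilon, x$rho0, x$flip_rule))
  cat(sprintf("  schedule = %s (M = %d, rate = %g), max_rounds = %g\n",
              x$schedule, x$opinion_update_period, x$opinion_rate,
              x$max_rounds))
  cat(sprintf("  tolerances: fixed point %g, opinion cluster %g\n",
              x$tol_fixedpoint, x$tol_cluster))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
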