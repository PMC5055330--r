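#' Bounded-confidence neighborhood of an agent
#'
#' The agents whose opinions influence agent `i`: `i` itself plus every
#' friend (`s_ij = +1`) whose opinion distance from `i` is at most
#' `epsilon`.  Enemies never influence an agent, whatever their distance.
#'
#' @param state A [bcpf_state()].
#' @param i Focal agent index.
#' @param epsilon Confidence level in `[0,1]`.
#' @param metric Opinion-distance metric.
#' @return List with `focal`, `members` (sorted indices, including `i`) and
#'   `size`.
#' @export
build_neighborhood <- function(state, i, epsilon,
                               metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(state, "bcpf_state"))
  N <- nrow(state$signs)
  if (i < 1 || i > N) stop("agent index out of range", call. = FALSE)
  d <- vapply(seq_len(N), function(j)
    opinion_distance(state$opinions, i, j, metric), 0.0)
  members <- sort(unique(c(as.integer(i),
                           which(state$signs[i, ] == 1L & d <= epsilon))))
  list(focal = i, members = members, size = length(members))
}

#' Revise one agent's opinion by bounded-confidence averaging
#'
#' Replaces `x_i`, issue by issue, with the arithmetic mean of the opinions
#' of its neighborhood (focal agent included).  The update is asynchronous:
#' it reads the current state and changes only row `i`.
#'
#' @inheritParams build_neighborhood
#' @param params A [bcpf_params()] (supplies `epsilon` and `metric`).
#' @return The updated state.
#' @export
revise_opinion <- function(state, i, params) {
  nb <- build_neighborhood(state, i, params$epsilon, params$metric)
  state$opinions[i, ] <- colMeans(state$opinions[nb$members, , drop = FALSE])
  state
}

#' Revise one triad (reference implementation)
#'
#' Balanced triads are never modified.  An unbalanced `(---)` triad flips
#' one link to friendship; an unbalanced `(-++)` triad flips its negative
#' link to friendship with probability `p`, otherwise it breaks one
#' friendship.  Which link is chosen depends on `params$flip_rule`:
#'
#' * `"preferential"` (BC-PF): the `(---)` link with the smallest opinion
#'   distance becomes friendship; the positive link with the largest
#'   distance is broken.  Distance ties are broken uniformly at random.
#' * `"random"` (LTD): uniform among the admissible links.
#' * `"constrained"` (CTD): the candidate is drawn as in LTD but applied
#'   only if the global unbalanced-triad count does not increase; otherwise
#'   the state is unchanged and the event is logged as rejected.
#'
#' This is the R reference implementation used for small systems and tests;
#' [run()] uses an equivalent compiled engine.
#'
#' @param state A [bcpf_state()].
#' @param triad Three distinct agent indices.
#' @param params A [bcpf_params()].
#' @return List with `state` (possibly updated) and `event` (`NULL` for
#'   balanced triads, else a list with `t`, `triad`, `pair`, `old_sign`,
#'   `new_sign`, `branch`, `applied`).
#' @export
revise_triad <- function(state, triad, params) {
  stopifnot(inherits(state, "bcpf_state"))
  triad <- validate_triad(triad, nrow(state$signs))
  pairs <- rbind(triad[c(1, 2)], triad[c(1, 3)], triad[c(2, 3)])
  sg <- apply(pairs, 1, function(pr) state$signs[pr[1], pr[2]])
  if (prod(sg) == 1L) return(list(state = state, event = NULL))

  dist_of <- function(q) opinion_distance(state$opinions, pairs[q, 1],
                                          pairs[q, 2], params$metric)
  pick_tie <- function(idx) if (length(idx) == 1L) idx else
    idx[floor(stats::runif(1) * length(idx)) + 1L]

  preferential <- params$flip_rule == "preferential"
  if (sum(sg == -1L) == 3L) {
    branch <- "all_negative_smallest"
    if (preferential) {
      d <- vapply(1:3, dist_of, 0.0)
      choice <- pick_tie(which(d == min(d)))
    } else {
      choice <- pick_tie(1:3)
    }
  } else if (stats::runif(1) < params$p) {
    branch <- "neg_to_pos_p"
    choice <- which(sg == -1L)
  } else {
    branch <- "pos_to_neg"
    pos <- which(sg == 1L)
    if (preferential) {
      d <- vapply(pos, dist_of, 0.0)
      choice <- pick_tie(pos[d == max(d)])
    } else {
      choice <- pick_tie(pos)
    }
  }

  i <- pairs[choice, 1]; j <- pairs[choice, 2]
  applied <- TRUE
  if (params$flip_rule == "constrained") {
    after <- flip_link(state, i, j)
    if (after$unbalanced > state$unbalanced) {
      applied <- FALSE
      branch <- "rejected"
    } else {
      state <- after
    }
  } else {
    state <- flip_link(state, i, j)
  }
  event <- list(t = state$t, triad = triad, pair = c(i, j),
                old_sign = if (applied) -state$signs[i, j] else
                  state$signs[i, j],
                new_sign = state$signs[i, j], branch = branch,
                applied = applied)
  list(state = state, event = event)
}

#' Advance the system by one time step (reference implementation)
#'
#' Selects one triad uniformly at random among all `N(N-1)(N-2)/6` and
#' revises it under the configured flip rule; whenever the step counter is
#' a multiple of `opinion_update_period`, one uniformly chosen agent
#' additionally revises its opinion.  A round is `N * M` steps.
#'
#' @param state A [bcpf_state()].
#' @param params A [bcpf_params()].
#' @return List with the updated `state` and the triad-revision `event`
#'   (`NULL` if the selected triad was balanced).
#' @export
step_state <- function(state, params) {
  N <- nrow(state$signs)
  state$t <- state$t + 1
  triad <- sample.int(N, 3L)
  out <- revise_triad(state, triad, params)
  state <- out$state
  if (state$t %% params$opinion_update_period == 0) {
    agent <- sample.int(N, 1L)
    state <- revise_opinion(state, agent, params)
  }
  list(state = state, event = out$event)
}

termination_labels <- c("absorbed", "max_rounds", "jammed", "opinion_cap")

#' Run the coupled dynamics to its absorbing state
#'
#' Iterates the interleaved schedule (one triad revision per step, one
#' opinion revision every `M` steps) until the network is balanced, then
#' continues revising one uniformly random agent's opinion per tick until
#' the fixed point: every `N` ticks a non-mutating check computes the
#' prospective change of each agent, and the run is absorbed when no agent
#' would move by `tol_fixedpoint` or more in a full revision sweep.
#' Network balance is absorbing: once every triad is balanced no link ever
#' flips again.  Runs that hit `max_rounds` before balance (or, for the
#' constrained rule, make no admissible flip for 50 consecutive rounds) are
#' returned flagged as non-absorbed, not as errors.
#'
#' On absorption, opinions within `tol_cluster` of each other are snapped
#' to their cluster mean for reporting (`opinions`); the unsnapped values
#' are kept in `opinions_raw`.
#'
#' @param params A [bcpf_params()]; `params$seed` (if non-`NULL`) makes the
#'   run fully reproducible.
#' @param state Optional initial [bcpf_state()] (e.g. from
#'   [read_state_csv()]); by default one is drawn by [init_random_state()].
#' @param record_series Record per-round observables (`F_unbal`, `D_plus`,
#'   `D_minus`, `N_op`)?  Disable for large ensembles.
#' @param record_flips Keep the full flip-event log?
#' @param max_sweeps Cap on post-balance `N`-tick opinion blocks.
#' @return An object of class `bcpf_run`; see Details.
#' @details The result contains: `t_balance` (steps to network balance, `NA`
#'   if not reached) and `rounds_balance`; `sweeps` (post-balance `N`-tick
#'   opinion blocks); `termination` (one of `"absorbed"`, `"max_rounds"`,
#'   `"jammed"`, `"opinion_cap"`) and `absorbed`; final `signs`,
#'   `opinions` (snapped), `opinions_raw`, and `opinions_near_absorption`
#'   (the state one sweep before per-sweep opinion motion first fell below
#'   `1e-6`, useful for studying near-absorption cluster geometry);
#'   `partition` (clique bipartition, `NULL` if unbalanced), `clique_sizes`,
#'   `S_dif`, `N_op`, `clusters`, `D_plus`, `D_minus`; the per-round
#'   `series` data frame; and `flip_counts` by rule branch.
#' @examples
#' res <- run(bcpf_params(N = 20, p = 0.1, epsilon = 0.2, seed = 42))
#' res$N_op
#' @export
run <- function(params, state = NULL, record_series = TRUE,
                record_flips = FALSE, max_sweeps = 1e5) {
  stopifnot(inherits(params, "bcpf_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(state)) state <- init_random_state(params)
  stopifnot(inherits(state, "bcpf_state"))
  if (nrow(state$signs) != params$N || ncol(state$opinions) != params$F)
    stop("initial state dimensions do not match `params`", call. = FALSE)
  engine_dispatch(params, state, network_frozen = FALSE,
                  record_series = record_series,
                  record_flips = record_flips, max_sweeps = max_sweeps)
}

#' Run the pure bounded-confidence baseline
#'
#' The network is fixed all-positive and never revised; only asynchronous
#' opinion revisions occur (one uniformly random agent per tick) until the
#' fixed point.  This is the classical Hegselmann-Krause dynamics on the complete
#' friendship graph and serves as the reference against which the coupled
#' model's consensus threshold is compared.
#'
#' @inheritParams run
#' @param opinions Optional `N x F` initial opinion matrix; by default
#'   drawn i.i.d. uniform.
#' @return A `bcpf_run` object (network trivially balanced, one clique).
#' @export
run_bc_baseline <- function(params, opinions = NULL, record_series = TRUE,
                            max_sweeps = 1e5) {
  stopifnot(inherits(params, "bcpf_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- params$N
  signs <- matrix(1L, N, N); diag(signs) <- 0L
  if (is.null(opinions))
    opinions <- matrix(stats::runif(N * params$F), nrow = N)
  state <- bcpf_state(signs, opinions)
  engine_dispatch(params, state, network_frozen = TRUE,
                  record_series = record_series, record_flips = FALSE,
                  max_sweeps = max_sweeps)
}

engine_dispatch <- function(params, state, network_frozen, record_series,
                            record_flips, max_sweeps) {
  eng <- engine_run(
    state$signs, state$opinions,
    p = params$p, eps = params$epsilon,
    metric = match(params$metric, c("chebyshev", "euclidean")) - 1L,
    flip_rule = match(params$flip_rule,
                      c("preferential", "random", "constrained")) - 1L,
    M = params$opinion_update_period, max_rounds = params$max_rounds,
    tol_fix = params$tol_fixedpoint, tol_cluster = params$tol_cluster,
    network_frozen = network_frozen, record_series = record_series,
    record_flips = record_flips,
    stochastic = params$schedule == "stochastic",
    opinion_rate = params$opinion_rate,
    jam_rounds = 50L, max_sweeps = max_sweeps, snapshot_tol = 1e-6)

  absorbed <- eng$termination == 0L
  opinions_raw <- eng$opinions
  opinions <- opinions_raw
  clusters <- opinion_clusters(opinions_raw, params$tol_cluster,
                               params$metric)
  if (absorbed) {
    for (cl in clusters) {
      opinions[cl, ] <- matrix(colMeans(opinions_raw[cl, , drop = FALSE]),
                               nrow = length(cl), ncol = params$F,
                               byrow = TRUE)
    }
  }

  balanced <- eng$unbalanced == 0
  partition <- if (balanced) extract_cliques(eng$signs) else NULL
  div <- diversity_measures_xs(eng$signs, opinions, params$metric)

  res <- list(
    params = params,
    seed = params$seed,
    t = eng$t,
    t_balance = eng$t_balance,
    rounds_balance = eng$t_balance /
      (params$N * params$opinion_update_period),
    rounds = eng$rounds,
    sweeps = eng$sweeps,
    termination = termination_labels[eng$termination + 1L],
    absorbed = absorbed,
    signs = eng$signs,
    opinions = opinions,
    opinions_raw = opinions_raw,
    opinions_near_absorption =
      if (eng$snapshot_taken) eng$opinions_near_absorption else NULL,
    unbalanced_final = eng$unbalanced,
    partition = partition,
    clique_sizes = if (balanced) lengths(partition) else NULL,
    S_dif = if (balanced) clique_size_difference(partition) else NA_real_,
    N_op = length(clusters),
    clusters = clusters,
    D_plus = div$D_plus,
    D_minus = div$D_minus,
    flip_counts = eng$flip_counts,
    series = as.data.frame(eng$series),
    flip_log = if (record_flips) as.data.frame(eng$flip_log) else NULL
  )
  class(res) <- "bcpf_run"
  res
}

#' @export
print.bcpf_run <- function(x, ...) {
  cat("BC-PF run\n")
  cat(sprintf("  termination: %s after %g steps (%.2f rounds) + %g sweeps\n",
              x$termination, x$t, x$rounds + 0, x$sweeps))
  if (!is.na(x$t_balance))
    cat(sprintf("  network balanced at step %g (%.2f rounds)\n",
                x$t_balance, x$rounds_balance))
  if (!is.null(x$clique_sizes))
    cat(sprintf("  cliques: %s (S_dif = %.1f)\n",
                paste(x$clique_sizes, collapse = " / "), x$S_dif))
  cat(sprintf("  N_op = %d distinct opinion(s); D+ = %s, D- = %s\n",
              x$N_op,
              formatC(x$D_plus, digits = 4),
              formatC(x$D_minus, digits = 4)))
  invisible(x)
}
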