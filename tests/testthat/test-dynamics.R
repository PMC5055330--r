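make_state <- function(signs, opinions) bcpf_state(signs, opinions)

test_that("neighborhoods contain the focal agent and confidence-close friends only", {
  s <- bipolar_signs(rep(1, 4))
  # agent 1 at 0.5; friends at 0.4 and 0.9; enemy at 0.5 exactly
  s[1, 4] <- s[4, 1] <- -1L
  st <- make_state(s, c(0.5, 0.4, 0.9, 0.5))
  nb <- build_neighborhood(st, 1, epsilon = 0.2)
  expect_setequal(nb$members, c(1, 2))  # enemy excluded despite distance 0
  expect_identical(nb$size, 2L)

  # epsilon = 0 with distinct opinions leaves the agent alone
  st2 <- make_state(bipolar_signs(rep(1, 5)), c(0.1, 0.3, 0.5, 0.7, 0.9))
  nb2 <- build_neighborhood(st2, 3, epsilon = 0)
  expect_identical(nb2$members, 3L)

  # epsilon = 1 with all links positive collects everyone
  nb3 <- build_neighborhood(st2, 2, epsilon = 1)
  expect_identical(nb3$members, 1:5)
})

test_that("opinion revision averages the neighborhood and fixes consensus", {
  pars <- bcpf_params(N = 4, epsilon = 0.2)
  s <- bipolar_signs(rep(1, 4))
  st <- make_state(s, c(0.5, 0.4, 0.9, 0.95))
  st2 <- revise_opinion(st, 1, pars)
  expect_equal(st2$opinions[1, 1], 0.45)          # mean of {0.5, 0.4}
  expect_equal(st2$opinions[-1, 1], st$opinions[-1, 1])  # others untouched

  # eta = 1: no change
  st3 <- revise_opinion(make_state(s, c(0.1, 0.5, 0.9, 0.7)), 1,
                        bcpf_params(N = 4, epsilon = 0.05))
  expect_identical(st3$opinions[1, 1], 0.1)

  # consensus is a fixed point
  stc <- make_state(s, rep(0.3, 4))
  expect_equal(revise_opinion(stc, 2, bcpf_params(N = 4, epsilon = 1))$
                 opinions[2, 1], 0.3)
})

test_that("preferential flips select links by opinion distance", {
  # (-++) triad, 1-p branch: the most distant friendship breaks
  s <- matrix(0L, 3, 3)
  s[1, 2] <- s[2, 1] <- -1L
  s[1, 3] <- s[3, 1] <- 1L   # distance 0.8
  s[2, 3] <- s[3, 2] <- 1L   # distance 0.7
  st <- make_state(s, c(0.1, 0.2, 0.9))
  pars <- bcpf_params(N = 3, p = 1e-12)  # forces the 1-p branch
  out <- revise_triad(st, c(1, 2, 3), pars)
  expect_identical(out$event$pair, c(1L, 3L))
  expect_identical(out$event$new_sign, -1L)
  expect_identical(out$event$branch, "pos_to_neg")
  expect_identical(out$state$unbalanced, 0L)

  # p branch: the negative link becomes friendship
  pars_hi <- bcpf_params(N = 3, p = 1 - 1e-12)
  out2 <- revise_triad(st, c(1, 2, 3), pars_hi)
  expect_identical(out2$event$pair, c(1L, 2L))
  expect_identical(out2$event$new_sign, 1L)

  # (---) triad: the closest pair becomes friends
  sm <- matrix(0L, 3, 3); sm[upper.tri(sm)] <- -1L; sm <- sm + t(sm)
  stm <- make_state(sm, c(0.5, 0.6, 0.1))  # pair distances .1, .4, .5
  out3 <- revise_triad(stm, c(1, 2, 3), bcpf_params(N = 3, p = 0.3))
  expect_identical(out3$event$pair, c(1L, 2L))
  expect_identical(out3$event$new_sign, 1L)
  expect_identical(out3$event$branch, "all_negative_smallest")

  # balanced triads are never modified
  sb <- matrix(0L, 3, 3)
  sb[1, 2] <- sb[2, 1] <- 1L; sb[1, 3] <- sb[3, 1] <- -1L
  sb[2, 3] <- sb[3, 2] <- -1L
  outb <- revise_triad(make_state(sb, runif(3)), c(1, 2, 3),
                       bcpf_params(N = 3))
  expect_null(outb$event)
  expect_identical(outb$state$signs, sb)
})

test_that("every applied flip leaves the revised triad balanced", {
  set.seed(31)
  for (rule in c("preferential", "random", "constrained")) {
    pars <- bcpf_params(N = 8, p = 0.3, flip_rule = rule)
    st <- init_random_state(pars)
    for (k in 1:50) {
      tr <- sort(sample(8, 3))
      out <- revise_triad(st, tr, pars)
      st <- out$state
      if (!is.null(out$event) && out$event$applied) {
        expect_true(attr(triad_type(st, tr), "balanced"))
      }
      expect_identical(st$unbalanced, oracle_unbalanced(st$signs))
    }
  }
})

test_that("random (LTD) flips are uniform over admissible links", {
  sm <- matrix(0L, 3, 3); sm[upper.tri(sm)] <- -1L; sm <- sm + t(sm)
  stm <- make_state(sm, c(0.1, 0.5, 0.9))
  pars <- bcpf_params(N = 3, p = 0.3, flip_rule = "random")
  n <- 6000
  set.seed(41)
  picks <- replicate(n, paste(revise_triad(stm, 1:3, pars)$event$pair,
                              collapse = "-"))
  freq <- table(picks) / n
  # three pairs, each ~1/3 within 3 sigma
  sd3 <- 3 * sqrt((1 / 3) * (2 / 3) / n)
  expect_length(freq, 3)
  expect_true(all(abs(freq - 1 / 3) < sd3))

  # (-++), 1-p branch: each positive link breaks with probability 1/2
  s <- matrix(0L, 3, 3)
  s[1, 2] <- s[2, 1] <- -1L; s[1, 3] <- s[3, 1] <- 1L; s[2, 3] <- s[3, 2] <- 1L
  stp <- make_state(s, c(0.1, 0.2, 0.9))
  parsp <- bcpf_params(N = 3, p = 1e-12, flip_rule = "random")
  set.seed(43)
  picks2 <- replicate(n, paste(revise_triad(stp, 1:3, parsp)$event$pair,
                               collapse = "-"))
  freq2 <- table(picks2) / n
  sd2 <- 3 * sqrt(0.25 / n)
  expect_length(freq2, 2)
  expect_true(all(abs(freq2 - 0.5) < sd2))
})

test_that("constrained (CTD) flips respect the global unbalanced count", {
  # N = 3: the only triad always balances itself, so flips always apply
  sm <- matrix(0L, 3, 3); sm[upper.tri(sm)] <- -1L; sm <- sm + t(sm)
  pars3 <- bcpf_params(N = 3, p = 0.3, flip_rule = "constrained")
  out <- revise_triad(make_state(sm, runif(3)), 1:3, pars3)
  expect_true(out$event$applied)
  expect_identical(out$state$unbalanced, 0L)

  # search a 6-agent instance where both 1-p candidates of a (-++) triad
  # would increase the count: the constrained rule must always reject
  set.seed(51)
  found <- FALSE
  pars6 <- bcpf_params(N = 6, p = 1e-12, flip_rule = "constrained")
  for (try in 1:2000) {
    signs <- random_signs(6)
    tr <- sort(sample(6, 3))
    sg <- c(signs[tr[1], tr[2]], signs[tr[1], tr[3]], signs[tr[2], tr[3]])
    if (sum(sg == -1L) != 1L) next
    st <- make_state(signs, runif(6))
    pairs <- rbind(tr[c(1, 2)], tr[c(1, 3)], tr[c(2, 3)])
    deltas <- sapply(which(sg == 1L), function(q) {
      oracle_unbalanced(flip_link(st, pairs[q, 1], pairs[q, 2])$signs) -
        st$unbalanced
    })
    if (all(deltas > 0)) { found <- TRUE; break }
  }
  expect_true(found)
  for (rep in 1:10) {
    out <- revise_triad(st, tr, pars6)
    expect_false(out$event$applied)
    expect_identical(out$event$branch, "rejected")
    expect_identical(out$state$signs, st$signs)
    expect_identical(out$state$unbalanced, st$unbalanced)
  }

  # property over random states: applied flips never increase the count
  set.seed(52)
  pars <- bcpf_params(N = 7, p = 0.3, flip_rule = "constrained")
  saw_rejection <- FALSE
  for (rep in 1:200) {
    st <- init_random_state(pars)
    u0 <- st$unbalanced
    out <- revise_triad(st, sort(sample(7, 3)), pars)
    if (is.null(out$event)) next
    if (out$event$applied) {
      expect_lte(out$state$unbalanced, u0)
    } else {
      saw_rejection <- TRUE
      expect_identical(out$state$unbalanced, u0)
    }
  }
  expect_true(saw_rejection)
})

test_that("the step schedule interleaves triad and opinion revisions", {
  pars <- bcpf_params(N = 6, p = 0.3, epsilon = 1, seed = 3)
  expect_identical(pars$opinion_update_period, 3L)
  set.seed(3)
  st <- init_random_state(pars)
  for (k in 1:30) {
    st_prev <- st
    out <- step_state(st, pars)
    st <- out$state
    expect_identical(st$t, st_prev$t + 1)
    expect_identical(st$unbalanced, oracle_unbalanced(st$signs))
    if (st$t %% pars$opinion_update_period != 0) {
      # opinions may only change on scheduled steps
      expect_identical(st$opinions, st_prev$opinions)
    }
  }
  expect_true(all(st$opinions >= 0 & st$opinions <= 1))
})

test_that("runs are bit-reproducible from the seed", {
  pars <- bcpf_params(N = 15, p = 0.2, epsilon = 0.3, seed = 99,
                      max_rounds = 20000)
  r1 <- run(pars, record_flips = TRUE)
  r2 <- run(pars, record_flips = TRUE)
  expect_identical(r1$signs, r2$signs)
  expect_identical(r1$opinions, r2$opinions)
  expect_identical(r1$t_balance, r2$t_balance)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$flip_log, r2$flip_log)
})

test_that("network balance is absorbing and opinions stay in [0,1]", {
  n_absorbed <- 0
  for (seed in 1:6) {
    res <- run(bcpf_params(N = 12, p = 0.2, epsilon = 0.25, seed = seed,
                           max_rounds = 20000), record_flips = TRUE)
    expect_true(all(res$opinions_raw >= 0 & res$opinions_raw <= 1))
    expect_true(all(res$opinions >= 0 & res$opinions <= 1))
    if (!res$absorbed) next  # heavy-tailed balance times
    n_absorbed <- n_absorbed + 1
    expect_identical(res$unbalanced_final, 0)
    expect_identical(count_unbalanced_triads(res$signs), 0L)
    # no flip event after the balance time
    if (nrow(res$flip_log) > 0)
      expect_lte(max(res$flip_log$t), res$t_balance)
  }
  expect_gte(n_absorbed, 4)
})

test_that("epsilon = 0 leaves every opinion bit-identical", {
  pars <- bcpf_params(N = 12, p = 0.2, epsilon = 0, seed = 17,
                      max_rounds = 20000)
  set.seed(17)
  x0 <- init_random_state(pars)$opinions  # same draw sequence as run()
  res <- run(pars)
  expect_identical(res$opinions_raw, x0)
})

test_that("p > 1/2 drives the network to the all-friends configuration", {
  for (seed in 1:10) {
    res <- run(bcpf_params(N = 16, p = 0.9, epsilon = 0.2, seed = seed,
                           max_rounds = 5000), record_series = FALSE)
    expect_true(res$absorbed)
    expect_length(res$partition$C2, 0)
    expect_true(all(res$signs[upper.tri(res$signs)] == 1L))
  }
})

test_that("LTD absorbing states split by p as in the random-flip model", {
  # smoke test of the Antal classification at small N
  n_lo <- 0; n_hi <- 0
  for (seed in 1:5) {
    lo <- run(bcpf_params(N = 10, p = 0.1, epsilon = 0.2, seed = seed,
                          flip_rule = "random", max_rounds = 5e4),
              record_series = FALSE)
    if (lo$absorbed) {
      n_lo <- n_lo + 1
      expect_gt(length(lo$partition$C2), 0)  # bipolar
    }
    hi <- run(bcpf_params(N = 10, p = 0.9, epsilon = 0.2, seed = seed,
                          flip_rule = "random", max_rounds = 5e4),
              record_series = FALSE)
    if (hi$absorbed) {
      n_hi <- n_hi + 1
      expect_length(hi$partition$C2, 0)      # all friends
    }
  }
  expect_gte(n_lo, 4); expect_gte(n_hi, 4)
})

test_that("a run hitting the round cap is flagged, not an error", {
  res <- run(bcpf_params(N = 20, p = 0.1, epsilon = 0.05, seed = 1,
                         max_rounds = 3), record_series = FALSE)
  expect_false(res$absorbed)
  expect_identical(res$termination, "max_rounds")
  expect_true(is.na(res$t_balance))
})

test_that("final opinion clusters within a clique are separated by more than epsilon", {
  n_checked <- 0
  for (seed in 1:8) {
    res <- run(bcpf_params(N = 30, p = 0.1, epsilon = 0.1, seed = seed,
                           max_rounds = 3000), record_series = FALSE)
    if (!res$absorbed) next
    n_checked <- n_checked + 1
    cl <- count_opinions(res, tol_cluster = 1e-6)
    for (part in res$partition) {
      idx <- which(vapply(cl$clusters, function(g) any(g %in% part), TRUE))
      if (length(idx) < 2) next
      cent <- cl$centroids[idx, , drop = FALSE]
      gaps <- as.vector(dist(cent, method = "maximum"))
      expect_true(all(gaps > res$params$epsilon))
    }
  }
  expect_gte(n_checked, 2)
})

test_that("the bounded-confidence baseline matches its known regimes", {
  # epsilon = 1: global averaging contracts to consensus
  r1 <- run_bc_baseline(bcpf_params(N = 20, epsilon = 1, seed = 5))
  expect_identical(r1$N_op, 1L)

  # epsilon = 0: nothing can move, one opinion per distinct initial value
  r0 <- run_bc_baseline(bcpf_params(N = 20, epsilon = 0, seed = 5))
  expect_identical(r0$N_op, 20L)
  set.seed(5)
  signs_draw <- NULL  # baseline draws opinions directly
  x0 <- matrix(runif(20), ncol = 1)
  expect_identical(r0$opinions_raw, x0)

  # small epsilon: several final opinions with pairwise gaps > epsilon
  rs <- run_bc_baseline(bcpf_params(N = 40, epsilon = 0.05, seed = 7))
  expect_gt(rs$N_op, 1L)
  cents <- sort(count_opinions(rs)$centroids[, 1])
  expect_true(all(diff(cents) > 0.05))
})

test_that("the stochastic schedule reproduces the dynamics' character", {
  n_absorbed <- 0
  for (seed in 1:6) {
    res <- run(bcpf_params(N = 20, p = 0.1, epsilon = 0.2, seed = seed,
                           schedule = "stochastic", opinion_rate = 2,
                           max_rounds = 3000), record_series = FALSE)
    if (!res$absorbed) next
    n_absorbed <- n_absorbed + 1
    expect_gt(length(res$partition$C2), 0)  # bipolar for p < 1/2
    expect_lte(res$N_op, 4L)
    expect_true(all(res$opinions >= 0 & res$opinions <= 1))
  }
  expect_gte(n_absorbed, 2)
})
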