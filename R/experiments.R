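#' Run one model variant
#'
#' Dispatches on the model label used throughout the ensemble tools:
#' `"bcpf"` (preferential flip), `"ltd"` (random flip), `"ctd"`
#' (constrained random flip) and `"bc"` (pure bounded confidence on a fixed
#' all-friends network).
#'
#' @param params A [bcpf_params()]; its `flip_rule` is overridden by the
#'   model label where applicable.
#' @param model One of `"bcpf"`, `"ltd"`, `"ctd"`, `"bc"`.
#' @param ... Passed to [run()] / [run_bc_baseline()].
#' @return A `bcpf_run`.
#' @export
run_model <- function(params, model = c("bcpf", "ltd", "ctd", "bc"), ...) {
  model <- match.arg(model)
  if (model == "bc") return(run_bc_baseline(params, ...))
  rule <- c(bcpf = "preferential", ltd = "random", ctd = "constrained")[model]
  if (params$flip_rule != rule) {
    params$flip_rule <- unname(rule)
  }
  run(params, ...)
}

#' Specify a parameter sweep
#'
#' @param params Base [bcpf_params()].
#' @param grid Named list of value vectors for the swept parameter(s)
#'   (crossed with `expand.grid`); may be empty for a single cell.
#' @param runs Runs per grid cell (>= 1).
#' @param base_seed Base RNG seed; the run with index `r` (1-based) in cell
#'   `c` uses seed `base_seed + (c-1)*runs + (r-1)`, unique per (cell, run).
#' @param model Model label, see [run_model()].
#' @return An object of class `bcpf_sweep_spec`.
#' @export
sweep_spec <- function(params, grid = list(), runs = 8L, base_seed = 1L,
                       model = c("bcpf", "ltd", "ctd", "bc")) {
  model <- match.arg(model)
  stopifnot(inherits(params, "bcpf_params"), runs >= 1)
  if (length(grid) > 0) {
    if (is.null(names(grid)) || any(names(grid) == ""))
      stop("`grid` must be a named list", call. = FALSE)
    if (any(lengths(grid) == 0)) stop("grids must be non-empty", call. = FALSE)
    if (!all(names(grid) %in% names(params)))
      stop("unknown parameter in `grid`: ",
           paste(setdiff(names(grid), names(params)), collapse = ", "),
           call. = FALSE)
  }
  structure(list(params = params, grid = grid, runs = as.integer(runs),
                 base_seed = as.integer(base_seed), model = model),
            class = "bcpf_sweep_spec")
}

cell_params <- function(spec, cell_values) {
  p <- spec$params
  for (nm in names(cell_values)) p[[nm]] <- cell_values[[nm]]
  # when N is swept and M was left at its default, recompute the default
  if ("N" %in% names(cell_values) &&
      p$opinion_update_period == default_opinion_period(spec$params$N)) {
    p$opinion_update_period <- NULL
  }
  # revalidate through the constructor
  do.call(bcpf_params, p[setdiff(names(p), "seed")])
}

run_record <- function(res, cell_id, run_id, seed) {
  bipolar <- !is.null(res$partition) && length(res$partition$C2) > 0
  all_friends <- !is.null(res$partition) && length(res$partition$C2) == 0
  segregated <- NA
  separable <- NA
  lower_op <- NA_real_; upper_op <- NA_real_
  if (res$absorbed && bipolar) {
    if (res$params$F == 1L) {
      segregated <- check_segregation_1d(res, res$partition)
      m1 <- mean(res$opinions[res$partition$C1, 1])
      m2 <- mean(res$opinions[res$partition$C2, 1])
      lower_op <- min(m1, m2); upper_op <- max(m1, m2)
    } else {
      separable <- check_hyperplane_separation(res, res$partition)
    }
  }
  data.frame(
    cell = cell_id, run = run_id, seed = seed,
    absorbed = res$absorbed, termination = res$termination,
    t_balance = res$t_balance, rounds_balance = res$rounds_balance,
    sweeps = res$sweeps, N_op = res$N_op,
    D_plus = res$D_plus, D_minus = res$D_minus,
    S_dif = res$S_dif, bipolar = bipolar, all_friends = all_friends,
    segregated = segregated, separable = separable,
    lower_clique_opinion = lower_op, upper_clique_opinion = upper_op,
    stringsAsFactors = FALSE)
}

#' Run an ensemble over a parameter sweep
#'
#' Executes `runs` seeded runs per grid cell and aggregates per-cell
#' statistics.  Medians and means of absorbing-state quantities are
#' computed over absorbed runs only; the absorbed fraction is reported
#' alongside.  The whole output is a pure function of the spec.
#'
#' @param spec A [sweep_spec()].
#' @param out Optional path for the tidy per-cell summary CSV.
#' @param runs_out Optional path for the per-run JSON-lines file.
#' @param quiet Suppress progress messages?
#' @return An object of class `bcpf_ensemble`: list with `summary` (one row
#'   per cell), `runs` (one row per run) and the `spec`.
#' @export
run_ensemble <- function(spec, out = NULL, runs_out = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "bcpf_sweep_spec"))
  cells <- if (length(spec$grid) > 0) expand.grid(spec$grid) else
    data.frame(.cell = 1)
  n_cells <- nrow(cells)
  rec_list <- vector("list", n_cells * spec$runs)
  sum_list <- vector("list", n_cells)

  for (ci in seq_len(n_cells)) {
    vals <- if (length(spec$grid) > 0)
      as.list(cells[ci, , drop = FALSE]) else list()
    pars <- cell_params(spec, vals)
    if (!quiet)
      message(sprintf("cell %d/%d: %s", ci, n_cells,
                      paste(names(vals), unlist(vals), sep = "=",
                            collapse = ", ")))
    recs <- vector("list", spec$runs)
    for (ri in seq_len(spec$runs)) {
      seed <- spec$base_seed + (ci - 1L) * spec$runs + (ri - 1L)
      pars$seed <- as.integer(seed)
      res <- run_model(pars, spec$model, record_series = FALSE)
      recs[[ri]] <- run_record(res, ci, ri, seed)
    }
    recs <- do.call(rbind, recs)
    rec_list[[ci]] <- recs
    ab <- recs[recs$absorbed, , drop = FALSE]
    srow <- data.frame(
      cell = ci,
      n_runs = spec$runs, n_absorbed = nrow(ab),
      frac_absorbed = nrow(ab) / spec$runs,
      T_typ_steps = if (nrow(ab) > 0) stats::median(ab$t_balance) else NA,
      T_typ_rounds = if (nrow(ab) > 0) stats::median(ab$rounds_balance)
                     else NA,
      N_op_mean = if (nrow(ab) > 0) mean(ab$N_op) else NA,
      N_op_min = if (nrow(ab) > 0) min(ab$N_op) else NA,
      N_op_max = if (nrow(ab) > 0) max(ab$N_op) else NA,
      D_plus_mean = if (nrow(ab) > 0) mean(ab$D_plus, na.rm = TRUE) else NA,
      D_minus_mean = if (nrow(ab) > 0) mean(ab$D_minus, na.rm = TRUE)
                     else NA,
      S_dif_mean = if (nrow(ab) > 0) mean(ab$S_dif, na.rm = TRUE) else NA,
      lower_clique_opinion_mean =
        if (any(!is.na(ab$lower_clique_opinion)))
          mean(ab$lower_clique_opinion, na.rm = TRUE) else NA,
      upper_clique_opinion_mean =
        if (any(!is.na(ab$upper_clique_opinion)))
          mean(ab$upper_clique_opinion, na.rm = TRUE) else NA,
      frac_bipolar = if (nrow(ab) > 0) mean(ab$bipolar) else NA,
      frac_all_friends = if (nrow(ab) > 0) mean(ab$all_friends) else NA,
      frac_segregated = if (any(!is.na(ab$segregated)))
        mean(ab$segregated, na.rm = TRUE) else NA,
      frac_separable = if (any(!is.na(ab$separable)))
        mean(ab$separable, na.rm = TRUE) else NA)
    if (length(spec$grid) > 0)
      srow <- cbind(cells[ci, , drop = FALSE], srow, row.names = NULL)
    sum_list[[ci]] <- srow
  }

  runs_df <- do.call(rbind, rec_list)
  if (length(spec$grid) > 0) {
    key <- cells[runs_df$cell, , drop = FALSE]
    row.names(key) <- NULL
    runs_df <- cbind(key, runs_df, row.names = NULL)
  }
  summary_df <- do.call(rbind, sum_list)
  if (!is.null(out))
    utils::write.csv(summary_df, out, row.names = FALSE)
  if (!is.null(runs_out)) {
    con <- file(runs_out, "w")
    on.exit(close(con))
    for (r in seq_len(nrow(runs_df)))
      writeLines(jsonlite::toJSON(as.list(runs_df[r, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
  }
  structure(list(summary = summary_df, runs = runs_df, spec = spec),
            class = "bcpf_ensemble")
}

#' @export
print.bcpf_ensemble <- function(x, ...) {
  cat(sprintf("BC-PF ensemble: %d cell(s) x %d run(s), model %s\n",
              nrow(x$summary), x$spec$runs, x$spec$model))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Histogram of clique-size differences
#'
#' @param s_dif Vector of `S_dif` values in `[0, 100]`.
#' @param bin_width Bin width in percent points (default 2).
#' @return Data frame with `bin_lo`, `bin_hi`, `count`, `freq`.
#' @export
s_dif_histogram <- function(s_dif, bin_width = 2) {
  s_dif <- s_dif[!is.na(s_dif)]
  breaks <- seq(0, 100 + bin_width, by = bin_width)
  cnt <- table(cut(s_dif, breaks, right = FALSE, include.lowest = TRUE))
  data.frame(bin_lo = utils::head(breaks, -1),
             bin_hi = utils::head(breaks, -1) + bin_width,
             count = as.integer(cnt),
             freq = as.integer(cnt) / max(1L, length(s_dif)))
}

#' Typical (median) time to reach social balance
#'
#' Runs `n_runs` seeded replicates and reports the median number of time
#' steps (and rounds) at which the network first became balanced, over
#' absorbed runs.  If fewer than half the runs absorbed the median is
#' undefined and reported as `NA` with `status = "undefined"`.
#'
#' @param params A [bcpf_params()].
#' @param n_runs Number of replicate runs.
#' @param model Model label, see [run_model()].
#' @param base_seed Seed of the first replicate (replicate `r` uses
#'   `base_seed + r - 1`); defaults to `params$seed` or 1.
#' @return List with `T_typ_steps`, `T_typ_rounds`, `n_absorbed`, `n_runs`,
#'   `status` and the per-run `t_balance` vector.
#' @export
estimate_Ttyp <- function(params, n_runs = 50L,
                          model = c("bcpf", "ltd", "ctd"),
                          base_seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_runs >= 1)
  if (is.null(base_seed)) base_seed <- if (!is.null(params$seed))
    params$seed else 1L
  tb <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    params$seed <- as.integer(base_seed + r - 1L)
    res <- run_model(params, model, record_series = FALSE)
    if (res$absorbed) tb[r] <- res$t_balance
  }
  n_abs <- sum(!is.na(tb))
  ok <- n_abs >= n_runs / 2
  M <- params$opinion_update_period
  list(T_typ_steps = if (ok) stats::median(tb, na.rm = TRUE) else NA_real_,
       T_typ_rounds = if (ok)
         stats::median(tb, na.rm = TRUE) / (params$N * M) else NA_real_,
       n_absorbed = n_abs, n_runs = n_runs,
       status = if (ok) "ok" else "undefined",
       t_balance = tb)
}

#' Estimate the consensus threshold on a confidence-level grid
#'
#' For the pure bounded-confidence baseline (`model = "bc"`): the smallest
#' grid `epsilon` at which every run reaches a single opinion.  For the
#' coupled model (`model = "bcpf"`): the smallest grid `epsilon` at which
#' every absorbed run ends with exactly two opinions, i.e. one per clique
#' (intra-clique consensus); cells with no absorbed run do not qualify.
#'
#' @param params Base [bcpf_params()].
#' @param model `"bc"` or `"bcpf"`.
#' @param eps_grid Ascending grid of confidence levels (default step 0.05).
#' @param runs Runs per grid value.
#' @param base_seed Base seed (see [sweep_spec()]).
#' @return List with `threshold` (`NA` if no grid value qualifies, with
#'   `status = "above grid"`), `status`, and the per-cell `table`.
#' @export
estimate_consensus_threshold <- function(params, model = c("bc", "bcpf"),
                                         eps_grid = seq(0.05, 1, by = 0.05),
                                         runs = 8L, base_seed = 1L) {
  model <- match.arg(model)
  if (is.unsorted(eps_grid, strictly = TRUE))
    stop("`eps_grid` must be strictly ascending", call. = FALSE)
  spec <- sweep_spec(params, grid = list(epsilon = eps_grid), runs = runs,
                     base_seed = base_seed, model = model)
  ens <- run_ensemble(spec)
  target_nop <- if (model == "bc") 1L else 2L
  per_run <- ens$runs
  qualifies <- vapply(seq_along(eps_grid), function(ci) {
    rr <- per_run[per_run$cell == ci, , drop = FALSE]
    ab <- rr[rr$absorbed, , drop = FALSE]
    if (model == "bc") {
      nrow(ab) == nrow(rr) && all(ab$N_op == target_nop)
    } else {
      nrow(ab) > 0 && all(ab$N_op == target_nop)
    }
  }, TRUE)
  tab <- cbind(ens$summary, qualifies = qualifies)
  idx <- which(qualifies)
  if (length(idx) == 0) {
    list(threshold = NA_real_, status = "above grid", table = tab)
  } else {
    list(threshold = eps_grid[min(idx)], status = "ok", table = tab)
  }
}

#' Estimate the critical flip probability of the bipolar/all-friends
#' transition
#'
#' Classifies each grid cell's absorbed runs as bipolar (two cliques) or
#' all-friends and returns the midpoint between the largest `p` whose runs
#' are all bipolar and the smallest `p` whose runs are all all-friends.
#' A non-monotone classification across the grid is flagged and the
#' bracketing interval returned instead of a point estimate.
#'
#' @param params Base [bcpf_params()].
#' @param p_grid Ascending grid of flip probabilities, excluding 0.5.
#' @param runs Runs per grid value.
#' @param base_seed Base seed.
#' @param model Model label (`"bcpf"` or `"ltd"`).
#' @return List with `p_c`, `interval`, `monotone`, `status` and the
#'   per-cell `table`.
#' @export
estimate_p_threshold <- function(params,
                                 p_grid = setdiff(seq(0.05, 0.95, 0.05), 0.5),
                                 runs = 8L, base_seed = 1L,
                                 model = c("bcpf", "ltd")) {
  model <- match.arg(model)
  if (is.unsorted(p_grid, strictly = TRUE))
    stop("`p_grid` must be strictly ascending", call. = FALSE)
  if (any(p_grid == 0.5))
    stop("`p_grid` must exclude the critical point 0.5", call. = FALSE)
  spec <- sweep_spec(params, grid = list(p = p_grid), runs = runs,
                     base_seed = base_seed, model = model)
  ens <- run_ensemble(spec)
  cls <- ifelse(ens$summary$n_absorbed == 0, "none",
         ifelse(ens$summary$frac_bipolar == 1, "bipolar",
         ifelse(ens$summary$frac_all_friends == 1, "all_friends", "mixed")))
  tab <- cbind(ens$summary, class = cls)
  bip <- p_grid[cls == "bipolar"]
  allf <- p_grid[cls == "all_friends"]
  if (length(bip) == 0 || length(allf) == 0) {
    return(list(p_c = NA_real_, interval = c(NA_real_, NA_real_),
                monotone = NA, status = "no transition in grid",
                table = tab))
  }
  lo <- max(bip); hi <- min(allf)
  monotone <- lo < hi &&
    all(p_grid[p_grid < lo & cls != "none"] %in% bip) &&
    all(p_grid[p_grid > hi & cls != "none"] %in% allf)
  if (monotone) {
    list(p_c = (lo + hi) / 2, interval = c(lo, hi), monotone = TRUE,
         status = "ok", table = tab)
  } else {
    list(p_c = NA_real_, interval = range(c(bip, allf)), monotone = FALSE,
         status = "non-monotone classification", table = tab)
  }
}
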