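#' Read and write states in the package's CSV dialects
#'
#' The network file has header `i,j,sign` with one row per unordered pair
#' (`i < j`, 1-based agent indices, sign `-1` or `1`).  The opinion file
#' has header `agent,x_1,...,x_F` with one row per agent.
#'
#' @param state A [bcpf_state()].
#' @param network_file,opinion_file File paths.
#' @return `write_state_csv` returns the state invisibly;
#'   `read_state_csv` returns a `bcpf_state`.
#' @export
write_state_csv <- function(state, network_file, opinion_file) {
  stopifnot(inherits(state, "bcpf_state"))
  N <- nrow(state$signs)
  up <- which(upper.tri(state$signs), arr.ind = TRUE)
  net <- data.frame(i = up[, 1], j = up[, 2],
                    sign = state$signs[up])
  net <- net[order(net$i, net$j), ]
  utils::write.csv(net, network_file, row.names = FALSE, quote = FALSE)
  ops <- data.frame(agent = seq_len(N), state$opinions)
  names(ops) <- c("agent", paste0("x_", seq_len(ncol(state$opinions))))
  utils::write.csv(ops, opinion_file, row.names = FALSE, quote = FALSE)
  invisible(state)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(network_file, opinion_file) {
  net <- utils::read.csv(network_file)
  if (!all(c("i", "j", "sign") %in% names(net)))
    stop("network CSV must have columns i,j,sign", call. = FALSE)
  ops <- utils::read.csv(opinion_file)
  if (names(ops)[1] != "agent")
    stop("opinion CSV must have an `agent` first column", call. = FALSE)
  ops <- ops[order(ops$agent), ]
  N <- nrow(ops)
  if (any(net$i >= net$j) || any(net$i < 1) || any(net$j > N))
    stop("network CSV must list each unordered pair once with i < j",
         call. = FALSE)
  if (nrow(net) != N * (N - 1) / 2)
    stop("network CSV must cover every pair of a complete network",
         call. = FALSE)
  signs <- matrix(0L, N, N)
  signs[cbind(net$i, net$j)] <- as.integer(net$sign)
  signs <- signs + t(signs)
  bcpf_state(signs, as.matrix(ops[, -1, drop = FALSE]))
}

#' Write a run record to JSON
#'
#' Serializes the scalar summary of a [run()] result: parameter echo, seed,
#' balance and convergence times, termination reason, clique sizes, final
#' opinion count and diversity measures, and flip-event counts by branch.
#'
#' @param res A `bcpf_run`.
#' @param path Output path (`.json`).
#' @return The JSON string, invisibly.
#' @export
write_run_json <- function(res, path) {
  stopifnot(inherits(res, "bcpf_run"))
  rec <- list(
    params = unclass(res$params),
    seed = res$seed,
    t = res$t,
    t_balance = res$t_balance,
    rounds_balance = res$rounds_balance,
    sweeps = res$sweeps,
    termination = res$termination,
    absorbed = res$absorbed,
    clique_sizes = res$clique_sizes,
    S_dif = res$S_dif,
    N_op = res$N_op,
    D_plus = res$D_plus,
    D_minus = res$D_minus,
    flip_counts = as.list(res$flip_counts))
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(json)
}

#' Write the per-round observable series to CSV
#'
#' Columns: `round,t,F_unbal,D_plus,D_minus,N_op`.
#'
#' @param res A `bcpf_run` produced with `record_series = TRUE`.
#' @param path Output path (`.csv`).
#' @export
write_series_csv <- function(res, path) {
  stopifnot(inherits(res, "bcpf_run"))
  if (nrow(res$series) == 0)
    stop("run was executed with record_series = FALSE", call. = FALSE)
  ser <- res$series
  names(ser) <- c("round", "t", "F_unbal", "D_plus", "D_minus", "N_op")
  utils::write.csv(ser, path, row.names = FALSE)
  invisible(ser)
}
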