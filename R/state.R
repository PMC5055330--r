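#' System state: complete signed network plus opinion matrix
#'
#' A `bcpf_state` holds the full configuration of the coupled dynamics:
#' a symmetric `N x N` sign matrix (`+1` friendship, `-1` enmity, `0` on the
#' diagonal), an `N x F` opinion matrix with entries in `[0,1]`, the
#' time-step counter `t` (one triad revision per step) and a cached count of
#' unbalanced triads that is maintained incrementally by [flip_link()].
#'
#' Agent indices are 1-based everywhere (API, files, logs).
#'
#' @param signs Symmetric integer matrix of `+1`/`-1` with zero diagonal.
#' @param opinions Numeric `N x F` matrix with entries in `[0,1]`.
#' @param t Time-step counter (default 0).
#' @return An object of class `bcpf_state`.
#' @seealso [init_random_state()], [flip_link()]
#' @export
bcpf_state <- function(signs, opinions, t = 0) {
  signs <- validate_signs(signs)
  N <- nrow(signs)
  if (is.vector(opinions)) opinions <- matrix(opinions, ncol = 1L)
  opinions <- as.matrix(opinions)
  if (nrow(opinions) != N)
    stop("`opinions` must have one row per agent", call. = FALSE)
  if (any(!is.finite(opinions)) || any(opinions < 0) || any(opinions > 1))
    stop("opinions must lie in [0, 1]", call. = FALSE)
  structure(
    list(signs = signs, opinions = opinions, t = t,
         unbalanced = count_unbalanced_triads(signs)),
    class = "bcpf_state"
  )
}

validate_signs <- function(signs) {
  signs <- as.matrix(signs)
  N <- nrow(signs)
  if (ncol(signs) != N || N < 3)
    stop("`signs` must be a square matrix with N >= 3", call. = FALSE)
  if (any(diag(signs) != 0))
    stop("`signs` must have a zero diagonal (no self-links)", call. = FALSE)
  off <- signs[row(signs) != col(signs)]
  if (any(off != 1 & off != -1))
    stop("every off-diagonal sign must be +1 or -1 (complete network)",
         call. = FALSE)
  if (any(signs != t(signs)))
    stop("`signs` must be symmetric", call. = FALSE)
  storage.mode(signs) <- "integer"
  signs
}

# Accept a bcpf_state or a bare sign matrix.
as_signs <- function(x) {
  if (inherits(x, "bcpf_state")) x$signs else validate_signs(x)
}

#' @export
print.bcpf_state <- function(x, ...) {
  N <- nrow(x$signs)
  cat(sprintf("BC-PF system state: N = %d agents, F = %d issue(s)\n",
              N, ncol(x$opinions)))
  cat(sprintf("  t = %g steps, unbalanced triads = %d / %d\n",
              x$t, x$unbalanced, n_triads(N)))
  cat(sprintf("  positive links: %d of %d\n",
              sum(x$signs[upper.tri(x$signs)] == 1L), N * (N - 1) / 2))
  invisible(x)
}

#' Draw a random initial state
#'
#' Link signs are i.i.d. positive with probability `rho0`; opinions are
#' i.i.d. uniform on `[0,1]` per agent and issue.  Uses the current RNG
#' state: call `set.seed()` first (or use [run()], which seeds from
#' `params$seed`).
#'
#' @param params A [bcpf_params()] object.
#' @return A `bcpf_state` with `t = 0` and the unbalanced-triad count
#'   initialized by full enumeration.
#' @examples
#' set.seed(1)
#' st <- init_random_state(bcpf_params(N = 10))
#' @export
init_random_state <- function(params) {
  N <- params$N
  signs <- matrix(0L, N, N)
  n_pairs <- N * (N - 1) / 2
  s <- ifelse(stats::runif(n_pairs) < params$rho0, 1L, -1L)
  signs[upper.tri(signs)] <- s
  signs <- signs + t(signs)
  opinions <- matrix(stats::runif(N * params$F), nrow = N, ncol = params$F)
  bcpf_state(signs, opinions, t = 0)
}

#' Count unbalanced triads
#'
#' The sum of sign products over all triads equals `trace(S^3)/6` for a
#' complete signed network, so the unbalanced count follows without explicit
#' enumeration; the result is exact integer arithmetic in doubles.
#'
#' @param signs Sign matrix or `bcpf_state`.
#' @return Integer number of triads `i<j<k` with `s_ij s_ik s_jk = -1`.
#' @export
count_unbalanced_triads <- function(signs) {
  s <- as_signs(signs)
  storage.mode(s) <- "double"
  total <- n_triads(nrow(s))
  sum_products <- sum(diag(s %*% s %*% s)) / 6
  as.integer(round((total - sum_products) / 2))
}

#' Classify a triad by its multiset of link signs
#'
#' Classes `+++` and `+--` are balanced (sign product `+1`); `-++` and
#' `---` are unbalanced (product `-1`).
#'
#' @param state A `bcpf_state` (or bare sign matrix).
#' @param triad Integer vector of three distinct agent indices.
#' @return One of `"+++"`, `"+--"`, `"-++"`, `"---"`, with attribute
#'   `balanced` (logical).
#' @examples
#' st <- bcpf_state(matrix(c(0, 1, 1, 1, 0, -1, 1, -1, 0), 3), runif(3))
#' triad_type(st, c(1, 2, 3))  # "-++", unbalanced
#' @export
triad_type <- function(state, triad) {
  s <- as_signs(state)
  triad <- validate_triad(triad, nrow(s))
  sg <- c(s[triad[1], triad[2]], s[triad[1], triad[3]], s[triad[2], triad[3]])
  n_neg <- sum(sg == -1L)
  cls <- c("+++", "-++", "+--", "---")[n_neg + 1L]
  attr(cls, "balanced") <- n_neg %% 2L == 0L
  cls
}

validate_triad <- function(triad, N) {
  if (length(triad) != 3L || anyNA(triad) || any(triad != round(triad)))
    stop("a triad is three distinct agent indices", call. = FALSE)
  triad <- as.integer(triad)
  if (any(triad < 1L) || any(triad > N) || anyDuplicated(triad))
    stop("triad indices must be distinct and in 1..N", call. = FALSE)
  sort(triad)
}

#' Opinion distance between two agents
#'
#' Chebyshev distance is the maximum per-issue absolute difference, the
#' model's native metric: two agents are within confidence `epsilon` only if
#' they differ by less than `epsilon` on every issue.  The euclidean
#' alternative is the root-sum-of-squares.  For `F = 1` both equal
#' `|x_i - x_j|`.
#'
#' @param opinions `N x F` opinion matrix (or a `bcpf_state`).
#' @param i,j Agent indices.
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @return Non-negative scalar distance.
#' @examples
#' x <- rbind(c(0.2, 0.9), c(0.5, 0.8))
#' opinion_distance(x, 1, 2)               # 0.3
#' opinion_distance(x, 1, 2, "euclidean")  # sqrt(0.09 + 0.01)
#' @export
opinion_distance <- function(opinions, i, j,
                             metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(opinions, "bcpf_state")) opinions <- opinions$opinions
  if (is.vector(opinions)) opinions <- matrix(opinions, ncol = 1L)
  N <- nrow(opinions)
  for (a in c(i, j)) {
    if (length(a) != 1L || is.na(a) || a < 1L || a > N || a != round(a))
      stop("agent index out of range", call. = FALSE)
  }
  d <- abs(opinions[i, ] - opinions[j, ])
  if (metric == "chebyshev") max(d) else sqrt(sum(d^2))
}

#' Full pairwise opinion-distance matrix
#'
#' @inheritParams opinion_distance
#' @return Symmetric `N x N` matrix of distances with zero diagonal.
#' @export
opinion_distance_matrix <- function(opinions,
                                    metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(opinions, "bcpf_state")) opinions <- opinions$opinions
  if (is.vector(opinions)) opinions <- matrix(opinions, ncol = 1L)
  method <- if (metric == "chebyshev") "maximum" else "euclidean"
  as.matrix(stats::dist(opinions, method = method))
}

# Positive-subgraph connected components, 1..k labels.
positive_components <- function(signs) {
  g <- igraph::graph_from_adjacency_matrix(signs > 0L, mode = "undirected")
  igraph::components(g)$membership
}

#' Is a complete signed network balanced?
#'
#' A complete signed network is balanced (every triad has sign product `+1`)
#' if and only if the agents split into at most two cliques with all
#' intra-clique links positive and all cross links negative.  This check
#' runs in O(N^2): the positive subgraph must have at most two connected
#' components and each component must be internally all-positive (cross
#' links between components are negative by construction of the components).
#'
#' @param network Sign matrix or `bcpf_state`.
#' @return Logical.
#' @export
is_balanced <- function(network) {
  s <- as_signs(network)
  comp <- positive_components(s)
  if (max(comp) > 2L) return(FALSE)
  for (c_id in seq_len(max(comp))) {
    members <- which(comp == c_id)
    if (length(members) > 1L) {
      block <- s[members, members, drop = FALSE]
      if (any(block[upper.tri(block)] != 1L)) return(FALSE)
    }
  }
  TRUE
}

#' Extract the clique bipartition of a balanced network
#'
#' @param network Sign matrix or `bcpf_state`; must be balanced.
#' @return List with components `C1` and `C2`: integer vectors of agent
#'   indices (`C2` empty for the all-friends configuration).  `C1` is the
#'   larger clique (ties broken by lowest member index).
#' @export
extract_cliques <- function(network) {
  s <- as_signs(network)
  if (!is_balanced(s))
    stop("network is not balanced: no clique bipartition exists",
         call. = FALSE)
  comp <- positive_components(s)
  cliques <- split(seq_len(nrow(s)), comp)
  if (length(cliques) == 1L) {
    list(C1 = cliques[[1]], C2 = integer(0))
  } else {
    ord <- order(-lengths(cliques), vapply(cliques, min, 1L))
    list(C1 = cliques[[ord[1]]], C2 = cliques[[ord[2]]])
  }
}

#' Flip the sign of one link, updating the unbalanced count incrementally
#'
#' Toggling `s_ij` flips the balance of exactly the `N - 2` triads that
#' contain the pair, so the cached count is updated in O(N).
#'
#' @param state A `bcpf_state`.
#' @param i,j Distinct agent indices.
#' @return The updated state (time counter untouched).
#' @export
flip_link <- function(state, i, j) {
  stopifnot(inherits(state, "bcpf_state"))
  N <- nrow(state$signs)
  if (i == j || any(c(i, j) < 1L) || any(c(i, j) > N))
    stop("invalid link", call. = FALSE)
  others <- setdiff(seq_len(N), c(i, j))
  prods <- state$signs[i, j] * state$signs[i, others] * state$signs[j, others]
  # triads that were balanced (+1) become unbalanced, and vice versa
  state$unbalanced <- state$unbalanced + sum(prods == 1L) - sum(prods == -1L)
  state$signs[i, j] <- -state$signs[i, j]
  state$signs[j, i] <- state$signs[i, j]
  state
}
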