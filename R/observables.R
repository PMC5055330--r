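#' @keywords internal
# Single-linkage opinion clusters at tolerance tol: connected components of
# the graph linking agents at distance <= tol.
opinion_clusters <- function(opinions, tol,
                             metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(opinions, "bcpf_state")) opinions <- opinions$opinions
  if (is.vector(opinions)) opinions <- matrix(opinions, ncol = 1L)
  N <- nrow(opinions)
  if (N == 1L) return(list(1L))
  d <- opinion_distance_matrix(opinions, metric)
  g <- igraph::graph_from_adjacency_matrix(d <= tol, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  unname(split(seq_len(N), comp))
}

#' Intra- and inter-clique opinion diversity
#'
#' `D_plus` is the mean opinion distance over unordered positive links
#' (friends' opinion dispersion); `D_minus` is the same over negative links
#' (enemies' opinion divergence).  Both are defined on any state, balanced
#' or not; in a balanced state positive links are exactly the intra-clique
#' pairs, so `D_plus` measures intra-clique diversity and `D_minus`
#' inter-clique separation.  If there are no positive (or no negative)
#' links the corresponding measure is undefined and reported as `NA`.
#'
#' @param state A [bcpf_state()] or [run()] result.
#' @param metric Opinion-distance metric (replaces `|x_j - x_i|` when
#'   `F > 1`).
#' @return List with `D_plus` and `D_minus`.
#' @examples
#' s <- matrix(c(0, 1, -1, 1, 0, -1, -1, -1, 0), 3)
#' st <- bcpf_state(s, c(0.1, 0.2, 0.9))
#' diversity_measures(st)  # D_plus = 0.1, D_minus = 0.75
#' @export
diversity_measures <- function(state, metric = NULL) {
  if (inherits(state, "bcpf_run")) {
    if (is.null(metric)) metric <- state$params$metric
    return(diversity_measures_xs(state$signs, state$opinions, metric))
  }
  stopifnot(inherits(state, "bcpf_state"))
  if (is.null(metric)) metric <- "chebyshev"
  diversity_measures_xs(state$signs, state$opinions, metric)
}

diversity_measures_xs <- function(signs, opinions, metric) {
  d <- opinion_distance_matrix(opinions, metric)
  up <- upper.tri(signs)
  pos <- signs == 1L & up
  neg <- signs == -1L & up
  list(D_plus = if (any(pos)) mean(d[pos]) else NA_real_,
       D_minus = if (any(neg)) mean(d[neg]) else NA_real_)
}

#' Count distinct opinions
#'
#' Groups agents by single-linkage clustering at distance `tol_cluster`;
#' `N_op` is the number of groups.  Asynchronous averaging never reaches
#' exact equality in floating point, hence the tolerance.
#'
#' @param state A [bcpf_state()], [run()] result, or opinion matrix.
#' @param tol_cluster Opinion-equality tolerance (default `1e-6`).
#' @param metric Opinion-distance metric.
#' @return List with `N_op`, `clusters` (list of agent-index vectors),
#'   `centroids` (one row per cluster) and `sizes`.
#' @examples
#' count_opinions(matrix(c(0.3, 0.3, 0.7)))$N_op  # 2
#' @export
count_opinions <- function(state, tol_cluster = 1e-6,
                           metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  opinions <- if (inherits(state, "bcpf_run")) state$opinions
              else if (inherits(state, "bcpf_state")) state$opinions
              else state
  if (is.vector(opinions)) opinions <- matrix(opinions, ncol = 1L)
  cl <- opinion_clusters(opinions, tol_cluster, metric)
  centroids <- do.call(rbind, lapply(cl, function(idx)
    colMeans(opinions[idx, , drop = FALSE])))
  list(N_op = length(cl), clusters = cl, centroids = centroids,
       sizes = lengths(cl))
}

#' Clique-size difference in percent points
#'
#' `S_dif = |C1 - C2| / N * 100` for a clique bipartition (an empty second
#' clique, the all-friends configuration, gives 100).
#'
#' @param partition List with `C1` and `C2` as produced by
#'   [extract_cliques()].
#' @return Scalar in `[0, 100]`.
#' @export
clique_size_difference <- function(partition) {
  n1 <- length(partition$C1); n2 <- length(partition$C2)
  abs(n1 - n2) / (n1 + n2) * 100
}

#' Check one-dimensional opinion segregation across cliques
#'
#' In a bipolar absorbing state of the coupled dynamics, opinions in one
#' clique all lie below the opinions in the other, defining a "left clique"
#' and a "right clique".  Returns `TRUE` iff the maximum opinion in one
#' clique is strictly below the minimum in the other (a tie counts as a
#' violation).
#'
#' @param state A [bcpf_state()], [run()] result, or opinion matrix/vector.
#' @param partition Clique bipartition with both cliques non-empty.
#' @return Logical.
#' @export
check_segregation_1d <- function(state, partition) {
  opinions <- if (inherits(state, "bcpf_run") ||
                  inherits(state, "bcpf_state")) state$opinions else state
  opinions <- as.matrix(opinions)
  if (ncol(opinions) != 1L)
    stop("segregation check applies to one-dimensional opinions",
         call. = FALSE)
  if (length(partition$C1) == 0L || length(partition$C2) == 0L)
    stop("not applicable: the state is not bipolar", call. = FALSE)
  a <- opinions[partition$C1, 1]; b <- opinions[partition$C2, 1]
  max(a) < min(b) || max(b) < min(a)
}

# --- exact 2-D convex-hull disjointness ---------------------------------

orient <- function(p, q, r) {
  (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
}

on_segment <- function(p, q, r) {
  # r collinear with p-q assumed; is r within the bounding box?
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

segments_intersect <- function(p1, p2, q1, q2) {
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
      o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) return(TRUE)
  (o1 == 0 && on_segment(p1, p2, q1)) ||
    (o2 == 0 && on_segment(p1, p2, q2)) ||
    (o3 == 0 && on_segment(q1, q2, p1)) ||
    (o4 == 0 && on_segment(q1, q2, p2))
}

hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  collinear <- all(vapply(3:n, function(r)
    orient(pts[1, ], pts[2, ], pts[r, ]) == 0, TRUE))
  if (collinear) {  # degenerate hull: keep the two extreme points
    dir <- if (diff(range(pts[, 1])) >= diff(range(pts[, 2]))) 1L else 2L
    return(pts[c(which.min(pts[, dir]), which.max(pts[, dir])), ,
               drop = FALSE])
  }
  pts[grDevices::chull(pts), , drop = FALSE]
}

hull_edges <- function(v) {
  n <- nrow(v)
  if (n == 1L) return(list(list(v[1, ], v[1, ])))
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  if (n == 2L) idx <- idx[1, , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r)
    list(v[idx[r, 1], ], v[idx[r, 2], ]))
}

point_in_hull <- function(pt, v) {
  n <- nrow(v)
  if (n == 1L) return(all(pt == v[1, ]))
  if (n == 2L)
    return(orient(v[1, ], v[2, ], pt) == 0 && on_segment(v[1, ], v[2, ], pt))
  side <- vapply(seq_len(n), function(r) {
    orient(v[r, ], v[if (r == n) 1L else r + 1L, ], pt)
  }, 0.0)
  all(side >= 0) || all(side <= 0)
}

hulls_disjoint_2d <- function(A, B) {
  va <- hull_vertices(A); vb <- hull_vertices(B)
  for (ea in hull_edges(va))
    for (eb in hull_edges(vb))
      if (segments_intersect(ea[[1]], ea[[2]], eb[[1]], eb[[2]]))
        return(FALSE)
  if (any(vapply(seq_len(nrow(va)), function(r)
        point_in_hull(va[r, ], vb), TRUE))) return(FALSE)
  if (any(vapply(seq_len(nrow(vb)), function(r)
        point_in_hull(vb[r, ], va), TRUE))) return(FALSE)
  TRUE
}

# Strict linear separability for any dimension >= 2 via the minimum
# distance between the two convex hulls: a quadratic program over the
# convexity weights (lambda, mu) minimizing ||A'lambda - B'mu||^2 on the
# product of simplices.  Separable iff the minimum distance is positive.
separable_qp <- function(A, B, tol = 1e-8) {
  M <- rbind(A, -B)                     # (m+k) x F point stack
  n <- nrow(M); m <- nrow(A)
  D <- M %*% t(M) + diag(1e-10, n)      # ridge keeps the QP positive definite
  Amat <- cbind(c(rep(1, m), rep(0, n - m)),
                c(rep(0, m), rep(1, n - m)),
                diag(n))
  bvec <- c(1, 1, rep(0, n))
  sol <- quadprog::solve.QP(D, rep(0, n), Amat, bvec, meq = 2)
  gap <- sqrt(max(0, sum((t(M) %*% sol$solution)^2)))
  gap > tol
}

#' Check linear separability of the two cliques' opinion sets
#'
#' Tests whether the opinion points of the two cliques are strictly
#' separated by a hyperplane in issue space.  For `F = 2` the decision is
#' made exactly by convex-hull disjointness (touching hulls count as not
#' separable); for `F > 2` by the minimum distance between the two convex
#' hulls, computed as a quadratic program.
#'
#' @param state A [bcpf_state()], [run()] result, or `N x F` opinion matrix
#'   with `F >= 2`.
#' @param partition Clique bipartition.  If one clique is empty the result
#'   is `TRUE` by convention, with attribute `degenerate = TRUE`.
#' @return Logical.
#' @examples
#' x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
#' check_hyperplane_separation(x, list(C1 = 1:2, C2 = 3:4))  # FALSE (XOR)
#' @export
check_hyperplane_separation <- function(state, partition) {
  opinions <- if (inherits(state, "bcpf_run") ||
                  inherits(state, "bcpf_state")) state$opinions else state
  opinions <- as.matrix(opinions)
  if (ncol(opinions) < 2L)
    stop("hyperplane separation applies to F >= 2", call. = FALSE)
  if (length(partition$C1) == 0L || length(partition$C2) == 0L) {
    res <- TRUE
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  A <- opinions[partition$C1, , drop = FALSE]
  B <- opinions[partition$C2, , drop = FALSE]
  if (ncol(opinions) == 2L) hulls_disjoint_2d(A, B) else separable_qp(A, B)
}

#' Opinion alignment score of a point set
#'
#' Measures how collinear a set of two-dimensional opinion points is: the
#' ratio `lambda1 / (lambda1 + lambda2)` of the eigenvalues of their 2x2
#' population covariance.  1 means perfectly collinear (rank-1 covariance),
#' 0.5 isotropic scatter.  During convergence the members of an opinion
#' cluster align along a single direction, echoing DeMarzo-style
#' unidimensional opinions at the cluster level.
#'
#' @param points Matrix with one row per point and 2 columns.
#' @return Scalar in `[0.5, 1]`, or `NA` (with a warning) when all points
#'   coincide.
#' @examples
#' alignment_score(cbind(1:3, 2 * (1:3)))  # 1: collinear
#' @export
alignment_score <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("not applicable: need at least 2 points", call. = FALSE)
  if (ncol(points) != 2L)
    stop("alignment score is defined for 2-dimensional opinions",
         call. = FALSE)
  centered <- sweep(points, 2, colMeans(points))
  covm <- crossprod(centered) / nrow(points)  # population covariance
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  if (sum(ev) <= 0) {
    warning("all points coincide: alignment undefined")
    return(NA_real_)
  }
  ev[1] / sum(ev)
}
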