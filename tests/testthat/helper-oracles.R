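# Independent oracles used across the test files.  These deliberately use
# naive enumeration so that the package's O(N)/O(N^2) implementations are
# checked against first-principles counts.

# Brute-force unbalanced-triad count by full enumeration.
oracle_unbalanced <- function(signs) {
  N <- nrow(signs)
  triads <- utils::combn(N, 3)
  sum(apply(triads, 2, function(tr)
    signs[tr[1], tr[2]] * signs[tr[1], tr[3]] * signs[tr[2], tr[3]] == -1))
}

# Brute-force balance verdict.
oracle_balanced <- function(signs) oracle_unbalanced(signs) == 0

# Random complete signed network as a plain matrix.
random_signs <- function(N, rho = 0.5) {
  s <- matrix(0L, N, N)
  v <- ifelse(stats::runif(N * (N - 1) / 2) < rho, 1L, -1L)
  s[upper.tri(s)] <- v
  s + t(s)
}

# Constructed bipolar sign matrix from a membership split.
bipolar_signs <- function(groups) {
  N <- length(groups)
  s <- outer(groups, groups, function(a, b) ifelse(a == b, 1L, -1L))
  diag(s) <- 0L
  s
}

# Discretized direction-sweep oracle for strict linear separability of two
# 2-D point sets: scans a fine grid of unit directions and checks whether
# some direction puts all of A strictly below all of B (or vice versa).
oracle_separable_sweep <- function(A, B, n_angles = 3600) {
  for (th in seq(0, pi, length.out = n_angles)) {
    w <- c(cos(th), sin(th))
    pa <- A %*% w; pb <- B %*% w
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
  }
  FALSE
}

# Small BC-PF run used by several files.  Balance times are heavy-tailed
# (a run whose opinions freeze into several mutually distant clusters can
# take very long to balance), so callers should tolerate occasional
# non-absorbed results under this cap.
absorbed_run <- function(N = 20, p = 0.1, epsilon = 0.2, seed = 42, ...) {
  run(bcpf_params(N = N, p = p, epsilon = epsilon, seed = seed,
                  max_rounds = 20000), ...)
}
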