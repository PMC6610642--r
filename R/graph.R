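#' Build a p-nearest-neighbor graph from a similarity matrix
#'
#' For every entity i, the neighbor set Np(i) holds the p entities with
#' the largest similarity to i (self excluded; ties broken toward the
#' smallest index). The graph weight between i and j is 1 when each is in
#' the other's neighbor set, 0 when neither is, and 1/2 when exactly one
#' is — the mutual / one-sided weighting used to sparsify similarities
#' before graph regularization.
#'
#' @param S square symmetric similarity matrix.
#' @param p neighbor count, integer in `[1, n - 1]`.
#' @return symmetric matrix `N` with entries in `{0, 1/2, 1}`, zero
#'   diagonal, same dimnames as `S`, and attribute `p`.
#' @export
pnn_graph <- function(S, p) {
  n <- nrow(S)
  check(is.matrix(S) && n == ncol(S), "S must be square")
  check(length(p) == 1L && !is.na(p) && p == as.integer(p), "p must be an integer")
  p <- as.integer(p)
  check(p >= 1L, "p must be >= 1")
  check(p <= n - 1L, "p must be <= n - 1 (got p = ", p, ", n = ", n, ")")
  # M[i, j] = 1 iff j is among the p largest similarities of row i
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf                          # self never a neighbor
    ord <- order(-s, seq_len(n))          # ties -> smallest index first
    M[i, ord[seq_len(p)]] <- 1
  }
  N <- (M + t(M)) / 2
  dimnames(N) <- dimnames(S)
  attr(N, "p") <- p
  N
}

#' Sparsify a similarity matrix through a neighbor graph
#'
#' Elementwise product of the similarity matrix with the p-NN graph
#' weights, so non-neighbor similarities become exactly 0 and one-sided
#' neighbor similarities are halved. The diagonal is zeroed because an
#' entity is never its own neighbor.
#'
#' @param S square symmetric similarity matrix.
#' @param N neighbor graph from [pnn_graph()], same dimension.
#' @return symmetric matrix `S_hat = N * S` (elementwise).
#' @export
sparsify_similarity <- function(S, N) {
  check(is.matrix(S) && is.matrix(N), "S and N must be matrices")
  check(all(dim(S) == dim(N)), "dimension mismatch between S and N")
  S_hat <- unclass(N) * unclass(S)
  dimnames(S_hat) <- dimnames(S)
  attributes(S_hat)$kind <- NULL
  S_hat
}

#' Unnormalized and normalized graph Laplacians
#'
#' Given a (sparsified) similarity matrix, computes the degree vector
#' `d_i = sum_r S_hat(i, r)`, the combinatorial Laplacian `L = D - S_hat`,
#' and the symmetric normalized Laplacian
#' `L_tilde = D^(-1/2) L D^(-1/2)`. Rows with non-positive degree get a 0
#' entry in `D^(-1/2)` (isolated nodes contribute nothing to `L_tilde`).
#'
#' For a nonnegative `S_hat`, `L` is positive semidefinite with zero row
#' sums and the eigenvalues of `L_tilde` lie in `[0, 2]`.
#'
#' @param S_hat square symmetric matrix (typically from
#'   [sparsify_similarity()]).
#' @return list with components `L`, `L_tilde` and `degree`.
#' @export
graph_laplacian <- function(S_hat) {
  check(is.matrix(S_hat) && nrow(S_hat) == ncol(S_hat), "S_hat must be square")
  check(max(abs(S_hat - t(S_hat))) <= 1e-8, "S_hat must be symmetric")
  d <- rowSums(S_hat)
  L <- diag(d, nrow = nrow(S_hat)) - S_hat
  d_isqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  L_tilde <- d_isqrt * L * rep(d_isqrt, each = nrow(L))  # D^-1/2 L D^-1/2
  dimnames(L) <- dimnames(L_tilde) <- dimnames(S_hat)
  list(L = L, L_tilde = L_tilde, degree = d)
}

# internal: full similarity -> normalized Laplacian pipeline used by wgrmf()
similarity_to_laplacian <- function(S, p, clip_negative = TRUE) {
  S <- unclass(S)
  if (clip_negative) S[S < 0] <- 0
  N <- pnn_graph(S, p)
  S_hat <- sparsify_similarity(S, N)
  graph_laplacian(S_hat)
}
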