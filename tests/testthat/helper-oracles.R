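# Independent oracles used across the suite. Each is written from the
# defining formula, deliberately sharing no code with the implementation.

# Jaccard by explicit set operations
jaccard_oracle <- function(fp) {
  n <- nrow(fp)
  S <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    bi <- which(fp[i, ] == 1); bj <- which(fp[j, ] == 1)
    S[i, j] <- length(intersect(bi, bj)) / length(union(bi, bj))
  }
  S
}

# p-NN graph by materializing every neighbor set explicitly
pnn_oracle <- function(S, p) {
  n <- nrow(S)
  Np <- lapply(seq_len(n), function(i) {
    s <- S[i, ]; s[i] <- -Inf
    order(-s, seq_len(n))[seq_len(p)]       # same smallest-index tie-break
  })
  N <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    in_i <- j %in% Np[[i]]; in_j <- i %in% Np[[j]]
    N[i, j] <- if (in_i && in_j) 1 else if (!in_i && !in_j) 0 else 0.5
  }
  N
}

# objective in its pairwise summation form:
# sum_ij W(R - AB')^2 + lambda_l(|A|^2+|B|^2)
#   + lambda_d sum_{i,r} Ltd(i,r) <a_i, a_r> + lambda_c sum_{j,q} Ltc(j,q) <b_j, b_q>
objective_oracle <- function(rm, A, B, Ltd, Ltc, par) {
  n <- nrow(rm$R); m <- ncol(rm$R)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    tot <- tot + rm$W[i, j] * (rm$R[i, j] - sum(A[i, ] * B[j, ]))^2
  }
  tot <- tot + par$lambda_l * (sum(A^2) + sum(B^2))
  for (i in seq_len(n)) for (r in seq_len(n)) {
    tot <- tot + par$lambda_d * Ltd[i, r] * sum(A[i, ] * A[r, ])
  }
  for (j in seq_len(m)) for (q in seq_len(m)) {
    tot <- tot + par$lambda_c * Ltc[j, q] * sum(B[j, ] * B[q, ])
  }
  tot
}

# ridge solution for one drug row via QR of the augmented system
ridge_row_oracle <- function(r_row, w_row, B, lambda_l) {
  obs <- which(w_row == 1)
  k <- ncol(B)
  X <- rbind(B[obs, , drop = FALSE], diag(sqrt(lambda_l), k))
  y <- c(r_row[obs], rep(0, k))
  as.numeric(qr.solve(X, y))
}

# gradient-descent comparator: L-BFGS-B on the vectorized objective
optim_oracle <- function(rm, init, Ltd, Ltc, par) {
  n <- nrow(rm$R); m <- ncol(rm$R); k <- par$k
  fn <- function(x) {
    A <- matrix(x[seq_len(n * k)], n, k)
    B <- matrix(x[-seq_len(n * k)], m, k)
    wgrmf_objective(rm, A, B, Ltd, Ltc, par)
  }
  stats::optim(c(init$A, init$B), fn, method = "L-BFGS-B",
               control = list(maxit = 2000, factr = 1e4))$value
}

# exact two-sided rank-sum p by enumerating group-a index sets and
# recomputing the statistic from raw values each time
ranksum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(na)])
  mu <- na * (n + 1) / 2
  sets <- utils::combn(n, na)
  count <- 0
  for (s in seq_len(ncol(sets))) {
    if (abs(sum(rk[sets[, s]]) - mu) >= abs(w_obs - mu) - 1e-9) count <- count + 1
  }
  count / ncol(sets)
}

# standard small fixture shared by solver/evaluation tests
standard_fixture <- function(seed = 42) {
  simulate_drug_response(n = 25, m = 40, k_true = 2, noise_sd = 0.1,
                         missing_fraction = 0.2, seed = seed)
}

standard_params <- function(...) {
  defaults <- list(k = 2, lambda_l = 2^-2, lambda_d = 2^-2, lambda_c = 2^-2,
                   p_drug = 5, p_cell = 5)
  do.call(wgrmf_params, utils::modifyList(defaults, list(...)))
}

# strip dimnames and auxiliary attributes for matrix comparison
plain <- function(M) matrix(as.numeric(M), nrow(M), ncol(M))
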