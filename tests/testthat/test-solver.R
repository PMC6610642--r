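test_that("objective reduces to its closed forms in degenerate settings", {
  sim <- simulate_drug_response(5, 6, 2, 0.2, 0.3, seed = 11)
  par0 <- wgrmf_params(k = 2, lambda_l = 0, lambda_d = 0, lambda_c = 0)
  A0 <- matrix(0, 5, 2); B0 <- matrix(0, 6, 2)
  expect_equal(wgrmf_objective(sim$rm, A0, B0, params = par0),
               sum((sim$rm$R * sim$rm$W)^2))       # residual term only
  full <- response_matrix(sim$truth_R, matrix(1, 5, 6))
  expect_equal(wgrmf_objective(full, sim$truth_A, sim$truth_B, params = par0), 0)
})

test_that("trace form of the objective matches the pairwise summation form", {
  sim <- simulate_drug_response(6, 5, 2, 0.2, 0.2, seed = 12)
  par <- wgrmf_params(k = 2, lambda_l = 0.3, lambda_d = 0.7, lambda_c = 0.4,
                      p_drug = 2, p_cell = 2)
  Ltd <- graph_laplacian(sparsify_similarity(sim$Sd, pnn_graph(sim$Sd, 2)))$L_tilde
  Ltc <- graph_laplacian(sparsify_similarity(sim$Sc, pnn_graph(sim$Sc, 2)))$L_tilde
  set.seed(1)
  A <- matrix(rnorm(12), 6, 2); B <- matrix(rnorm(10), 5, 2)
  expect_equal(wgrmf_objective(sim$rm, A, B, Ltd, Ltc, par),
               objective_oracle(sim$rm, A, B, Ltd, Ltc, par),
               tolerance = 1e-10)
})

test_that("SVD initialization is exact on low-rank data and deterministic", {
  u <- c(1, -2, 0.5, 3); v <- c(2, 0.1, -1, 0.7, 1.4)
  rm1 <- response_matrix(outer(u, v), matrix(1, 4, 5))
  f <- wgrmf_init(rm1, k = 1)
  expect_equal(tcrossprod(f$A, f$B), unname(rm1$R), tolerance = 1e-8)
  # full rank k = min(n, m) reconstructs any fully observed matrix
  set.seed(5)
  R <- matrix(rnorm(20), 4, 5)
  rm2 <- response_matrix(R, matrix(1, 4, 5))
  f2 <- wgrmf_init(rm2, k = 4)
  expect_lt(norm(R - tcrossprod(f2$A, f2$B), "F"), 1e-6 * norm(R, "F"))
  g1 <- wgrmf_init(rm2, k = 2, seed = 9, method = "gaussian")
  g2 <- wgrmf_init(rm2, k = 2, seed = 9, method = "gaussian")
  expect_identical(g1, g2)
  expect_error(wgrmf_init(rm2, k = 5), "min",
               class = "wgrmf_validation_error")
})

test_that("one A-sweep without graph terms is the per-row ridge solution", {
  sim <- simulate_drug_response(7, 9, 2, 0.3, 0.3, seed = 21)
  par <- wgrmf_params(k = 2, lambda_l = 0.6, lambda_d = 0, lambda_c = 0)
  init <- wgrmf_init(sim$rm, 2, seed = 3, method = "gaussian")
  out <- wgrmf_sweep(sim$rm, init$A, init$B, params = par)
  for (i in 1:7) {
    expect_equal(out$A[i, ],
                 ridge_row_oracle(sim$rm$R[i, ], sim$rm$W[i, ], init$B,
                                  par$lambda_l),
                 tolerance = 1e-8, label = paste("row", i))
  }
})

test_that("with orthonormal B, full W and no penalty, a_i projects R onto B", {
  set.seed(8)
  B <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  R <- matrix(rnorm(24), 4, 6)
  rm <- response_matrix(R, matrix(1, 4, 6))
  par <- wgrmf_params(k = 2, lambda_l = 0, lambda_d = 0, lambda_c = 0)
  out <- wgrmf_sweep(rm, matrix(0, 4, 2), B, params = par)
  expect_equal(out$A, R %*% B, tolerance = 1e-10)
})

test_that("converged factors are a fixed point of the sweep", {
  sim <- standard_fixture()
  par <- standard_params(tol = 1e-12, max_sweeps = 500)
  fit <- suppressWarnings(wgrmf(sim$rm, sim$Sd, sim$Sc, par))
  Ltd <- wgrmf:::similarity_to_laplacian(sim$Sd, par$p_drug)$L_tilde
  Ltc <- wgrmf:::similarity_to_laplacian(sim$Sc, par$p_cell)$L_tilde
  again <- wgrmf_sweep(sim$rm, fit$A, fit$B, Ltd, Ltc, par)
  expect_lt(max(abs(again$A - fit$A)), 1e-4)
  expect_lt(max(abs(again$B - fit$B)), 1e-4)
})

test_that("fit decreases the objective and recovers low-rank structure", {
  sim <- simulate_drug_response(20, 30, 2, 0.03, 0, seed = 31)
  par <- wgrmf_params(k = 2, lambda_l = 0.25, lambda_d = 0, lambda_c = 0)
  fit <- wgrmf(sim$rm, params = par)
  traj <- fit$objective_trajectory
  expect_lte(traj[length(traj)], traj[1])
  resid <- norm(sim$rm$R - predict(fit), "F") / norm(sim$rm$R, "F")
  expect_lt(resid, 0.05)
  expect_length(traj, fit$sweeps_run + 1)

  # 30% mask, moderate lambdas: monotone convergence within the cap
  sim2 <- simulate_drug_response(20, 30, 2, 0.1, 0.3, seed = 32)
  fit2 <- wgrmf(sim2$rm, sim2$Sd, sim2$Sc, standard_params(max_sweeps = 200))
  expect_true(fit2$converged)
  expect_true(all(diff(fit2$objective_trajectory) <= 1e-8))

  # huge tol stops after a single sweep
  fit3 <- wgrmf(sim2$rm, params = wgrmf_params(k = 2, tol = 1))
  expect_equal(fit3$sweeps_run, 1L)
  expect_length(fit3$objective_trajectory, 2L)
})

test_that("predict is the factor product with identifiers attached", {
  B <- matrix(rnorm(10), 5, 2)
  fit <- structure(list(A = diag(2), B = B, drug_ids = c("d1", "d2"),
                        cell_ids = paste0("c", 1:5)), class = "wgrmf")
  expect_equal(unname(predict(fit)), t(B))
  a <- c(1, -1, 2); b <- c(3, 0.5)
  fit2 <- structure(list(A = matrix(a), B = matrix(b), drug_ids = 1:3,
                         cell_ids = 1:2), class = "wgrmf")
  expect_equal(unname(predict(fit2)), outer(a, b))
  # converged fit on noiseless fully observed data reproduces the truth
  sim <- simulate_drug_response(15, 20, 2, 0, 0, seed = 33)
  fit3 <- wgrmf(sim$rm, sim$Sd, sim$Sc,
                standard_params(lambda_l = 1e-3, lambda_d = 1e-3,
                                lambda_c = 1e-3, tol = 1e-9))
  expect_lt(max(abs(predict(fit3) - sim$truth_R)), 0.05 * sd(sim$truth_R))
})

test_that("stronger Tikhonov regularization shrinks the factors", {
  sim <- simulate_drug_response(12, 15, 2, 0.2, 0.2, seed = 41)
  norms <- sapply(c(0.05, 0.25, 1, 4), function(ll) {
    fit <- wgrmf(sim$rm, sim$Sd, sim$Sc, standard_params(lambda_l = ll))
    sum(fit$A^2) + sum(fit$B^2)
  })
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("the drug graph term pulls neighboring latent vectors together", {
  sim <- simulate_drug_response(15, 20, 2, 0.3, 0.2, seed = 43)
  S_hat <- sparsify_similarity(sim$Sd, pnn_graph(sim$Sd, 5))
  pairs <- which(S_hat > 0 & upper.tri(S_hat), arr.ind = TRUE)
  mean_dist <- function(fit) {
    mean(sqrt(rowSums((fit$A[pairs[, 1], ] - fit$A[pairs[, 2], ])^2)))
  }
  fit_on <- suppressWarnings(
    wgrmf(sim$rm, sim$Sd, sim$Sc, standard_params(lambda_d = 8)))
  fit_off <- wgrmf(sim$rm, sim$Sd, sim$Sc, standard_params(lambda_d = 0))
  expect_lt(mean_dist(fit_on), mean_dist(fit_off))
})

test_that("fits are bit-deterministic and singular systems are explained", {
  sim <- simulate_drug_response(10, 12, 2, 0.2, 0.3, seed = 51)
  f1 <- wgrmf(sim$rm, sim$Sd, sim$Sc, standard_params(seed = 5))
  f2 <- wgrmf(sim$rm, sim$Sd, sim$Sc, standard_params(seed = 5))
  expect_identical(f1$objective_trajectory, f2$objective_trajectory)
  expect_identical(f1$A, f2$A)
  # lambda_l = 0 with an underdetermined row cannot be solved
  R <- matrix(rnorm(12), 3, 4)
  W <- matrix(1, 3, 4); W[1, ] <- 0                 # drug 1 fully masked
  rm <- response_matrix(R, W)
  par0 <- wgrmf_params(k = 2, lambda_l = 0, lambda_d = 0, lambda_c = 0)
  init <- wgrmf_init(rm, 2)
  expect_error(wgrmf_sweep(rm, init$A, init$B, params = par0),
               "lambda_l", class = "wgrmf_singular_error")
})

test_that("model serialization round-trips exactly", {
  sim <- simulate_drug_response(8, 10, 2, 0.2, 0.2, seed = 61)
  fit <- wgrmf(sim$rm, sim$Sd, sim$Sc, standard_params())
  path <- withr::local_tempfile(fileext = ".json")
  wgrmf_save(fit, path)
  back <- wgrmf_load(path)
  expect_equal(back$A, fit$A)
  expect_equal(back$B, fit$B)
  expect_equal(back$objective_trajectory, fit$objective_trajectory)
  expect_identical(back$drug_ids, fit$drug_ids)
  expect_identical(unclass(back$params), unclass(fit$params))
})
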