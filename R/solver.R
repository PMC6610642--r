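#' Construct a drug-by-cell-line response matrix with observation mask
#'
#' Bundles the response grid `R` (drugs in rows, cell lines in columns)
#' with the binary weight matrix `W` marking which entries are observed.
#' Masked-out entries of `R` are ignored by every downstream computation
#' (they are stored as 0 internally).
#'
#' @param R numeric matrix of responses (log-IC50 or activity-area style);
#'   `NA` entries are treated as unobserved when `W` is not supplied.
#' @param W binary matrix of the same shape, 1 = observed. Defaults to
#'   `!is.na(R)`.
#' @param drug_ids,cell_ids identifiers; default to dimnames of `R`.
#' @return an object of class `response_matrix`: a list with components
#'   `R`, `W`, `drug_ids`, `cell_ids`.
#' @export
response_matrix <- function(R, W = NULL, drug_ids = rownames(R),
                            cell_ids = colnames(R)) {
  check(is.matrix(R), "R must be a matrix")
  if (is.null(W)) W <- !is.na(R)
  W <- matrix(as.numeric(W), nrow(R), ncol(R))
  check(all(W %in% c(0, 1)), "W entries must be exactly 0 or 1")
  check(all(dim(W) == dim(R)), "R and W must have the same shape")
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(R)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(R)))
  check(!anyDuplicated(drug_ids) && !anyDuplicated(cell_ids), "ids must be unique")
  check(length(drug_ids) == nrow(R) && length(cell_ids) == ncol(R),
        "id lengths must match matrix shape")
  storage.mode(R) <- "double"
  R[W == 0] <- 0
  check(!anyNA(R), "R has missing values at observed (W = 1) positions")
  dimnames(R) <- dimnames(W) <- list(drug_ids, cell_ids)
  structure(list(R = R, W = W, drug_ids = drug_ids, cell_ids = cell_ids),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d drugs x %d cell lines, %d/%d observed (%.1f%%)\n",
              nrow(x$R), ncol(x$R), sum(x$W), length(x$W),
              100 * mean(x$W)))
  invisible(x)
}

#' Hyperparameters for the graph-regularized factorization
#'
#' @param k latent dimension (>= 1).
#' @param lambda_l Tikhonov (ridge) weight on the Frobenius norms of both
#'   factor matrices; must be > 0 for the row updates to stay well posed
#'   when a row or column loses all its observations.
#' @param lambda_d,lambda_c weights of the drug and cell-line graph
#'   regularizers (>= 0); 0 disables the corresponding graph term.
#' @param p_drug,p_cell neighbor counts of the p-NN graphs.
#' @param max_sweeps cap on alternating update sweeps.
#' @param tol relative objective-change threshold declaring convergence.
#' @param seed RNG seed used by stochastic initialization.
#' @param init `"svd"` (mean-imputed truncated SVD, deterministic) or
#'   `"gaussian"` (random factors scaled 1/sqrt(k)).
#' @param clip_negative clip negative similarity values to 0 before graph
#'   construction (recommended; the graph regularizer assumes nonnegative
#'   weights).
#' @return an object of class `wgrmf_params` (a validated list).
#' @export
wgrmf_params <- function(k = 2, lambda_l = 2^-2, lambda_d = 2^-2, lambda_c = 2^-2,
                         p_drug = 5, p_cell = 5, max_sweeps = 200, tol = 1e-5,
                         seed = 1, init = c("svd", "gaussian"),
                         clip_negative = TRUE) {
  init <- match.arg(init)
  check(k >= 1 && k == as.integer(k), "k must be a positive integer")
  check(lambda_l >= 0 && lambda_d >= 0 && lambda_c >= 0, "lambdas must be >= 0")
  check(tol > 0, "tol must be > 0")
  check(max_sweeps >= 1, "max_sweeps must be >= 1")
  structure(list(k = as.integer(k), lambda_l = lambda_l, lambda_d = lambda_d,
                 lambda_c = lambda_c, p_drug = as.integer(p_drug),
                 p_cell = as.integer(p_cell), max_sweeps = as.integer(max_sweeps),
                 tol = tol, seed = as.integer(seed), init = init,
                 clip_negative = isTRUE(clip_negative)),
            class = "wgrmf_params")
}

#' Value of the regularized factorization objective
#'
#' Computes
#' `||W o (R - A B')||_F^2 + lambda_l (||A||_F^2 + ||B||_F^2) +
#'  lambda_d Tr(A' Ld A) + lambda_c Tr(B' Lc B)`
#' where `Ld`, `Lc` are the (normalized) graph Laplacians of the
#' sparsified drug and cell-line similarities.
#'
#' @param rm a [response_matrix()].
#' @param A,B factor matrices (drugs x k, cell lines x k).
#' @param Ld_tilde,Lc_tilde Laplacian matrices; `NULL` means the
#'   corresponding graph term is absent (treated as 0).
#' @param params a [wgrmf_params()].
#' @return a single nonnegative number (for PSD Laplacians).
#' @export
wgrmf_objective <- function(rm, A, B, Ld_tilde = NULL, Lc_tilde = NULL, params) {
  check(inherits(rm, "response_matrix"), "rm must be a response_matrix")
  n <- nrow(rm$R); m <- ncol(rm$R); k <- ncol(A)
  check(nrow(A) == n && nrow(B) == m && ncol(B) == k,
        "factor shapes inconsistent with response matrix")
  resid <- rm$W * (rm$R - tcrossprod(A, B))
  val <- sum(resid^2) + params$lambda_l * (sum(A^2) + sum(B^2))
  if (!is.null(Ld_tilde) && params$lambda_d > 0) {
    check(all(dim(Ld_tilde) == c(n, n)), "Ld_tilde shape mismatch")
    val <- val + params$lambda_d * sum(A * (Ld_tilde %*% A))
  }
  if (!is.null(Lc_tilde) && params$lambda_c > 0) {
    check(all(dim(Lc_tilde) == c(m, m)), "Lc_tilde shape mismatch")
    val <- val + params$lambda_c * sum(B * (Lc_tilde %*% B))
  }
  val
}

#' Initialize latent factors
#'
#' Default strategy: unobserved entries of `R` are filled with the mean of
#' the observed entries, the rank-k truncated SVD `U S V'` is taken, and
#' the factors are `A = U S^(1/2)`, `B = V S^(1/2)`. This is deterministic
#' and gives a strong starting point for masked factorization. A random
#' Gaussian fallback (entries `N(0, 1/k)`) is selectable.
#'
#' @param rm a [response_matrix()].
#' @param k latent dimension, at most `min(n, m)`.
#' @param seed RNG seed (used only by `method = "gaussian"`).
#' @param method `"svd"` or `"gaussian"`.
#' @return list with matrices `A` (n x k) and `B` (m x k).
#' @export
wgrmf_init <- function(rm, k, seed = 1, method = c("svd", "gaussian")) {
  method <- match.arg(method)
  n <- nrow(rm$R); m <- ncol(rm$R)
  check(k >= 1 && k <= min(n, m), "k must satisfy 1 <= k <= min(n, m)")
  if (method == "gaussian") {
    return(with_seed(seed, list(
      A = matrix(rnorm(n * k, sd = 1 / sqrt(k)), n, k),
      B = matrix(rnorm(m * k, sd = 1 / sqrt(k)), m, k)
    )))
  }
  R_imp <- rm$R
  obs <- rm$W == 1
  fill <- if (any(obs)) mean(rm$R[obs]) else 0
  R_imp[!obs] <- fill
  sv <- svd(R_imp, nu = k, nv = k)
  s_half <- sqrt(sv$d[seq_len(k)])
  list(A = sv$u * rep(s_half, each = n),
       B = sv$v * rep(s_half, each = m))
}

#' One alternating update sweep over all drug rows then all cell-line rows
#'
#' Each drug's latent row is set to the solution of the k x k linear
#' system
#' `a_i [ sum_j W(i,j) b_j b_j' + (lambda_l + lambda_d Ld_tilde(i,i)) I ] =
#'  sum_j W(i,j) R(i,j) b_j - lambda_d sum_{r != i} Ld_tilde(i,r) a_r`,
#' then each cell line's row symmetrically. This is exact block
#' coordinate descent on [wgrmf_objective()]: each row update minimizes
#' the objective in that row given all others, so the objective never
#' increases and fixed points of the sweep are exactly the objective's
#' stationary points. Updates are Gauss-Seidel: the Laplacian coupling
#' term uses rows already updated in the current sweep. (Keeping the
#' diagonal Laplacian contribution on the right-hand side instead gives
#' the same fixed points but only a fixed-point iteration, which can
#' oscillate or diverge when the graph weight rivals the ridge weight.)
#'
#' @inheritParams wgrmf_objective
#' @return list with updated `A` and `B`.
#' @export
wgrmf_sweep <- function(rm, A, B, Ld_tilde = NULL, Lc_tilde = NULL, params) {
  n <- nrow(rm$R); m <- ncol(rm$R); k <- ncol(A)
  check(nrow(A) == n && nrow(B) == m && ncol(B) == k,
        "factor shapes inconsistent with response matrix")
  Ik <- diag(params$lambda_l, k)
  solve_row <- function(G, rhs) {
    tryCatch(solve(G, rhs),
             error = function(e) stop(errorCondition(
               paste0("singular row system (too few observations); ",
                      "set lambda_l > 0: ", conditionMessage(e)),
               class = c("wgrmf_singular_error", "error"))))
  }
  for (i in seq_len(n)) {
    w <- rm$W[i, ]
    Bw <- B * w
    G <- crossprod(B, Bw) + Ik
    rhs <- as.numeric(crossprod(Bw, rm$R[i, ]))
    if (!is.null(Ld_tilde) && params$lambda_d > 0) {
      lt <- Ld_tilde[i, ]
      rhs <- rhs - params$lambda_d * (as.numeric(lt %*% A) - lt[i] * A[i, ])
      G <- G + diag(params$lambda_d * lt[i], k)
    }
    A[i, ] <- solve_row(G, rhs)
  }
  for (j in seq_len(m)) {
    w <- rm$W[, j]
    Aw <- A * w
    G <- crossprod(A, Aw) + Ik
    rhs <- as.numeric(crossprod(Aw, rm$R[, j]))
    if (!is.null(Lc_tilde) && params$lambda_c > 0) {
      lt <- Lc_tilde[j, ]
      rhs <- rhs - params$lambda_c * (as.numeric(lt %*% B) - lt[j] * B[j, ])
      G <- G + diag(params$lambda_c * lt[j], k)
    }
    B[j, ] <- solve_row(G, rhs)
  }
  list(A = A, B = B)
}

#' Fit the weighted graph-regularized factorization
#'
#' End-to-end fit: builds p-nearest-neighbor graphs from the drug and
#' cell-line similarity matrices, sparsifies them, forms normalized graph
#' Laplacians, initializes the factors, and runs alternating row-wise
#' update sweeps until the relative change of the objective drops below
#' `params$tol` or `params$max_sweeps` is reached.
#'
#' @param rm a [response_matrix()]; every value the model learns from has
#'   `W = 1` there.
#' @param Sd,Sc drug and cell-line similarity matrices
#'   (see [similarity_matrix()]); pass `NULL` to drop the corresponding
#'   graph term regardless of its lambda.
#' @param params a [wgrmf_params()].
#' @return an object of class `wgrmf`: factors `A`, `B`, the
#'   `objective_trajectory` (length `sweeps_run + 1`, initial value
#'   included), `converged`, `sweeps_run`, ids and `params`.
#' @export
wgrmf <- function(rm, Sd = NULL, Sc = NULL, params = wgrmf_params()) {
  check(inherits(rm, "response_matrix"), "rm must be a response_matrix")
  check(inherits(params, "wgrmf_params"), "params must come from wgrmf_params()")
  n <- nrow(rm$R); m <- ncol(rm$R)
  Ld_tilde <- Lc_tilde <- NULL
  if (!is.null(Sd) && params$lambda_d > 0) {
    check(nrow(Sd) == n, "Sd dimension must match drug count")
    Ld_tilde <- similarity_to_laplacian(Sd, params$p_drug,
                                        params$clip_negative)$L_tilde
  }
  if (!is.null(Sc) && params$lambda_c > 0) {
    check(nrow(Sc) == m, "Sc dimension must match cell-line count")
    Lc_tilde <- similarity_to_laplacian(Sc, params$p_cell,
                                        params$clip_negative)$L_tilde
  }
  fac <- wgrmf_init(rm, params$k, params$seed, params$init)
  A <- fac$A; B <- fac$B
  obj <- wgrmf_objective(rm, A, B, Ld_tilde, Lc_tilde, params)
  trajectory <- obj
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(params$max_sweeps)) {
    fac <- wgrmf_sweep(rm, A, B, Ld_tilde, Lc_tilde, params)
    A <- fac$A; B <- fac$B
    obj_new <- wgrmf_objective(rm, A, B, Ld_tilde, Lc_tilde, params)
    trajectory <- c(trajectory, obj_new)
    sweeps <- s
    if (!is.finite(obj_new)) {
      warning("objective became non-finite; stopping early")
      break
    }
    if (obj_new > obj + 1e-12 * max(1, abs(obj))) {
      warning(sprintf("objective increased at sweep %d (%.6g -> %.6g)",
                      s, obj, obj_new))
    }
    rel <- abs(obj - obj_new) / max(abs(obj), .Machine$double.eps)
    obj <- obj_new
    if (rel < params$tol) {
      converged <- TRUE
      break
    }
  }
  rownames(A) <- rm$drug_ids
  rownames(B) <- rm$cell_ids
  structure(list(A = A, B = B, objective_trajectory = trajectory,
                 converged = converged, sweeps_run = sweeps,
                 drug_ids = rm$drug_ids, cell_ids = rm$cell_ids,
                 params = params),
            class = "wgrmf")
}

#' @export
print.wgrmf <- function(x, ...) {
  cat(sprintf(paste0("wgrmf fit: %d drugs x %d cell lines, k = %d\n",
                     "  objective %.6g -> %.6g in %d sweeps (%s)\n"),
              nrow(x$A), nrow(x$B), ncol(x$A),
              x$objective_trajectory[1],
              x$objective_trajectory[length(x$objective_trajectory)],
              x$sweeps_run,
              if (x$converged) "converged" else "max sweeps reached"))
  invisible(x)
}

#' Predicted response matrix from fitted factors
#'
#' @param object a fitted `wgrmf` object.
#' @param ... unused.
#' @return the n x m matrix `A B'` with drug/cell-line dimnames.
#' @export
predict.wgrmf <- function(object, ...) {
  R_hat <- tcrossprod(object$A, object$B)
  dimnames(R_hat) <- list(object$drug_ids, object$cell_ids)
  R_hat
}

#' Serialize a fitted model to JSON
#'
#' Writes factors, hyperparameters, identifiers and the objective
#' trajectory to a single JSON file at full double precision, so that
#' [wgrmf_load()] round-trips the model exactly.
#'
#' @param fit a `wgrmf` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
wgrmf_save <- function(fit, path) {
  check(inherits(fit, "wgrmf"), "fit must be a wgrmf object")
  payload <- list(
    A = unname(fit$A), B = unname(fit$B),
    objective_trajectory = fit$objective_trajectory,
    converged = fit$converged, sweeps_run = fit$sweeps_run,
    drug_ids = fit$drug_ids, cell_ids = fit$cell_ids,
    params = unclass(fit$params)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path file written by [wgrmf_save()].
#' @return a `wgrmf` object.
#' @export
wgrmf_load <- function(path) {
  check(file.exists(path), "model file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(wgrmf_params, x$params[names(x$params) != ""])
  A <- as.matrix(x$A); B <- as.matrix(x$B)
  rownames(A) <- x$drug_ids
  rownames(B) <- x$cell_ids
  structure(list(A = A, B = B,
                 objective_trajectory = as.numeric(x$objective_trajectory),
                 converged = isTRUE(x$converged),
                 sweeps_run = as.integer(x$sweeps_run),
                 drug_ids = x$drug_ids, cell_ids = x$cell_ids,
                 params = params),
            class = "wgrmf")
}
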