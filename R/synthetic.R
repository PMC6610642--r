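#' Simulate a drug-response dataset with low-rank structure
#'
#' Generates the statistical structure the factorization model assumes:
#' a rank-`k_true` ground-truth response matrix `truth_R = A B'` with
#' standard-Gaussian factors, additive Gaussian noise scaled to the
#' spread of the truth, an observation mask at a configurable missing
#' fraction (exact count, sampled uniformly), and drug / cell-line
#' similarity matrices derived from the true factors. Similarity is the
#' cosine between factor rows mapped to `[0, 1]` via `(1 + cos) / 2`, so
#' entities close in the latent space are similar by construction — the
#' local-invariance assumption the graph regularizer relies on holds
#' exactly, isolating solver behavior from similarity quality.
#'
#' @param n,m numbers of drugs and cell lines.
#' @param k_true generating rank, at most `min(n, m)`.
#' @param noise_sd noise level as a fraction of `sd(truth_R)`.
#' @param missing_fraction fraction of entries masked, in `[0, 1)`.
#' @param seed RNG seed; the dataset is a deterministic function of it.
#' @return object of class `wgrmf_sim`: `rm` (a [response_matrix()]),
#'   `Sd`, `Sc` (similarity matrices), `truth_A`, `truth_B`, `truth_R`,
#'   and `gen_params`.
#' @export
simulate_drug_response <- function(n = 25, m = 40, k_true = 2, noise_sd = 0.1,
                                   missing_fraction = 0.2, seed = 1) {
  check(k_true >= 1 && k_true <= min(n, m), "k_true must be in [1, min(n, m)]")
  check(missing_fraction >= 0 && missing_fraction < 1,
        "missing_fraction must be in [0, 1)")
  with_seed(seed, {
    drug_ids <- sprintf("drug%02d", seq_len(n))
    cell_ids <- sprintf("cell%02d", seq_len(m))
    A <- matrix(rnorm(n * k_true), n, k_true, dimnames = list(drug_ids, NULL))
    B <- matrix(rnorm(m * k_true), m, k_true, dimnames = list(cell_ids, NULL))
    truth_R <- tcrossprod(A, B)
    dimnames(truth_R) <- list(drug_ids, cell_ids)
    R <- truth_R + matrix(rnorm(n * m, sd = noise_sd * stats::sd(truth_R)), n, m)
    W <- matrix(1, n, m)
    n_miss <- round(missing_fraction * n * m)
    if (n_miss > 0) W[sample.int(n * m, n_miss)] <- 0
    rm <- response_matrix(R, W, drug_ids, cell_ids)
    Sd <- similarity_matrix(factor_cosine_similarity(A), drug_ids, "drug")
    Sc <- similarity_matrix(factor_cosine_similarity(B), cell_ids, "cell_line")
    structure(list(rm = rm, Sd = Sd, Sc = Sc,
                   truth_A = A, truth_B = B, truth_R = truth_R,
                   gen_params = list(n = n, m = m, k_true = k_true,
                                     noise_sd = noise_sd,
                                     missing_fraction = missing_fraction,
                                     seed = seed)),
              class = "wgrmf_sim")
  })
}

# internal: cosine similarity between rows, mapped from [-1, 1] to [0, 1]
factor_cosine_similarity <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  C <- tcrossprod(X / nrm)
  C[C > 1] <- 1; C[C < -1] <- -1
  S <- (1 + C) / 2
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Simulate binary drug fingerprints
#'
#' Convenience generator for exercising the Jaccard similarity path end
#' to end: Gaussian feature loadings thresholded at 0 give binary
#' vectors. This emulates the format, not the statistics, of real
#' chemical fingerprints. Rows that would be all-zero (or all-one) are
#' resampled so every fingerprint is valid.
#'
#' @param n number of drugs.
#' @param bits fingerprint length.
#' @param seed RNG seed.
#' @return binary matrix `n x bits` with drug ids as rownames.
#' @export
simulate_fingerprints <- function(n = 25, bits = 64, seed = 1) {
  with_seed(seed, {
    fp <- matrix(as.numeric(matrix(rnorm(n * bits), n, bits) > 0), n, bits)
    bad <- rowSums(fp) %in% c(0, bits)
    while (any(bad)) {
      fp[bad, ] <- as.numeric(matrix(rnorm(sum(bad) * bits), sum(bad), bits) > 0)
      bad <- rowSums(fp) %in% c(0, bits)
    }
    rownames(fp) <- sprintf("drug%02d", seq_len(n))
    fp
  })
}
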