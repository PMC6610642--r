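#' Jaccard similarity between binary fingerprints
#'
#' Computes the pairwise Jaccard coefficient |bits_i AND bits_j| /
#' |bits_i OR bits_j| between rows of a binary fingerprint matrix, the
#' standard choice for chemical-substructure fingerprints (e.g. PubChem
#' bit vectors). The result is exactly symmetric with unit diagonal.
#'
#' @param fingerprints numeric matrix, drugs in rows, fingerprint bits in
#'   columns; entries must be exactly 0 or 1; rownames are the drug ids.
#' @return a symmetric numeric matrix with entries in \[0, 1\], unit
#'   diagonal, dimnames set to the drug ids, and attribute
#'   `kind = "drug"`.
#' @details An entity whose fingerprint is all zeros has an undefined
#'   Jaccard coefficient against another all-zero entity (0/0), so
#'   all-zero fingerprints are rejected with an error naming the entity.
#' @examples
#' fp <- rbind(d1 = c(1, 1, 0, 0), d2 = c(1, 0, 1, 0))
#' jaccard_similarity(fp)  # off-diagonal 1/3
#' @export
jaccard_similarity <- function(fingerprints) {
  fingerprints <- as_feature_table(fingerprints, kind = "binary_fingerprint")
  check(nrow(fingerprints) >= 2L, "need at least 2 entities")
  zero <- rowSums(fingerprints) == 0
  if (any(zero)) {
    check(FALSE, "all-zero fingerprint for entity: ",
          paste(rownames(fingerprints)[zero], collapse = ", "))
  }
  inter <- tcrossprod(fingerprints)          # |i AND j|
  n_bits <- rowSums(fingerprints)
  uni <- outer(n_bits, n_bits, "+") - inter  # |i OR j|
  S <- inter / uni
  S <- (S + t(S)) / 2
  diag(S) <- 1
  similarity_matrix(S, rownames(fingerprints), kind = "drug")
}

#' Pearson similarity between continuous profiles
#'
#' Computes the pairwise Pearson correlation between rows of a continuous
#' feature matrix, as used for cell-line gene-expression profiles. The
#' result is symmetrized numerically and has unit diagonal.
#'
#' @param profiles numeric matrix, entities in rows, features in columns;
#'   rownames are the entity ids. Missing values are rejected.
#' @param clip_negative if `TRUE`, negative correlations are clipped to 0.
#'   Defaults to `FALSE` (correlations kept as computed).
#' @return a symmetric numeric matrix with entries in \[-1, 1\] (or
#'   \[0, 1\] when clipped), unit diagonal, attribute `kind = "cell_line"`.
#' @export
pearson_similarity <- function(profiles, clip_negative = FALSE) {
  profiles <- as_feature_table(profiles, kind = "continuous_profile")
  check(nrow(profiles) >= 2L, "need at least 2 entities")
  check(ncol(profiles) >= 2L, "need at least 2 features")
  v <- apply(profiles, 1L, stats::var)
  if (any(v == 0)) {
    check(FALSE, "zero-variance profile for entity: ",
          paste(rownames(profiles)[v == 0], collapse = ", "))
  }
  S <- stats::cor(t(profiles))
  if (clip_negative) S[S < 0] <- 0
  S <- (S + t(S)) / 2
  diag(S) <- 1
  similarity_matrix(S, rownames(profiles), kind = "cell_line")
}

# internal: validate / coerce a feature table
as_feature_table <- function(x, kind) {
  check(is.matrix(x) || is.data.frame(x), "feature table must be a matrix")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("e", seq_len(nrow(x)))
  check(!anyDuplicated(rownames(x)), "entity ids must be unique")
  check(!anyNA(x), "feature table contains missing values; impute or drop upstream")
  if (kind == "binary_fingerprint") {
    check(all(x %in% c(0, 1)), "fingerprint entries must be exactly 0 or 1")
  }
  x
}

#' Construct a similarity matrix object
#'
#' Light wrapper that validates symmetry and attaches entity ids and a
#' `kind` attribute (`"drug"` or `"cell_line"`). Used by the similarity
#' builders and accepted everywhere a similarity matrix is an input.
#'
#' @param S square numeric matrix.
#' @param ids entity identifiers (defaults to existing rownames).
#' @param kind `"drug"` or `"cell_line"`.
#' @param tol asymmetry tolerance before symmetrization is refused.
#' @return `S` with dimnames set and attribute `kind`, exactly symmetric.
#' @export
similarity_matrix <- function(S, ids = rownames(S), kind = c("drug", "cell_line"),
                              tol = 1e-8) {
  kind <- match.arg(kind)
  check(is.matrix(S) && nrow(S) == ncol(S), "similarity matrix must be square")
  check(!anyNA(S), "similarity matrix contains missing values")
  check(max(abs(S - t(S))) <= tol, "similarity matrix is not symmetric")
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(S)))
  check(length(ids) == nrow(S), "ids length must match matrix dimension")
  check(!anyDuplicated(ids), "entity ids must be unique")
  S <- (S + t(S)) / 2
  dimnames(S) <- list(ids, ids)
  attr(S, "kind") <- kind
  S
}
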