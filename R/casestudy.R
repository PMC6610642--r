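#' Rank a drug's unmeasured cell lines by predicted sensitivity
#'
#' Selects the cell lines with no observed response to the given drug,
#' orders them most-sensitive-first under the declared response
#' orientation of the predicted values, and returns the top `top_n`.
#' Used to nominate candidate sensitive cell lines for follow-up.
#'
#' @param rm a [response_matrix()].
#' @param R_hat predicted response grid, e.g. from [predict.wgrmf()].
#' @param drug_id identifier of the drug row.
#' @param top_n maximum number of cell lines to return (default 20).
#' @param orientation `"sensitive_low"` (IC50-like) or
#'   `"sensitive_high"` (activity-area-like).
#' @return data.frame with columns `cell_id` and `predicted`, ordered
#'   most sensitive first; zero rows (with a message) when the drug is
#'   fully observed.
#' @export
rank_unmeasured <- function(rm, R_hat, drug_id, top_n = 20,
                            orientation = c("sensitive_low",
                                            "sensitive_high")) {
  orientation <- match.arg(orientation)
  check(inherits(rm, "response_matrix"), "rm must be a response_matrix")
  check(all(dim(R_hat) == dim(rm$R)), "R_hat shape must match the response matrix")
  i <- match(drug_id, rm$drug_ids)
  check(!is.na(i), "unknown drug id: ", drug_id)
  unobserved <- which(rm$W[i, ] == 0)
  if (length(unobserved) == 0) {
    message(sprintf("drug %s is fully observed; nothing to rank", drug_id))
    return(data.frame(cell_id = character(0), predicted = numeric(0)))
  }
  pred <- R_hat[i, unobserved]
  ord <- if (orientation == "sensitive_low") {
    order(pred, seq_along(pred))
  } else {
    order(-pred, seq_along(pred))
  }
  take <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(cell_id = rm$cell_ids[unobserved][take],
             predicted = unname(pred[take]),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of two response groups
#'
#' Two-sided rank-sum (Mann-Whitney) test between two groups of response
#' values, e.g. mutated versus wild-type cell lines for one drug. Ties
#' get midranks. For combined sample size up to 20 the null distribution
#' of the rank sum is enumerated exhaustively over all group-label
#' assignments (conditional on the observed midranks); above that a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param values_a,values_b numeric response vectors, both non-empty,
#'   combined length >= 3.
#' @param method `"auto"` (enumerate iff combined n <= 20), `"exact"` or
#'   `"approx"`.
#' @return object of class `wgrmf_ranksum`: `statistic` (rank sum of
#'   group a), `p_value` (two-sided), `method`, `n_a`, `n_b`.
#' @export
ranksum_test <- function(values_a, values_b,
                         method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  check(length(values_a) >= 1L && length(values_b) >= 1L,
        "both groups must be non-empty")
  na <- length(values_a); nb <- length(values_b); n <- na + nb
  check(n >= 3L, "combined sample size must be >= 3")
  if (method == "auto") method <- if (n <= 20L) "exact" else "approx"
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)                      # midranks for ties
  w <- sum(rk[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (method == "exact") {
    sums <- colSums(matrix(rk[combn(n, na)], nrow = na))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1                               # all values tied: no evidence
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)   # continuity-corrected
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n_a = na, n_b = nb),
            class = "wgrmf_ranksum")
}

#' @export
print.wgrmf_ranksum <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): W = %g, n = %d + %d, two-sided p = %.4g\n",
              x$method, x$statistic, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' Compare predicted responses between annotated cell-line groups
#'
#' Splits one drug's response values (observed, predicted, or both) by a
#' two-column status table (cell line id, status) and runs
#' [ranksum_test()] between the two status groups — the consistency
#' check used to relate, e.g., gene-mutation status to drug sensitivity.
#'
#' @param responses named numeric vector of response values for one drug
#'   (names = cell-line ids).
#' @param status data.frame with columns `cell_id` and `status`; `status`
#'   must take exactly 2 distinct values among the cells present in
#'   `responses`.
#' @return a `wgrmf_ranksum` with attribute `"groups"` naming the two
#'   status levels (group a first).
#' @export
group_compare <- function(responses, status) {
  check(is.data.frame(status) && all(c("cell_id", "status") %in% names(status)),
        "status must have columns cell_id and status")
  keep <- status$cell_id %in% names(responses)
  status <- status[keep, , drop = FALSE]
  lev <- sort(unique(as.character(status$status)))
  check(length(lev) == 2L, "status must have exactly 2 levels among scored cells")
  a <- responses[status$cell_id[status$status == lev[1]]]
  b <- responses[status$cell_id[status$status == lev[2]]]
  out <- ranksum_test(a, b)
  attr(out, "groups") <- lev
  out
}
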