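#' Pearson correlation between observed and predicted responses
#'
#' Direct textbook formula: centered cross-product over the product of
#' centered norms, computed on the `nd` known responses of one drug.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return a number in `[-1, 1]`, or `NA` when either vector has zero
#'   variance (undefined correlation; callers exclude and count these).
#' @export
pcc <- function(observed, predicted) {
  check(length(observed) == length(predicted), "length mismatch")
  check(length(observed) >= 2L, "need at least 2 paired values")
  o <- observed - mean(observed)
  p <- predicted - mean(predicted)
  denom <- sqrt(sum(o^2)) * sqrt(sum(p^2))
  if (denom == 0) return(NA_real_)
  sum(o * p) / denom
}

#' Root-mean-square error between observed and predicted responses
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  check(length(observed) == length(predicted), "length mismatch")
  check(length(observed) >= 1L, "need at least 1 paired value")
  sqrt(mean((observed - predicted)^2))
}

#' Sensitive and resistant quartiles of a drug's response profile
#'
#' Ranks the observed responses, splits into four equal parts of size
#' `floor(nd / 4)`, and returns the extreme quartiles: the most sensitive
#' and the most resistant cell lines. For IC50-like data lower values
#' mean sensitive (`orientation = "sensitive_low"`, the default); for
#' activity-area-like data use `"sensitive_high"`. Ties are broken by
#' input order, so the split is deterministic.
#'
#' @param responses named numeric vector of one drug's observed
#'   responses (names = cell-line ids).
#' @param orientation `"sensitive_low"` or `"sensitive_high"`.
#' @return list with character vectors `sensitive` and `resistant`,
#'   each of length `floor(length(responses) / 4)`.
#' @export
sensitive_resistant_split <- function(responses,
                                      orientation = c("sensitive_low",
                                                      "sensitive_high")) {
  orientation <- match.arg(orientation)
  nd <- length(responses)
  check(nd >= 4L, "need at least 4 observed responses for a quartile split")
  ids <- names(responses)
  if (is.null(ids)) ids <- as.character(seq_len(nd))
  q <- nd %/% 4L
  ord <- order(responses, seq_len(nd))   # ascending, ties by input order
  low <- ids[ord[seq_len(q)]]
  high <- ids[ord[seq(nd - q + 1L, nd)]]
  if (orientation == "sensitive_low") {
    list(sensitive = low, resistant = high)
  } else {
    list(sensitive = high, resistant = low)
  }
}

# internal: per-drug metric table for one repeat, given the full matrices
# of observed and held-out-predicted values (entries with W = 0 are NA)
per_drug_metrics <- function(obs_mat, pred_mat, orientation) {
  drugs <- rownames(obs_mat)
  out <- data.frame(drug = drugs, pcc = NA_real_, rmse = NA_real_,
                    pcc_sr = NA_real_, rmse_sr = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(drugs)) {
    keep <- !is.na(obs_mat[i, ])
    o <- obs_mat[i, keep]
    p <- pred_mat[i, keep]
    if (length(o) >= 2L) {
      out$pcc[i] <- pcc(o, p)
      out$rmse[i] <- rmse(o, p)
    }
    if (length(o) >= 4L) {
      sr <- sensitive_resistant_split(o, orientation)
      idx <- c(sr$sensitive, sr$resistant)
      out$pcc_sr[i] <- pcc(o[idx], p[idx])
      out$rmse_sr[i] <- rmse(o[idx], p[idx])
    }
  }
  out
}

#' Repeated entry-wise k-fold cross-validation
#'
#' The observed entries (not rows or columns) of the response matrix are
#' partitioned into `n_folds` near-equal subsets. Each fold in turn is
#' masked out, the model refit on the remaining observations, and the
#' held-out entries predicted. Once all folds are done every observed
#' entry has exactly one held-out prediction; per-drug PCC, RMSE and
#' their sensitive/resistant-quartile restrictions (PCCsr, RMSEsr) are
#' computed from these assembled pairs. The whole procedure is repeated
#' `n_repeats` times with distinct partitions derived from `seed`, and
#' the summary reports the mean and SD across repeats of the
#' drug-averaged metrics.
#'
#' @inheritParams wgrmf
#' @param n_folds number of folds (default 10).
#' @param n_repeats number of independent repetitions of the full CV.
#' @param seed master seed; every partition is derived from it.
#' @param orientation response orientation for the quartile split, see
#'   [sensitive_resistant_split()].
#' @return object of class `wgrmf_cv`: `per_drug` (drug x repeat metric
#'   table), `summary` (metric, mean, sd), `fold_assignments` (per
#'   repeat, fold index of each observed entry), `params`,
#'   `n_undefined_pcc` (count of drug/repeat cells excluded for
#'   zero-variance predictions).
#' @export
wgrmf_cv <- function(rm, Sd = NULL, Sc = NULL, params = wgrmf_params(),
                     n_folds = 10, n_repeats = 1, seed = 1,
                     orientation = c("sensitive_low", "sensitive_high")) {
  orientation <- match.arg(orientation)
  check(inherits(rm, "response_matrix"), "rm must be a response_matrix")
  obs_idx <- which(rm$W == 1)
  check(n_folds >= 2L, "n_folds must be >= 2")
  check(length(obs_idx) >= n_folds, "need at least n_folds observed entries")
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_repeats))
  per_drug <- NULL
  fold_assignments <- vector("list", n_repeats)
  n_undefined <- 0L
  obs_template <- rm$R
  obs_template[rm$W == 0] <- NA
  for (r in seq_len(n_repeats)) {
    perm <- with_seed(rep_seeds[r], sample(obs_idx))
    fold_of <- rep_len(seq_len(n_folds), length(obs_idx))
    folds <- split(perm, fold_of)
    assignment <- integer(length(obs_idx))
    assignment[match(perm, obs_idx)] <- fold_of
    fold_assignments[[r]] <- assignment
    pred_mat <- matrix(NA_real_, nrow(rm$R), ncol(rm$R),
                       dimnames = dimnames(rm$R))
    for (f in seq_len(n_folds)) {
      test_idx <- folds[[f]]
      W_train <- rm$W
      W_train[test_idx] <- 0
      check(sum(W_train) > 0, "a fold left zero training entries")
      rm_train <- response_matrix(rm$R, W_train, rm$drug_ids, rm$cell_ids)
      fit <- wgrmf(rm_train, Sd, Sc, params)
      R_hat <- predict(fit)
      pred_mat[test_idx] <- R_hat[test_idx]
    }
    tab <- per_drug_metrics(obs_template, pred_mat, orientation)
    tab <- cbind(rep = r, tab)
    n_undefined <- n_undefined + sum(is.na(tab$pcc))
    per_drug <- rbind(per_drug, tab)
  }
  if (n_undefined > 0) {
    message(sprintf("%d drug/repeat cells had undefined PCC and were excluded",
                    n_undefined))
  }
  metrics <- c("pcc", "rmse", "pcc_sr", "rmse_sr")
  by_rep <- sapply(metrics, function(mname) {
    tapply(per_drug[[mname]], per_drug$rep,
           function(v) mean(v, na.rm = TRUE))
  })
  by_rep <- matrix(by_rep, nrow = n_repeats,
                   dimnames = list(NULL, metrics))
  summary_tab <- data.frame(
    metric = metrics,
    mean = colMeans(by_rep),
    sd = apply(by_rep, 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_drug = per_drug, summary = summary_tab,
                 by_repeat = as.data.frame(by_rep),
                 fold_assignments = fold_assignments,
                 observed_index = obs_idx,
                 params = params, n_folds = n_folds, n_repeats = n_repeats,
                 seed = seed, orientation = orientation,
                 n_undefined_pcc = n_undefined),
            class = "wgrmf_cv")
}

#' @export
print.wgrmf_cv <- function(x, ...) {
  cat(sprintf("wgrmf cross-validation: %d folds x %d repeats\n",
              x$n_folds, x$n_repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  drug-averaged %-7s %.4f +/- %s\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), "NA", sprintf("%.4f", s$sd[i]))))
  }
  invisible(x)
}

#' Exhaustive hyperparameter grid search by cross-validation
#'
#' Evaluates every combination of the supplied grids by k-fold
#' cross-validation on the given (training) data and returns the
#' combination maximizing the drug-averaged PCC. When called on the
#' training portion inside an outer CV this yields a nested, leak-free
#' selection. Ties are broken toward larger `lambda_l`, then smaller `k`
#' (prefer the stronger regularization). Combinations whose evaluation
#' fails are excluded with a warning.
#'
#' @inheritParams wgrmf_cv
#' @param grids named list of candidate values; recognized names are the
#'   fields of [wgrmf_params()] (e.g. `k`, `lambda_l`, `lambda_d`,
#'   `lambda_c`, `p_drug`, `p_cell`). Unlisted fields are taken from
#'   `params`.
#' @return the selected `wgrmf_params`, with the full evaluation table in
#'   attribute `"results"`.
#' @export
wgrmf_grid_search <- function(rm, Sd = NULL, Sc = NULL, grids,
                              params = wgrmf_params(), n_folds = 10,
                              seed = 1) {
  check(is.list(grids) && length(grids) > 0, "grids must be a non-empty list")
  check(all(lengths(grids) > 0), "every grid must be non-empty")
  known <- names(formals(wgrmf_params))
  bad <- setdiff(names(grids), known)
  check(length(bad) == 0, "unknown grid parameter: ", paste(bad, collapse = ", "))
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p_i <- unclass(params)
    p_i[names(combos)] <- as.list(combos[i, , drop = FALSE])
    p_i <- do.call(wgrmf_params, p_i[known[known %in% names(p_i)]])
    scores[i] <- tryCatch({
      cv <- suppressWarnings(suppressMessages(
        wgrmf_cv(rm, Sd, Sc, p_i, n_folds = n_folds, n_repeats = 1,
                 seed = seed)))
      cv$summary$mean[cv$summary$metric == "pcc"]
    }, error = function(e) {
      warning(sprintf("grid cell %d failed: %s", i, conditionMessage(e)))
      NA_real_
    })
  }
  check(any(!is.na(scores)), "every grid combination failed")
  lambda_l_col <- if ("lambda_l" %in% names(combos)) combos$lambda_l else
    rep(params$lambda_l, nrow(combos))
  k_col <- if ("k" %in% names(combos)) combos$k else rep(params$k, nrow(combos))
  score_key <- round(scores, 12)
  ord <- order(-score_key, -lambda_l_col, k_col, na.last = TRUE)
  best <- ord[1]
  p_best <- unclass(params)
  p_best[names(combos)] <- as.list(combos[best, , drop = FALSE])
  p_best <- do.call(wgrmf_params, p_best[known[known %in% names(p_best)]])
  attr(p_best, "results") <- cbind(combos, pcc = scores)
  p_best
}
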