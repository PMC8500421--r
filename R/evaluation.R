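#' Factorial sweep of indices and model kinds
#'
#' Fits every requested (index, model kind) combination on the same
#' season table, and reports conventional goodness of fit (R-squared,
#' RMSE) alongside the welfare-based quality metrics (RIB, AFP, premium,
#' payout-error class counts) for each resulting contract.  Failures of
#' individual combinations are recorded in the row's `error` column
#' rather than aborting the sweep.
#'
#' @param data Season table containing a mortality column and the raw
#'   index columns.
#' @param indices Character vector of index column names.
#' @param kinds Character vector of model kinds (see [loss_model()]).
#' @param terms A [contract_terms()].
#' @param rho Relative risk aversion for the welfare evaluation.
#' @param standardize Logical; z-score each index per location before
#'   fitting (default `TRUE`).  Columns already standardized can be
#'   swept with `standardize = FALSE`.
#' @param log_indices Subset of `indices` to log-transform before
#'   standardization.
#' @param tau Quantile level passed to `kind = "qr"` fits.
#' @return A `data.frame` of class `"rib_sweep"`, one row per (index,
#'   kind): `r_squared`, `rmse`, `RIB`, `afp`, `premium`, the five class
#'   counts, and `error` (`NA` on success).
#' @export
rib_sweep <- function(data, indices, kinds = c("lm", "lm0", "lm5", "sm"),
                      terms = contract_terms(), rho = 2,
                      standardize = TRUE, log_indices = character(),
                      tau = 0.77) {
  if (length(indices) == 0L || length(kinds) == 0L) {
    stop("need at least one index and one model kind")
  }
  missing_idx <- setdiff(indices, names(data))
  if (length(missing_idx) > 0L) {
    stop("index column(s) not in data: ",
         paste(missing_idx, collapse = ", "))
  }
  rows <- list()
  for (idx in indices) {
    prep_err <- NULL
    if (standardize) {
      d <- tryCatch(zscore_index(data, idx, log = idx %in% log_indices),
                    error = function(e) {
                      prep_err <<- conditionMessage(e)
                      NULL
                    })
      zcol <- paste0("z_", idx)
    } else {
      d <- data
      zcol <- idx
    }
    for (kind in kinds) {
      row <- data.frame(index = idx, kind = kind, r_squared = NA_real_,
                        rmse = NA_real_, RIB = NA_real_, afp = NA_real_,
                        premium = NA_real_, TN = NA_integer_,
                        FP = NA_integer_, FN_small = NA_integer_,
                        FN_intermediate = NA_integer_,
                        FN_severe = NA_integer_, error = NA_character_,
                        stringsAsFactors = FALSE)
      res <- if (!is.null(prep_err)) {
        simpleError(prep_err)
      } else tryCatch({
        fit <- loss_model(stats::reformulate(zcol, "mortality"), d,
                          kind = kind, tau = tau)
        gof <- goodness_of_fit(fit, d)
        ev <- evaluate_contract(d, model = fit, terms = terms, rho = rho)
        cc <- as.integer(ev$class_counts)
        names(cc) <- names(ev$class_counts)
        list(gof = gof, ev = ev, cc = cc)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$r_squared <- res$gof$r_squared
        row$rmse <- res$gof$rmse
        row$RIB <- res$ev$welfare$RIB
        row$afp <- res$ev$pricing$afp_index
        row$premium <- res$ev$pricing$premium_index
        for (cl in names(res$cc)) row[[cl]] <- res$cc[[cl]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$RIB, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("rib_sweep", "data.frame")
  out
}

#' K-fold cross-validated goodness of fit and RIB
#'
#' Randomly partitions the location-season records into `k` folds
#' (seeded), refits the loss model on each training split, and pools the
#' out-of-fold predictions so every record is predicted exactly once.
#' R-squared and the RIB are then computed once on the pooled out-of-fold
#' series.  By default the index-contract premium applied to each record
#' is re-priced from its fold's training payouts (`pricing =
#' "per_fold"`); `pricing = "pooled"` prices once from the pooled
#' out-of-fold payouts.  The perfect contract is always priced on the
#' full sample.
#'
#' @param data Season table.
#' @param index Index column name (standardized per location before
#'   fitting unless `standardize = FALSE`).
#' @param kind Model kind (see [loss_model()]).
#' @param terms A [contract_terms()].
#' @param rho Relative risk aversion.
#' @param k Number of folds (default 5; `k = nrow(data)` gives
#'   leave-one-out).
#' @param seed Integer seed for the fold assignment.
#' @param block_by Optional column name (e.g. `"location"`): assign whole
#'   blocks to folds instead of individual records (spatially blocked
#'   CV).
#' @param pricing `"per_fold"` (default) or `"pooled"`.
#' @param standardize,log_index,tau As in [rib_sweep()].
#' @return A list of class `"rib_cv"`: `k`, `seed`, `folds` (assignment
#'   vector), `r_squared` and `RIB` (pooled out-of-fold),
#'   `r_squared_insample` and `RIB_insample`, `fold_r_squared` (per
#'   fold, on that fold's held-out records), and the pooled predictions.
#' @export
kfold_cv <- function(data, index, kind = "sm", terms = contract_terms(),
                     rho = 2, k = 5L, seed = 1L, block_by = NULL,
                     pricing = c("per_fold", "pooled"),
                     standardize = TRUE, log_index = FALSE, tau = 0.77) {
  pricing <- match.arg(pricing)
  n <- nrow(data)
  if (k < 2L || k > n) stop("k must be between 2 and n (k = n is ",
                            "leave-one-out)")
  zcol <- if (standardize) {
    data <- zscore_index(data, index, log = log_index)
    paste0("z_", index)
  } else index
  form <- stats::reformulate(zcol, "mortality")

  set.seed(as.integer(seed))
  folds <- if (is.null(block_by)) {
    sample(rep_len(seq_len(k), n))
  } else {
    blocks <- unique(data[[block_by]])
    if (length(blocks) < k) stop("fewer blocks than folds")
    bf <- sample(rep_len(seq_len(k), length(blocks)))
    bf[match(data[[block_by]], blocks)]
  }

  pooled_pred <- rep(NA_real_, n)
  prem_rec <- rep(NA_real_, n)
  fold_r2 <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fit <- tryCatch(
      loss_model(form, data[tr, , drop = FALSE], kind = kind, tau = tau),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    pooled_pred[te] <- predict(fit, data[te, , drop = FALSE], clip = TRUE)
    tr_pay <- indemnity(predict(fit, data[tr, , drop = FALSE],
                                clip = TRUE) , terms)
    prem_rec[te] <- premium(mean(tr_pay), terms$markup)
    M_te <- data$mortality[te]
    sst <- sum((M_te - mean(M_te))^2)
    fold_r2[f] <- if (sst > 0) {
      pr <- predict(fit, data[te, , drop = FALSE], clip = TRUE)
      1 - sum((M_te - pr)^2) / sst
    } else NA_real_
  }
  M <- data$mortality
  r2_cv <- 1 - sum((M - pooled_pred)^2) / sum((M - mean(M))^2)

  ev_cv <- evaluate_contract(
    data, predictions = pooled_pred, terms = terms, rho = rho,
    premium_index = if (pricing == "per_fold") prem_rec else NULL)

  fit_full <- loss_model(form, data, kind = kind, tau = tau)
  gof_full <- goodness_of_fit(fit_full, data)
  ev_full <- evaluate_contract(data, model = fit_full, terms = terms,
                               rho = rho)
  structure(list(k = k, seed = as.integer(seed), folds = folds,
                 pricing = pricing,
                 r_squared = r2_cv, RIB = ev_cv$welfare$RIB,
                 r_squared_insample = gof_full$r_squared,
                 RIB_insample = ev_full$welfare$RIB,
                 fold_r_squared = fold_r2, predictions = pooled_pred),
            class = "rib_cv")
}

#' @export
print.rib_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ", pricing ",
      x$pricing, ")\n", sep = "")
  cat(sprintf("  R-squared: %.3f out-of-fold vs %.3f in-sample\n",
              x$r_squared, x$r_squared_insample))
  cat(sprintf("  RIB:       %.3f out-of-fold vs %.3f in-sample\n",
              x$RIB, x$RIB_insample))
  invisible(x)
}
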