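#' Constant relative risk aversion utility
#'
#' `U(k) = k^(1 - rho) / (1 - rho)` for `rho != 1`, and `U(k) = log(k)`
#' for `rho = 1` (the continuous limit).  `rho = 0` is risk neutrality
#' (`U(k) = k`).  Wealth must be strictly positive.
#'
#' @param k Wealth, strictly positive.
#' @param rho Coefficient of relative risk aversion, `>= 0`; default 2.
#' @return Utility value(s).
#' @export
crra_utility <- function(k, rho = 2) {
  .check_rho(rho)
  .check_wealth(k)
  if (rho == 1) log(k) else k^(1 - rho) / (1 - rho)
}

#' Shadow value of money (marginal utility of wealth)
#'
#' `lambda(k) = k^(-rho)`, the derivative of the CRRA utility function:
#' high when wealth is scarce (bad states), low when wealth is plentiful.
#'
#' @inheritParams crra_utility
#' @return Marginal utility value(s).
#' @export
shadow_value <- function(k, rho = 2) {
  .check_rho(rho)
  .check_wealth(k)
  k^(-rho)
}

.check_rho <- function(rho) {
  if (length(rho) != 1L || !is.finite(rho) || rho < 0) {
    stop("rho must be a single non-negative number")
  }
}

.check_wealth <- function(k) {
  if (any(!is.finite(k) | k <= 0)) {
    bad <- which(!is.finite(k) | k <= 0)
    stop("non-positive wealth in state(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; CRRA utility requires strictly positive wealth ",
         "(see wealth_floor)")
  }
}

#' Expected utility over wealth states
#'
#' `EU = sum(U(k_j) * pi_j)`.  With `weights = NULL` every state gets
#' weight `1/n` (the empirical mode: a simple average across observed
#' location-seasons).
#'
#' @param k Wealth in each state, strictly positive.
#' @param rho Relative risk aversion.
#' @param weights Optional probabilities summing to 1.
#' @return Expected utility (a scalar).
#' @export
expected_utility <- function(k, rho = 2, weights = NULL) {
  u <- crra_utility(k, rho)
  if (is.null(weights)) return(mean(u))
  if (length(weights) != length(k)) stop("weights and k differ in length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  sum(u * weights)
}

#' Certainty equivalent of an expected utility
#'
#' The sure wealth that yields utility `eu`: the inverse of the CRRA
#' utility function, `CE = ((1 - rho) * eu)^(1 / (1 - rho))` for
#' `rho != 1`, `CE = exp(eu)` for `rho = 1`, and `CE = eu` at risk
#' neutrality.
#'
#' @param eu Expected utility.
#' @param rho Relative risk aversion.
#' @return Certainty-equivalent wealth.
#' @export
certainty_equivalent <- function(eu, rho = 2) {
  .check_rho(rho)
  if (rho == 0) return(eu)
  if (rho == 1) return(exp(eu))
  base <- (1 - rho) * eu
  if (any(base <= 0)) {
    stop("expected utility outside the attainable range for rho = ", rho)
  }
  base^(1 / (1 - rho))
}

#' Insurance benefit
#'
#' The expected-utility gain from holding a contract,
#' `IB = EU_with - EU_without`; on the certainty-equivalent (currency)
#' scale, `IBhat = CE_with - CE_without`.  Both differences have the same
#' sign because the certainty equivalent is monotone in expected utility.
#' A contract meets the minimum quality standard when `IB > 0`.
#'
#' @param eu_with,eu_without Expected utilities (or certainty
#'   equivalents) with and without the contract, computed under the same
#'   risk aversion on the same outcome states.
#' @return The difference.
#' @export
insurance_benefit <- function(eu_with, eu_without) {
  if (length(eu_with) != 1L || length(eu_without) != 1L) {
    stop("insurance_benefit expects scalar expected utilities")
  }
  eu_with - eu_without
}

#' Relative insurance benefit
#'
#' `RIB = IBhat_J / IBhat_P`: the certainty-equivalent benefit of a
#' candidate index contract relative to the perfect contract (payouts
#' based on observed losses) on the same data.  1 means as good as
#' perfect insurance, 0 no better than no insurance, negative worse than
#' no insurance.  Only defined when perfect insurance itself is
#' beneficial (`IBhat_P > 0`).
#'
#' @param ibhat_j Certainty-equivalent benefit of the candidate contract.
#' @param ibhat_p Certainty-equivalent benefit of the perfect contract.
#' @return The ratio (dimensionless, `<= 1` up to floating tolerance).
#' @export
rib <- function(ibhat_j, ibhat_p) {
  if (!is.finite(ibhat_p) || ibhat_p <= 0) {
    stop("perfect insurance offers no benefit on this data ",
         "(IBhat_P <= 0); RIB undefined")
  }
  ibhat_j / ibhat_p
}

#' Classify seasonal payout errors of an index contract
#'
#' Compares index payouts `I_J` with perfect-contract payouts `I_P`
#' season by season.  With shortfall
#' `s = (I_P - I_J) / insured value` (the default denominator;
#' `denominator = "perfect_payout"` divides by `I_P` instead):
#' true negative (`TN`) when no payment was due and none paid; false
#' positive (`FP`) when the contract overpays (`s < 0`); and false
#' negatives split by severity: `FN_small` (underpays by at most the
#' small threshold, including exact payment), `FN_intermediate`, and
#' `FN_severe` (underpays by more than the severe threshold).  The five
#' classes partition every record.
#'
#' @param payout_perfect,payout_index Payouts in currency.
#' @param terms A [contract_terms()] (supplies the insured value).
#' @param thresholds Named vector `c(small = 0.10, severe = 0.30)`:
#'   shortfall fractions separating the false-negative severities.
#' @param denominator `"insured_value"` (default) or `"perfect_payout"`.
#' @return A factor with levels `TN`, `FP`, `FN_small`,
#'   `FN_intermediate`, `FN_severe`.
#' @export
classify_payouts <- function(payout_perfect, payout_index,
                             terms = contract_terms(),
                             thresholds = c(small = 0.10, severe = 0.30),
                             denominator = c("insured_value",
                                             "perfect_payout")) {
  denominator <- match.arg(denominator)
  if (length(payout_perfect) != length(payout_index)) {
    stop("payout vectors differ in length")
  }
  denom <- switch(denominator,
    insured_value = terms$insured_tlu * terms$tlu_value,
    perfect_payout = ifelse(payout_perfect > 0, payout_perfect, 1))
  s <- (payout_perfect - payout_index) / denom
  cls <- character(length(s))
  cls[payout_perfect == 0 & payout_index == 0] <- "TN"
  cls[s < 0] <- "FP"
  fn <- payout_perfect > 0 & s >= 0
  cls[fn & s <= thresholds[["small"]]] <- "FN_small"
  cls[fn & s > thresholds[["small"]] & s <= thresholds[["severe"]]] <-
    "FN_intermediate"
  cls[fn & s > thresholds[["severe"]]] <- "FN_severe"
  # I_P == I_J == 0 handled as TN above; any remainder is exact payment
  cls[cls == ""] <- "FN_small"
  factor(cls, levels = c("TN", "FP", "FN_small", "FN_intermediate",
                         "FN_severe"))
}

#' Evaluate an index-insurance contract end to end
#'
#' Runs the full welfare accounting for a candidate contract on observed
#' location-season mortality: predict mortality from the loss model (or
#' take supplied predictions), apply the indemnity schedule to both the
#' predictions (index contract) and the observations (perfect contract),
#' price both contracts actuarially from their own backcast payouts with
#' the markup, build the three wealth series (uninsured, index-insured,
#' perfect-insured), and compute expected utilities, certainty
#' equivalents, insurance benefits, the RIB, the payout-error
#' classification, and the per-state records needed for the Taylor
#' decomposition.
#'
#' All wealth accounting is done internally on the normalized scale
#' (fractions of the insured herd value), with currency applied as a
#' final scale; CRRA utility is homothetic so certainty equivalents scale
#' linearly and the RIB is unit-free.
#'
#' @param data Season table with a mortality column (and the model's
#'   predictor column if `model` is given).
#' @param model A fitted [loss_model()], or `NULL` if `predictions` are
#'   supplied directly.
#' @param predictions Optional vector of predicted mortality fractions
#'   (one per row of `data`); overrides `model`.
#' @param terms A [contract_terms()].
#' @param rho Relative risk aversion (default 2).
#' @param weights Optional state probabilities (default: equal weight per
#'   location-season).
#' @param mortality_col Name of the mortality column.
#' @param wealth_floor Optional floor (currency) applied to insured and
#'   uninsured wealth before taking utilities.  The default (`NULL`)
#'   raises an error on non-positive wealth instead of silently flooring.
#' @param lambda_at Wealth at which the shadow value is evaluated in the
#'   decomposition records: `"uninsured"` (default; the state the
#'   household is in absent the transfer) or `"insured"`.
#' @param premium_index,premium_perfect Optional premium overrides
#'   (currency per season, scalar or per record), used e.g. by
#'   cross-validation to apply fold-specific pricing; default `NULL`
#'   prices from the backcast payouts in `data`.
#' @return An object of class `"rib_eval"`: a list with components
#'   `welfare` (EU_N/EU_J/EU_P on the normalized-wealth scale, CE_N/CE_J/
#'   CE_P in currency, IB_J, IB_P, IBhat_J, IBhat_P, RIB), `pricing`
#'   (AFP and premium in currency for both contracts), `records` (a
#'   per-season data.frame with payouts, wealth, Delta, the shadow value,
#'   weights and the error class), `class_counts`, `terms`, and `rho`.
#' @examples
#' d <- simulate_seasons(scenario_config(seed = 7))
#' ev <- evaluate_contract(d, predictions = d$mortality)  # perfect index
#' ev$welfare$RIB  # exactly 1
#' @export
evaluate_contract <- function(data, model = NULL, predictions = NULL,
                              terms = contract_terms(), rho = 2,
                              weights = NULL, mortality_col = "mortality",
                              wealth_floor = NULL,
                              lambda_at = c("uninsured", "insured"),
                              premium_index = NULL,
                              premium_perfect = NULL) {
  lambda_at <- match.arg(lambda_at)
  M <- as.numeric(data[[mortality_col]])
  if (anyNA(M)) stop("missing mortality in evaluation data")
  if (any(M < 0 | M > 1)) stop("mortality must be in [0, 1]")
  n <- length(M)
  if (is.null(predictions)) {
    if (is.null(model)) stop("supply either a fitted model or predictions")
    predictions <- predict(model, data, clip = TRUE)
  }
  if (length(predictions) != n) stop("predictions do not match data rows")
  predictions <- pmin(pmax(as.numeric(predictions), 0), 1)

  w <- if (is.null(weights)) rep(1 / n, n) else {
    if (length(weights) != n) stop("weights do not match data rows")
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
      stop("weights must be non-negative and sum to 1")
    }
    weights
  }

  t <- terms$trigger; m <- terms$markup
  V <- terms$insured_tlu * terms$tlu_value  # currency per normalized unit

  # normalized (fraction-of-insured-value) accounting
  i_j <- pmax(0, predictions - t)
  i_p <- pmax(0, M - t)
  afp_j <- sum(i_j * w); afp_p <- sum(i_p * w)
  p_j <- if (is.null(premium_index)) afp_j * (1 + m) else premium_index / V
  p_p <- if (is.null(premium_perfect)) afp_p * (1 + m) else
    premium_perfect / V
  k_n <- 1 - M
  k_j <- k_n + i_j - p_j
  k_p <- k_n + i_p - p_p
  if (!is.null(wealth_floor)) {
    fl <- wealth_floor / V
    k_n <- pmax(k_n, fl); k_j <- pmax(k_j, fl); k_p <- pmax(k_p, fl)
  }

  eu_n <- expected_utility(k_n, rho, w)
  eu_j <- expected_utility(k_j, rho, w)
  eu_p <- expected_utility(k_p, rho, w)
  ce_n <- certainty_equivalent(eu_n, rho) * V
  ce_j <- certainty_equivalent(eu_j, rho) * V
  ce_p <- certainty_equivalent(eu_p, rho) * V
  ib_j <- insurance_benefit(eu_j, eu_n)
  ib_p <- insurance_benefit(eu_p, eu_n)
  ibhat_j <- ce_j - ce_n
  ibhat_p <- ce_p - ce_n
  # RIB is only meaningful when perfect insurance itself is beneficial;
  # the report carries NA in that case (rib() itself raises an error)
  rib_val <- if (is.finite(ibhat_p) && ibhat_p > 0) {
    rib(ibhat_j, ibhat_p)
  } else {
    NA_real_
  }

  lam <- shadow_value(if (lambda_at == "uninsured") k_n else k_j, rho)
  cls <- classify_payouts(i_p * V, i_j * V, terms)
  key_cols <- intersect(c("location", "year", "season"), names(data))
  records <- cbind(
    data[key_cols],
    data.frame(
      mortality = M, predicted = predictions,
      payout_perfect = i_p * V, payout_index = i_j * V,
      wealth_n = k_n * V, wealth_j = k_j * V, wealth_p = k_p * V,
      delta = (i_j - p_j) * V,           # insured minus uninsured wealth
      lambda = lam, weight = w, error_class = cls,
      stringsAsFactors = FALSE
    )
  )
  structure(list(
    welfare = list(EU_N = eu_n, EU_J = eu_j, EU_P = eu_p,
                   CE_N = ce_n, CE_J = ce_j, CE_P = ce_p,
                   IB_J = ib_j, IB_P = ib_p,
                   IBhat_J = ibhat_j, IBhat_P = ibhat_p, RIB = rib_val),
    pricing = list(afp_index = afp_j * V, premium_index = p_j * V,
                   afp_perfect = afp_p * V, premium_perfect = p_p * V),
    records = records,
    class_counts = table(records$error_class),
    terms = terms, rho = rho, lambda_at = lambda_at, n = n
  ), class = "rib_eval")
}

#' @export
print.rib_eval <- function(x, digits = 4, ...) {
  w <- x$welfare
  cat("Index-insurance contract evaluation (rho = ", x$rho, ", n = ",
      x$n, ")\n", sep = "")
  cat(sprintf("  CE no insurance:   %10.2f\n", w$CE_N))
  cat(sprintf("  CE index contract: %10.2f   (IBhat_J %+.2f)\n",
              w$CE_J, w$IBhat_J))
  cat(sprintf("  CE perfect:        %10.2f   (IBhat_P %+.2f)\n",
              w$CE_P, w$IBhat_P))
  cat(sprintf("  premium (index):   %10.2f   AFP %.2f\n",
              x$pricing$premium_index, x$pricing$afp_index))
  cat(sprintf("  RIB: %.*f\n", digits, w$RIB))
  cat("  payout classes: ",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.rib_eval <- function(object, ...) {
  c(object$welfare[c("CE_N", "CE_J", "CE_P", "IBhat_J", "IBhat_P", "RIB")],
    object$pricing)
}

#' First-order decomposition of the insurance benefit
#'
#' Approximates the insurance benefit as the probability-weighted sum of
#' the wealth transfer in each state times the shadow value of money when
#' the transfer occurs:
#' `IB ~ sum_j Delta(M_j) * lambda(k_j) * pi_j` (a first-order Taylor
#' expansion of expected utility around the no-insurance wealth).  The
#' approximation error relative to the exact expected-utility difference
#' is reported; it vanishes quadratically as payouts and premium shrink.
#'
#' @param x A `"rib_eval"` from [evaluate_contract()].
#' @param rho Risk aversion; defaults to the one stored in `x`.
#' @return A list with `rows` (per-state contributions), `total` (the
#'   Taylor approximation of IB, on the normalized-wealth utility
#'   scale), `exact_ib`, and `approx_error = total - exact_ib`.
#' @export
decompose_ib <- function(x, rho = x$rho) {
  if (!inherits(x, "rib_eval")) stop("x must be a rib_eval object")
  V <- x$terms$insured_tlu * x$terms$tlu_value
  r <- x$records
  delta <- r$delta / V
  k_n <- r$wealth_n / V
  lam <- shadow_value(k_n, rho)
  contrib <- delta * lam * r$weight
  exact <- expected_utility(r$wealth_j / V, rho, r$weight) -
    expected_utility(k_n, rho, r$weight)
  rows <- data.frame(delta = delta, lambda = lam, weight = r$weight,
                     contribution = contrib)
  list(rows = rows, total = sum(contrib), exact_ib = exact,
       approx_error = sum(contrib) - exact)
}

#' Sensitivity of RIB to risk aversion
#'
#' Re-evaluates a contract over a grid of relative risk aversion values
#' (default 0 to 3, the range over which field estimates for smallholder
#' populations vary).  `rho = 1` uses the log-utility branch.  Where the
#' perfect contract offers no benefit (e.g. `rho = 0` with a positive
#' markup, where insurance is a pure cost), RIB is undefined and reported
#' as `NA`.
#'
#' @inheritParams evaluate_contract
#' @param rho_grid Numeric vector of risk-aversion values.
#' @return A data.frame with one row per `rho`: the expected utilities,
#'   certainty equivalents, benefits and RIB.
#' @export
rho_sweep <- function(data, model = NULL, predictions = NULL,
                      terms = contract_terms(),
                      rho_grid = seq(0, 3, by = 0.25), ...) {
  rows <- lapply(rho_grid, function(r) {
    ev <- tryCatch(
      evaluate_contract(data, model = model, predictions = predictions,
                        terms = terms, rho = r, ...),
      error = function(e) NULL)
    if (is.null(ev)) {
      return(data.frame(rho = r, EU_N = NA, EU_J = NA, EU_P = NA,
                        CE_N = NA, CE_J = NA, CE_P = NA, IB_J = NA,
                        IB_P = NA, IBhat_J = NA, IBhat_P = NA, RIB = NA))
    }
    w <- ev$welfare
    data.frame(rho = r, EU_N = w$EU_N, EU_J = w$EU_J, EU_P = w$EU_P,
               CE_N = w$CE_N, CE_J = w$CE_J, CE_P = w$CE_P,
               IB_J = w$IB_J, IB_P = w$IB_P,
               IBhat_J = w$IBhat_J, IBhat_P = w$IBhat_P, RIB = w$RIB)
  })
  do.call(rbind, rows)
}
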