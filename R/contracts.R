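#' Define index-insurance contract terms
#'
#' The livestock contract pays `max(0, M - trigger)` per insured TLU: a
#' deductible contract that restores herd value lost beyond the trigger
#' mortality.  The premium is the actuarially fair price (long-run mean
#' payout) loaded by a proportional markup.  A crop-yield variant pays on
#' the shortfall of predicted yield below a fraction of the location's
#' long-term mean yield.
#'
#' @param trigger Mortality fraction below which nothing is paid
#'   (deductible); default 0.23.
#' @param markup Proportional premium loading over the actuarially fair
#'   price; default 0.25.
#' @param insured_tlu Number of TLU insured; default 1.
#' @param tlu_value Currency value of one TLU; default 1000 (USD).
#' @param mode `"livestock"` (default) or `"crop"`.
#' @param crop_price Unit value `q` of the crop (crop mode).
#' @param mean_yield Long-term mean yield `mu_l` for the location (crop
#'   mode).
#' @param yield_trigger Yield trigger fraction `t_y` (crop mode).
#' @return A list of class `"contract_terms"`.
#' @export
contract_terms <- function(trigger = 0.23, markup = 0.25, insured_tlu = 1,
                           tlu_value = 1000,
                           mode = c("livestock", "crop"),
                           crop_price = NULL, mean_yield = NULL,
                           yield_trigger = NULL) {
  mode <- match.arg(mode)
  if (trigger < 0 || trigger >= 1) stop("trigger must be in [0, 1)")
  if (markup < 0) stop("markup must be non-negative")
  if (insured_tlu <= 0) stop("insured_tlu must be positive")
  if (tlu_value <= 0) stop("tlu_value must be positive")
  structure(list(trigger = trigger, markup = markup,
                 insured_tlu = insured_tlu, tlu_value = tlu_value,
                 mode = mode, crop_price = crop_price,
                 mean_yield = mean_yield, yield_trigger = yield_trigger),
            class = "contract_terms")
}

#' @export
print.contract_terms <- function(x, ...) {
  cat("Contract terms (", x$mode, "): trigger ", x$trigger,
      ", markup ", x$markup, ", ", x$insured_tlu, " TLU @ ",
      x$tlu_value, "\n", sep = "")
  invisible(x)
}

#' Indemnity payout of a mortality-triggered contract
#'
#' `max(0, M - trigger) * insured_tlu * tlu_value`: nothing is paid below
#' the deductible, and losses beyond it are compensated in full.  The same
#' schedule applies whether `M` is the observed mortality (the perfect
#' contract) or a model prediction (an index contract).
#'
#' @param M Mortality fraction(s) in `[0, 1]`.
#' @param terms A [contract_terms()] object.
#' @return Payout(s) in currency.
#' @examples
#' indemnity(0.65, contract_terms())  # $420 on a $1000 TLU at trigger 0.23
#' @export
indemnity <- function(M, terms = contract_terms()) {
  if (any(!is.na(M) & (M < 0 | M > 1))) stop("mortality must be in [0, 1]")
  pmax(0, M - terms$trigger) * terms$insured_tlu * terms$tlu_value
}

#' Indemnity payout of a crop-yield contract
#'
#' `q * max(0, t_y * mu_l - yhat)`: pays the value of the shortfall of
#' (predicted) yield below the trigger fraction of the location's
#' long-term mean yield.
#'
#' @param predicted_yield Predicted (or observed) yield, `>= 0`.
#' @param terms A [contract_terms()] with `mode = "crop"` and
#'   `crop_price`, `mean_yield`, `yield_trigger` set.
#' @return Payout(s) in currency.
#' @export
indemnity_crop <- function(predicted_yield, terms) {
  if (is.null(terms$mean_yield) || terms$mean_yield <= 0) {
    stop("crop contract requires a positive long-term mean yield")
  }
  if (is.null(terms$crop_price) || is.null(terms$yield_trigger)) {
    stop("crop contract requires crop_price and yield_trigger")
  }
  if (any(predicted_yield < 0)) stop("predicted yield must be non-negative")
  terms$crop_price *
    pmax(0, terms$yield_trigger * terms$mean_yield - predicted_yield)
}

#' Actuarially fair price
#'
#' The expected indemnity payout per insured unit: a probability-weighted
#' average over a discrete outcome distribution (binned mode), or the
#' simple mean over observed location-seasons (empirical mode,
#' `weights = NULL`).
#'
#' @param payouts Numeric vector of payouts.
#' @param weights Optional probabilities, same length, summing to 1;
#'   `NULL` for equal weights.
#' @return The AFP in the units of `payouts`.
#' @export
actuarially_fair_price <- function(payouts, weights = NULL) {
  if (length(payouts) == 0L) stop("empty payout list")
  if (is.null(weights)) return(mean(payouts))
  if (length(weights) != length(payouts)) {
    stop("weights and payouts differ in length")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  sum(payouts * weights)
}

#' Marked-up premium
#'
#' `premium = afp * (1 + markup)`.  An AFP of $20 at a 25% markup costs
#' the household $25 per season.
#'
#' @param afp Actuarially fair price, `>= 0`.
#' @param markup Proportional loading, `>= 0`.
#' @return The premium.
#' @export
premium <- function(afp, markup = 0.25) {
  if (any(afp < 0)) stop("afp must be non-negative")
  if (markup < 0) stop("markup must be non-negative")
  afp * (1 + markup)
}

#' Price a contract from backcast payouts
#'
#' @param payouts Payouts (currency) over the pricing sample or outcome
#'   states.
#' @param terms A [contract_terms()].
#' @param weights Optional state probabilities (binned mode).
#' @return A list of class `"priced_contract"` with `afp` and `premium`.
#' @export
price_contract <- function(payouts, terms = contract_terms(),
                           weights = NULL) {
  afp <- actuarially_fair_price(payouts, weights)
  structure(list(terms = terms, afp = afp,
                 premium = premium(afp, terms$markup)),
            class = "priced_contract")
}

#' @export
print.priced_contract <- function(x, ...) {
  cat("Priced contract: AFP ", format(x$afp), ", premium ",
      format(x$premium), " (markup ", x$terms$markup, ")\n", sep = "")
  invisible(x)
}

#' Next-season wealth with and without insurance
#'
#' Uninsured wealth is the surviving herd value
#' `insured_tlu * tlu_value * (1 - M)`; insured wealth adds the indemnity
#' received and subtracts the premium (paid every season, including payout
#' seasons).
#'
#' @param M Mortality fraction(s).
#' @param indemnity_paid Indemnity received (currency); ignored when
#'   `insured = FALSE`.
#' @param premium_paid Premium paid (currency); ignored when
#'   `insured = FALSE`.
#' @param terms A [contract_terms()].
#' @param insured Logical.
#' @return Wealth in currency (can be negative; welfare functions guard
#'   the domain).
#' @export
wealth_next <- function(M, indemnity_paid = 0, premium_paid = 0,
                        terms = contract_terms(), insured = TRUE) {
  if (any(!is.na(M) & (M < 0 | M > 1))) stop("mortality must be in [0, 1]")
  base <- terms$insured_tlu * terms$tlu_value * (1 - M)
  if (!insured) return(base)
  base + indemnity_paid - premium_paid
}
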