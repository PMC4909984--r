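#' Prospect-theory agent parameters
#'
#' Choice model used for the (computerised) social partner and for synthetic
#' subjects: power utility with curvature `rho` shared across gains and
#' losses and multiplicative loss aversion `lambda` on losses. Probability
#' weighting is omitted because all gambles are 50/50, so any weighting is
#' absorbed into the other parameters. The default partner has typical
#' preferences: loss aversion 1.35 and risk aversion in gains / risk seeking
#' in losses, rho = 0.9, choosing deterministically.
#'
#' @param lambda loss aversion, > 0.
#' @param rho utility curvature, in (0, 2).
#' @param mu inverse temperature for softmax choice; `Inf` (default) gives
#'   deterministic expected-utility maximisation with ties broken to safe.
#' @return object of class `pt_params`.
#' @export
pt_params <- function(lambda = 1.35, rho = 0.9, mu = Inf) {
  if (!is.finite(lambda) || lambda <= 0)
    stop_mswb("pt_params: lambda must be positive", class = "mswb_param_error")
  if (!is.finite(rho) || rho <= 0 || rho >= 2)
    stop_mswb("pt_params: rho must lie in (0, 2)", class = "mswb_param_error")
  if (is.na(mu) || mu < 0)
    stop_mswb("pt_params: mu must be >= 0 or Inf", class = "mswb_param_error")
  structure(list(lambda = lambda, rho = rho, mu = mu), class = "pt_params")
}

#' Prospect-theory utility
#'
#' `u(x) = x^rho` for gains and `u(x) = -lambda * (-x)^rho` for losses;
#' `u(0) = 0`. Vectorised over `x`.
#'
#' @param x monetary amount(s), GBP.
#' @param params a [pt_params()].
#' @return utilities, dimensionless.
#' @export
pt_utility <- function(x, params = pt_params()) {
  stopifnot(inherits(params, "pt_params"))
  ifelse(x >= 0, x^params$rho, -params$lambda * (-x)^params$rho)
}

# Expected-utility difference gamble - safe for rows of a trial data frame.
pt_value_diff <- function(trials, params) {
  eu_gamble <- 0.5 * pt_utility(trials$gamble_high, params) +
    0.5 * pt_utility(trials$gamble_low, params)
  eu_gamble - pt_utility(trials$safe_amount, params)
}

#' Simulate a choice between safe option and gamble
#'
#' Deterministic mode (`mu = Inf`): gamble iff its expected utility strictly
#' exceeds the safe option's (ties go to safe). Softmax mode: gamble with
#' probability `plogis(mu * (EU_gamble - EU_safe))`. Vectorised over the rows
#' of `trials`.
#'
#' @param trials data frame of trial specifications (battery rows).
#' @param params a [pt_params()].
#' @param seed integer seed, used only in softmax mode.
#' @return character vector, `"safe"` or `"gamble"`, one per trial.
#' @export
pt_choice <- function(trials, params = pt_params(), seed = 1L) {
  stopifnot(inherits(params, "pt_params"))
  dv <- pt_value_diff(trials, params)
  if (is.infinite(params$mu)) {
    ifelse(dv > 0, "gamble", "safe")
  } else {
    p <- stats::plogis(params$mu * dv)
    with_seed(seed, ifelse(runif(length(dv)) < p, "gamble", "safe"))
  }
}

#' Simulate one session of the task
#'
#' Plays out a session schedule. On non-social trials the subject agent
#' chooses and, if gambling, a single fair coin resolves the outcome. On
#' social trials the partner agent chooses for both players: a safe choice
#' pays both players the safe amount; a gamble choice resolves two
#' independent fair coins, one for the subject and one for the partner, over
#' the same two outcomes — the design feature that generates advantageous
#' and disadvantageous inequality.
#'
#' @param schedule an `mswb_schedule`.
#' @param subject_params,partner_params [pt_params()] for the two agents.
#' @param seed integer seed; outcomes are deterministic given all arguments.
#' @return data frame with one row per trial: `trial_index`, `is_social`,
#'   `chooser` ("subject"/"partner"), `choice` ("safe"/"gamble"),
#'   `outcome_subject`, `outcome_partner` (`NA` on non-social trials).
#' @export
simulate_session <- function(schedule, subject_params = pt_params(),
                             partner_params = pt_params(), seed = 1L) {
  tr <- schedule$trials
  n <- nrow(tr)
  seeds <- derive_seeds(as.numeric(seed) + 2000029, 3L)
  choice <- character(n)
  soc <- tr$is_social
  if (any(!soc))
    choice[!soc] <- pt_choice(tr[!soc, , drop = FALSE], subject_params,
                              seed = seeds[1])
  if (any(soc))
    choice[soc] <- pt_choice(tr[soc, , drop = FALSE], partner_params,
                             seed = seeds[2])
  with_seed(seeds[3], {
    coin_subj <- runif(n) < tr$gamble_prob
    coin_part <- runif(n) < tr$gamble_prob
    gam <- choice == "gamble"
    outcome_subject <- ifelse(gam,
                              ifelse(coin_subj, tr$gamble_high, tr$gamble_low),
                              tr$safe_amount)
    outcome_partner <- ifelse(soc,
                              ifelse(gam,
                                     ifelse(coin_part, tr$gamble_high,
                                            tr$gamble_low),
                                     tr$safe_amount),
                              NA_real_)
    data.frame(trial_index = tr$trial_index,
               is_social = soc,
               chooser = ifelse(soc, "partner", "subject"),
               choice = choice,
               outcome_subject = outcome_subject,
               outcome_partner = outcome_partner)
  })
}
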