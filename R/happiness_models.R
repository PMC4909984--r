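#' Happiness model specifications
#'
#' Three nested exponential-decay models of momentary happiness are
#' supported. All share weights on decayed sums of chosen certain rewards
#' (CR), chosen-gamble expected values (EV) and reward prediction errors
#' (RPE). The social variants add inequality terms computed from the
#' subject's reward R and the partner's reward O on social trials:
#'
#' * `nonsocial` — CR, EV, RPE only (4 free parameters incl. the forgetting
#'   factor gamma).
#' * `simple_inequality` — adds one weight on `|R - O|` (5 parameters).
#' * `guilt_envy` — adds separate weights on advantageous inequality
#'   `max(R - O, 0)` ("guilt", w4) and disadvantageous inequality
#'   `max(O - R, 0)` ("envy", w5) (6 parameters).
#'
#' Ratings are z-scored before fitting, so no constant term is included.
#'
#' @param name one of `"nonsocial"`, `"simple_inequality"`, `"guilt_envy"`.
#' @return object of class `model_spec` with elements `name`, `terms`
#'   (design-matrix columns, in order) and `n_params` (weights + gamma).
#' @export
model_spec <- function(name = c("nonsocial", "simple_inequality",
                                "guilt_envy")) {
  name <- match.arg(name)
  terms <- switch(name,
                  nonsocial = c("CR", "EV", "RPE"),
                  simple_inequality = c("CR", "EV", "RPE", "inequality"),
                  guilt_envy = c("CR", "EV", "RPE", "guilt", "envy"))
  structure(list(name = name, terms = terms,
                 n_params = length(terms) + 1L),
            class = "model_spec")
}

#' All three model specifications
#' @return named list of [model_spec()] objects.
#' @export
all_models <- function() {
  ms <- lapply(c("nonsocial", "simple_inequality", "guilt_envy"), model_spec)
  names(ms) <- vapply(ms, `[[`, "", "name")
  ms
}

#' Derive per-trial model events from outcomes
#'
#' Converts simulated (or recorded) trial outcomes into the per-trial inputs
#' of the happiness models. Terms for unchosen options are zero: a safe
#' choice sets CR to the safe amount and EV = RPE = 0; a gamble choice sets
#' CR = 0, EV to the gamble's mean and RPE to outcome minus EV. On social
#' trials R and O record the subject's and partner's rewards; on non-social
#' trials O is absent (NA) and all inequality terms are zero.
#'
#' @param outcomes data frame from [simulate_session()].
#' @param schedule the `mswb_schedule` the outcomes came from.
#' @return data frame with columns `trial_index`, `is_social`, `CR`, `EV`,
#'   `RPE`, `R`, `O`.
#' @export
derive_events <- function(outcomes, schedule) {
  tr <- schedule$trials
  if (nrow(outcomes) != nrow(tr) ||
      !identical(as.integer(outcomes$trial_index), as.integer(tr$trial_index)))
    stop_mswb("outcomes do not align with schedule trials",
              class = "mswb_alignment_error")
  gam <- outcomes$choice == "gamble"
  ev <- (tr$gamble_high + tr$gamble_low) / 2
  data.frame(trial_index = tr$trial_index,
             is_social = tr$is_social,
             CR = ifelse(gam, 0, tr$safe_amount),
             EV = ifelse(gam, ev, 0),
             RPE = ifelse(gam, outcomes$outcome_subject - ev, 0),
             R = outcomes$outcome_subject,
             O = outcomes$outcome_partner)
}

#' Exponentially decayed sum
#'
#' `sum_{j <= t} gamma^(t - j) * values[j]`: a forgetting factor `gamma` in
#' \[0, 1\] makes recent events more influential than earlier ones
#' (`gamma^0 = 1` even at `gamma = 0`, so `gamma = 0` keeps only trial `t`
#' and `gamma = 1` is a plain cumulative sum).
#'
#' @param values numeric per-trial values, indexed 1..n.
#' @param gamma forgetting factor in \[0, 1\].
#' @param t reference trial index (1..n), or 0 for "no trials yet" (sum 0).
#' @return the decayed sum, same units as `values`.
#' @export
decayed_sum <- function(values, gamma, t) {
  check_gamma(gamma)
  if (t == 0L) return(0)
  stopifnot(t >= 1L, t <= length(values))
  j <- seq_len(t)
  sum(gamma^(t - j) * values[j])
}

check_gamma <- function(gamma) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop_mswb("gamma must lie in [0, 1]", class = "mswb_param_error")
  invisible(gamma)
}

# Per-trial term values for a model: matrix n_trials x length(terms).
event_terms <- function(events, terms) {
  soc <- events$is_social
  diffRO <- ifelse(soc & !is.na(events$O), events$R - events$O, 0)
  cols <- list(CR = events$CR, EV = events$EV, RPE = events$RPE,
               inequality = abs(diffRO),
               guilt = pmax(diffRO, 0),
               envy = pmax(-diffRO, 0))
  m <- do.call(cbind, cols[terms])
  colnames(m) <- terms
  m
}

#' Build the design matrix of decayed regressors
#'
#' Row `r`, column `k` holds the decayed sum of term `k` over all trials up
#' to rating `r`'s reference trial (the most recent completed trial; a
#' rating at the very start of a session, position 0, yields a zero row).
#' Columns are ordered `CR, EV, RPE`, then `inequality` or `guilt, envy`
#' for the social models.
#'
#' @param events data frame from [derive_events()].
#' @param positions integer reference trial indices, one per rating
#'   (see [rating_positions()]).
#' @param gamma forgetting factor in \[0, 1\].
#' @param model a [model_spec()].
#' @return numeric matrix, `length(positions)` rows.
#' @export
build_design_matrix <- function(events, positions, gamma,
                                model = model_spec("guilt_envy")) {
  check_gamma(gamma)
  stopifnot(inherits(model, "model_spec"))
  terms <- event_terms(events, model$terms)
  if (!length(positions))
    return(matrix(numeric(), 0L, length(model$terms),
                  dimnames = list(NULL, model$terms)))
  stopifnot(all(positions >= 0L), all(positions <= nrow(terms)))
  # recursive filter computes all cumulative decayed sums in O(n) per term
  dec <- apply(terms, 2L, function(x)
    as.numeric(stats::filter(x, gamma, method = "recursive")))
  dec <- rbind(0, matrix(dec, nrow = nrow(terms)))  # row 1 <-> position 0
  out <- dec[positions + 1L, , drop = FALSE]
  colnames(out) <- model$terms
  out
}

#' Predict happiness ratings from model parameters
#'
#' Linear prediction: design matrix of decayed regressors times the model
#' weights. No constant term (ratings are z-scored). With all social weights
#' zero, the guilt-envy model's predictions equal the non-social model's.
#'
#' @param params named list or vector with one weight per model term (names
#'   matching `model$terms`) and `gamma`.
#' @param events data frame from [derive_events()].
#' @param positions rating reference trial indices.
#' @param model a [model_spec()].
#' @return numeric vector of predicted ratings (z-units).
#' @export
predict_ratings <- function(params, events, positions,
                            model = model_spec("guilt_envy")) {
  params <- as.list(params)
  missing <- setdiff(c(model$terms, "gamma"), names(params))
  if (length(missing))
    stop_mswb("params lack: ", paste(missing, collapse = ", "),
              class = "mswb_param_error")
  X <- build_design_matrix(events, positions, params$gamma, model)
  w <- unlist(params[model$terms])
  drop(X %*% w)
}
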